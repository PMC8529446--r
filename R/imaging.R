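# Phase-separation quantification: FRAP double normalisation and
# single-exponential recovery fitting, droplet segmentation and counting,
# compound-screen statistics, two-channel colocalization, and the
# xenograft tumor-volume utility.

#' Read a FRAP trace table
#'
#' Expects a TSV with columns `time_s`, `roi`, `background`,
#' `reference`: raw integrated intensities of the bleached ROI, a
#' background region, and an unbleached reference region, sampled on a
#' common time grid with the bleach at t = 0 and at least one pre-bleach
#' point at negative time.
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
readFRAPTrace <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE,
                   stringsAsFactors = FALSE)
  need <- c("time_s", "roi", "background", "reference")
  if (!all(need %in% names(df)))
    stop("FRAP trace needs columns: ", paste(need, collapse = ", "))
  if (is.unsorted(df$time_s, strictly = TRUE))
    stop("time_s must be strictly increasing")
  df
}

#' Double-normalise a FRAP trace
#'
#' Background-subtracts both the ROI and the unbleached reference region,
#' divides ROI by reference to correct acquisition photobleaching, and
#' scales by the mean of the same quotient over the pre-bleach points so
#' the pre-bleach mean is 1 by construction.
#'
#' @param trace data.frame with `time_s`, `roi`, `background`,
#'   `reference`.
#' @return data.frame with `time_s` and normalised `intensity`.
#' @export
frapNormalize <- function(trace) {
  denom <- trace$reference - trace$background
  bad <- which(denom <= 0)
  if (length(bad))
    stop(sprintf("reference minus background is non-positive at t = %g s",
                 trace$time_s[bad[1]]))
  pre <- trace$time_s < 0
  if (!any(pre)) stop("trace has no pre-bleach (negative time) points")
  q <- (trace$roi - trace$background) / denom
  data.frame(time_s = trace$time_s, intensity = q / mean(q[pre]))
}

#' Fit single-exponential FRAP recovery
#'
#' Least-squares fit of
#' \eqn{I(t) = floor + (plateau - floor)(1 - e^{-kt})} to the post-bleach
#' (t >= 0) portion of a normalised trace, with deterministic
#' initialisation (floor from the first post-bleach point, plateau from
#' the mean of the last 10 points, k from the time to half recovery) and
#' bounds k > 0, plateau between floor and 1.5. Reports the mobile
#' fraction \eqn{(plateau - floor)/(1 - floor)} and half-time
#' \eqn{\ln 2 / k}. Non-convergence yields a flagged record, not an
#' exception.
#'
#' @param normalized data.frame from [frapNormalize()].
#' @return [FRAPFit-class].
#' @export
frapFit <- function(normalized) {
  post <- normalized[normalized$time_s >= 0, , drop = FALSE]
  if (nrow(post) < 10L) stop("need at least 10 post-bleach points")
  t <- post$time_s
  y <- post$intensity
  fl0 <- y[1]
  pl0 <- mean(tail(y, 10L))
  if (pl0 < fl0) pl0 <- fl0
  failFit <- function(msg) new("FRAPFit", plateau = NA_real_, rate = NA_real_,
                               postBleachFloor = NA_real_,
                               mobileFraction = NA_real_, tHalf = NA_real_,
                               converged = FALSE, message = msg)
  if (stats::sd(y) < 1e-12 || pl0 - fl0 < 1e-12) {
    # no recovery at all: plateau = floor, mobile fraction 0
    return(new("FRAPFit", plateau = fl0, rate = NA_real_,
               postBleachFloor = fl0, mobileFraction = 0,
               tHalf = NA_real_, converged = TRUE,
               message = "no recovery (plateau equals floor)"))
  }
  half <- fl0 + (pl0 - fl0) / 2
  iHalf <- which(y >= half)[1]
  k0 <- if (!is.na(iHalf) && t[iHalf] > 0) log(2) / t[iHalf] else 0.1
  # parameterise plateau = floor + delta, delta >= 0, to keep the bound
  # plateau >= floor linear in the parameters
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ fl + d * (1 - exp(-k * t)),
                      start = list(fl = fl0, d = pl0 - fl0, k = k0),
                      lower = c(fl = -0.5, d = 0, k = 1e-6),
                      upper = c(fl = 1.5, d = 2, k = Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) return(failFit(conditionMessage(fit)))
  cf <- stats::coef(fit)
  fl <- unname(cf["fl"]); pl <- unname(cf["fl"] + cf["d"]); k <- unname(cf["k"])
  if (pl > 1.5) pl <- 1.5
  mob <- if (fl < 1) (pl - fl) / (1 - fl) else NA_real_
  mob <- min(max(mob, 0), 1)
  new("FRAPFit", plateau = pl, rate = k, postBleachFloor = fl,
      mobileFraction = mob, tHalf = log(2) / k, converged = TRUE,
      message = "")
}

# ---- droplet segmentation -------------------------------------------------

#' Segment fluorescent droplets in a grayscale image
#'
#' Binarises the image (Otsu threshold on the intensity-rescaled image by
#' default, or a fixed threshold on raw intensities), labels connected
#' components with 8-connectivity, and discards components below the
#' minimum area, whose circularity \eqn{4\pi A / P^2} falls below the
#' minimum (default 0.6, tolerant of pixelated disks), or whose mean
#' intensity fails to exceed the sub-threshold background mean by
#' `minContrastSd` background standard deviations — the contrast gate is
#' affine-invariant and keeps a droplet-free pure-noise image from
#' segmenting into spurious blobs. A blank image yields an empty droplet
#' set, not an error.
#'
#' @param image numeric matrix (grayscale).
#' @param thresholdMethod `"otsu"` or `"fixed"`.
#' @param threshold fixed threshold (required for `"fixed"`; must lie in
#'   the image intensity range).
#' @param minArea minimum component area in px^2 (default 9).
#' @param minCircularity minimum circularity (default 0.6).
#' @param minContrastSd minimum component contrast over the background,
#'   in background standard deviations (default 5; 0 disables).
#' @param imageId,channel identifiers stored on the result.
#' @return [DropletSet-class].
#' @export
segmentDroplets <- function(image, thresholdMethod = c("otsu", "fixed"),
                            threshold = NULL, minArea = 9,
                            minCircularity = 0.6, minContrastSd = 5,
                            imageId = "image", channel = "") {
  thresholdMethod <- match.arg(thresholdMethod)
  if (!length(image)) stop("image is empty")
  img <- as.matrix(image)
  emptySet <- new("DropletSet",
                  droplets = data.frame(x = numeric(0), y = numeric(0),
                                        area = numeric(0),
                                        meanIntensity = numeric(0),
                                        circularity = numeric(0)),
                  imageId = imageId, channel = channel)
  if (thresholdMethod == "otsu") {
    rng <- range(img)
    if (diff(rng) == 0) return(emptySet)
    scaled <- (img - rng[1]) / diff(rng)
    th <- EBImage::otsu(EBImage::Image(scaled))
    bw <- scaled > th
  } else {
    if (is.null(threshold)) stop("fixed thresholding needs a threshold")
    if (threshold < min(img) || threshold > max(img))
      stop("fixed threshold outside image intensity range")
    bw <- img > threshold
  }
  if (!any(bw)) return(emptySet)
  lab <- EBImage::bwlabel(EBImage::Image(bw))
  shape <- EBImage::computeFeatures.shape(lab)
  mom <- EBImage::computeFeatures.moment(lab)
  area <- shape[, "s.area"]
  perim <- shape[, "s.perimeter"]
  circ <- ifelse(perim > 0, pmin(4 * pi * area / perim^2, 1), 1)
  labv <- as.integer(EBImage::imageData(lab))
  meanInt <- tapply(as.numeric(img)[labv > 0], labv[labv > 0], mean)
  bg <- as.numeric(img)[labv == 0]
  bgSd <- if (length(bg) > 1) stats::sd(bg) else 0
  contrastFloor <- if (length(bg)) mean(bg) + minContrastSd * bgSd else -Inf
  keep <- which(area >= minArea & circ >= minCircularity &
                  as.numeric(meanInt[as.character(seq_along(area))]) >=
                    contrastFloor)
  df <- data.frame(x = mom[keep, "m.cx"], y = mom[keep, "m.cy"],
                   area = area[keep],
                   meanIntensity = as.numeric(meanInt[as.character(keep)]),
                   circularity = circ[keep], row.names = NULL)
  new("DropletSet", droplets = df, imageId = imageId, channel = channel)
}

#' Fraction of droplets colocalised between two channels
#'
#' Greedy nearest-centroid matching: the globally closest unmatched pair
#' within `maxCentroidDist` is matched repeatedly, each droplet at most
#' once. Returns the matched fraction of `a`'s droplets (`NA` when `a`
#' is empty).
#'
#' @param a,b [DropletSet-class] from the same image frame.
#' @param maxCentroidDist maximum centroid distance in px.
#' @return numeric fraction in \eqn{[0, 1]}, or `NA`.
#' @export
colocalize <- function(a, b, maxCentroidDist) {
  da <- droplets(a); db <- droplets(b)
  if (!nrow(da)) return(NA_real_)
  if (!nrow(db)) return(0)
  d <- sqrt(outer(da$x, db$x, "-")^2 + outer(da$y, db$y, "-")^2)
  matched <- 0L
  while (TRUE) {
    m <- which(d == min(d), arr.ind = TRUE)
    if (!is.finite(min(d)) || min(d) > maxCentroidDist) break
    i <- m[1, 1]; j <- m[1, 2]
    matched <- matched + 1L
    d[i, ] <- Inf
    d[, j] <- Inf
    if (all(!is.finite(d))) break
  }
  matched / nrow(da)
}

.countOf <- function(x) {
  if (is(x, "DropletSet")) nrow(droplets(x)) else as.numeric(x)
}

#' Relative droplet number of a treated arm versus control
#'
#' Mean droplet count per treated image divided by mean droplet count
#' per control image (DMSO arm in a compound screen). A control arm with
#' zero mean count leaves the statistic undefined (`NA`).
#'
#' @param treated,control lists of [DropletSet-class] (or numeric
#'   per-image counts); at least one image per arm.
#' @return list with `relative`, `treatedCounts`, `controlCounts`.
#' @export
screenStatistic <- function(treated, control) {
  if (!length(treated) || !length(control))
    stop("need at least one image per arm")
  tc <- vapply(if (is.list(treated)) treated else as.list(treated),
               .countOf, numeric(1))
  cc <- vapply(if (is.list(control)) control else as.list(control),
               .countOf, numeric(1))
  rel <- if (mean(cc) == 0) NA_real_ else mean(tc) / mean(cc)
  list(relative = rel, treatedCounts = tc, controlCounts = cc)
}

#' Compound-screen table of relative droplet numbers
#'
#' @param arms named list of per-compound lists of [DropletSet-class]
#'   or counts.
#' @param control name of the control arm within `arms` (default
#'   `"DMSO"`).
#' @return data.frame with columns `compound`, `relative_number`,
#'   `n_images`; the control arm's relative number is 1 by construction.
#' @export
screenTable <- function(arms, control = "DMSO") {
  if (!control %in% names(arms)) stop("control arm not found: ", control)
  ctrl <- arms[[control]]
  df <- data.frame(
    compound = names(arms),
    relative_number = vapply(arms, function(a)
      screenStatistic(a, ctrl)$relative, numeric(1)),
    n_images = vapply(arms, length, integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  df
}

#' Xenograft tumor volume from caliper measurements
#'
#' \eqn{volume (mm^3) = length \times width \times width / 2}.
#' Measurements must be positive; a width exceeding the length is
#' computed anyway with a warning.
#'
#' @param length tumor length in mm.
#' @param width tumor width in mm.
#' @return volume in mm^3 (vectorised).
#' @export
tumorVolume <- function(length, width) {
  if (any(length <= 0) || any(width <= 0))
    stop("length and width must be positive")
  if (any(width > length))
    warning("width exceeds length; computing anyway")
  length * width * width / 2
}
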