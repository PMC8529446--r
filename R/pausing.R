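# RNA polymerase II promoter-proximal pausing: pausing index (traveling
# ratio), metagene profiles over scaled gene bodies, and binned signal
# matrices around binding sites.

.decodeCoverage <- function(track, chrom, s, e) {
  # per-base numeric coverage over [s, e] (1-based closed), zero-padded
  # outside the track
  n <- e - s + 1L
  out <- numeric(n)
  if (!chrom %in% names(track)) return(out)
  rle <- track[[chrom]]
  len <- length(rle)
  cs <- max(s, 1L)
  ce <- min(e, len)
  if (cs > ce) return(out)
  out[(cs - s + 1L):(ce - s + 1L)] <- as.numeric(rle[cs:ce])
  out
}

#' Pol II pausing index per gene
#'
#' The pausing index (traveling ratio) is the ratio of mean Pol II
#' coverage in the promoter window (TSS +/- `promoterHalfwidth` bp) to
#' mean coverage over the gene body (TSS to TES). Genes whose body is
#' shorter than twice the promoter half-width are flagged `too_short`;
#' genes with zero body coverage are flagged `undefined_body` and get an
#' `NA` index rather than infinity.
#'
#' @param genes `GRanges` gene models with `gene_id` and explicit strand.
#' @param track `RleList` Pol II coverage.
#' @param promoterHalfwidth promoter half-width in bp (default 500).
#' @return data.frame with columns `gene_id`, `promoter_mean`,
#'   `body_mean`, `pi`, `flag`.
#' @export
pausingIndex <- function(genes, track, promoterHalfwidth = 500) {
  if (promoterHalfwidth <= 0) stop("promoterHalfwidth must be positive")
  tss <- geneTSS(genes)
  plus <- as.character(strand(genes)) == "+"
  # strand-oriented window of width 2*halfwidth centered on the TSS
  prom <- GRanges(seqnames(genes),
                  IRanges(ifelse(plus, tss - promoterHalfwidth,
                                 tss - promoterHalfwidth + 1L),
                          ifelse(plus, tss + promoterHalfwidth - 1L,
                                 tss + promoterHalfwidth)))
  body <- GRanges(seqnames(genes), IRanges(start(genes), end(genes)))
  pm <- meanCoverage(track, prom)
  bm <- meanCoverage(track, body)
  flag <- rep("ok", length(genes))
  flag[width(genes) <= 2 * promoterHalfwidth] <- "too_short"
  flag[flag == "ok" & bm == 0] <- "undefined_body"
  pi <- ifelse(flag == "ok", pm / bm, NA_real_)
  data.frame(gene_id = genes$gene_id, promoter_mean = pm, body_mean = bm,
             pi = pi, flag = flag, stringsAsFactors = FALSE)
}

.binMeans <- function(v, nbins) {
  idx <- floor((seq_along(v) - 1L) * nbins / length(v)) + 1L
  as.numeric(tapply(v, idx, mean))
}

#' Metagene coverage profile over scaled gene bodies
#'
#' Each gene body is rescaled into `bodyBins` equal-width bins
#' (strand-oriented: minus-strand genes are reversed) with `flankBins`
#' fixed-width bins over `flankBp` of upstream and downstream flank.
#' Each gene's profile is normalised by the mean of its own binned
#' profile (so equally shaped genes of different lengths normalise
#' identically), and the output is the unweighted mean across genes.
#' Genes shorter than `bodyBins` bp, or with zero coverage, are skipped
#' with a message.
#'
#' @param genes `GRanges` gene models.
#' @param track `RleList` coverage.
#' @param bodyBins number of gene-body bins (default 100).
#' @param flankBp flank size in bp on each side (default 2000).
#' @param flankBins number of bins per flank (default 20).
#' @return list with `values` (length `bodyBins + 2 * flankBins`),
#'   `bodyBins`, `flankBins`, `flankBp`, `nGenes`.
#' @export
metageneProfile <- function(genes, track, bodyBins = 100, flankBp = 2000,
                            flankBins = 20) {
  if (!length(genes)) stop("no genes supplied")
  if (flankBp %% flankBins != 0)
    stop("flankBp must be divisible by flankBins")
  profiles <- list()
  skipped <- 0L
  for (i in seq_along(genes)) {
    g <- genes[i]
    if (width(g) < bodyBins) { skipped <- skipped + 1L; next }
    chrom <- as.character(seqnames(g))
    up <- .decodeCoverage(track, chrom, start(g) - flankBp, start(g) - 1L)
    body <- .decodeCoverage(track, chrom, start(g), end(g))
    down <- .decodeCoverage(track, chrom, end(g) + 1L, end(g) + flankBp)
    if (as.character(strand(g)) == "-") {
      tmp <- rev(up); up <- rev(down); down <- tmp
      body <- rev(body)
    }
    prof <- c(.binMeans(up, flankBins), .binMeans(body, bodyBins),
              .binMeans(down, flankBins))
    # normalise by the gene's mean binned coverage (flanks weighted as
    # bins, not bases, so equally shaped genes of different lengths give
    # identical normalised profiles)
    gm <- mean(prof)
    if (gm == 0) { skipped <- skipped + 1L; next }
    profiles[[length(profiles) + 1L]] <- prof / gm
  }
  if (skipped)
    message(skipped, " gene(s) skipped (too short or zero coverage)")
  if (!length(profiles)) stop("no genes usable for metagene profile")
  values <- colMeans(do.call(rbind, profiles))
  list(values = values, bodyBins = bodyBins, flankBins = flankBins,
       flankBp = flankBp, nGenes = length(profiles))
}

#' Binned signal matrix around interval centers
#'
#' Row i is the binned mean coverage over
#' `[center_i - window, center_i + window)`; row order follows the input.
#'
#' @param centers `GRanges` (midpoints are used) or integer positions
#'   with `chrom` supplied.
#' @param track `RleList` coverage.
#' @param window half-window in bp; must be divisible by `bin`.
#' @param bin bin width in bp.
#' @param chrom chromosome names when `centers` is a position vector.
#' @return numeric matrix, one row per center, `2 * window / bin`
#'   columns.
#' @export
signalMatrix <- function(centers, track, window, bin, chrom = NULL) {
  if (window %% bin != 0) stop("window must be divisible by bin")
  if (is(centers, "GRanges")) {
    chrom <- as.character(seqnames(centers))
    pos <- (start(centers) + end(centers)) %/% 2L
  } else {
    pos <- as.integer(centers)
    if (is.null(chrom)) stop("chrom required for position-vector centers")
    if (length(chrom) == 1L) chrom <- rep(chrom, length(pos))
  }
  nb <- as.integer(2 * window / bin)
  binStarts <- seq(-window, window - bin, by = bin)
  m <- matrix(0, nrow = length(pos), ncol = nb)
  for (i in seq_along(pos)) {
    gr <- GRanges(chrom[i], IRanges(pos[i] + binStarts,
                                    pos[i] + binStarts + bin - 1L))
    m[i, ] <- meanCoverage(track, gr)
  }
  m
}

#' Write pausing-index table
#'
#' @param piTable data.frame from [pausingIndex()].
#' @param path output TSV path.
#' @export
writePausingTable <- function(piTable, path) {
  write.table(piTable, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
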