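#' @import methods
#' @importFrom S4Vectors mcols mcols<- DataFrame
#' @importFrom GenomicRanges GRanges
NULL

#' Position weight matrix record
#'
#' A JASPAR-style position frequency matrix together with the pseudocount
#' and background model used to turn it into log-odds scores.
#'
#' @slot tfName transcription factor name the motif belongs to.
#' @slot profile 4 x L numeric matrix of base frequencies (rows A, C, G, T).
#' @slot pseudocount positive pseudocount added (background-weighted) when
#'   normalising columns to probabilities.
#' @slot background numeric(4) background base probabilities, summing to 1.
#' @export
setClass("PWMRecord",
  representation(
    tfName = "character",
    profile = "matrix",
    pseudocount = "numeric",
    background = "numeric"
  )
)

setValidity("PWMRecord", function(object) {
  msg <- NULL
  m <- object@profile
  if (nrow(m) != 4L) msg <- c(msg, "profile must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4L) msg <- c(msg, "motif length must be >= 4")
  if (any(m < 0)) msg <- c(msg, "profile entries must be non-negative")
  if (any(colSums(m) <= 0)) msg <- c(msg, "each profile column must have positive sum")
  if (length(object@background) != 4L || abs(sum(object@background) - 1) > 1e-6)
    msg <- c(msg, "background must be 4 probabilities summing to 1")
  if (length(object@pseudocount) != 1L || object@pseudocount <= 0)
    msg <- c(msg, "pseudocount must be a single positive number")
  if (is.null(msg)) TRUE else msg
})

#' Scaled signal-vs-rank curve with slope-1 cutoff
#'
#' Holds the enhancer rank curve used to separate super-enhancers from
#' typical enhancers: region signals sorted ascending, both axes scaled to
#' \eqn{[0, 1]}, and the index/height where the discrete slope of the curve
#' first exceeds 1 and stays above 1.
#'
#' @slot signal numeric, region signals sorted ascending.
#' @slot scaledRank numeric in \eqn{[0,1]}, \eqn{(i-1)/(n-1)}.
#' @slot scaledSignal numeric in \eqn{[0,1]}, signal divided by its maximum.
#' @slot cutoffIndex integer index of the cutoff on the sorted curve, or
#'   `NA` when the curve is degenerate or the slope never exceeds 1.
#' @slot cutoffSignal scaled signal at `cutoffIndex`, or `NA`.
#' @export
setClass("SERankCurve",
  representation(
    signal = "numeric",
    scaledRank = "numeric",
    scaledSignal = "numeric",
    cutoffIndex = "integer",
    cutoffSignal = "numeric"
  )
)

#' Super-enhancer call set
#'
#' Result of [callSuperEnhancers()]: stitched enhancer regions labelled
#' SE or TE, with ranks, total signal, and nearest-TSS gene assignments,
#' plus the rank curve the cutoff was derived from.
#'
#' @slot calls `GRanges` of stitched regions with metadata columns
#'   `totalSignal`, `rank` (1 = highest signal), `label` ("SE"/"TE"),
#'   `assignedGene`, and `nConstituents`.
#' @slot curve the [SERankCurve-class] used for classification.
#' @export
setClass("SECallSet",
  representation(calls = "GRanges", curve = "SERankCurve")
)

#' Directed TF-to-TF circuitry graph
#'
#' Nodes are SE-driven transcription factors; a directed edge (u, v) means
#' at least one motif hit of u's PWM inside a super-enhancer assigned to
#' v's gene. IN degree of v counts distinct regulators (self included);
#' OUT degree of u counts distinct targets.
#'
#' @slot nodes character vector of TF gene ids.
#' @slot edges data.frame with columns `source`, `target`, `n_hits`,
#'   `best_score`.
#' @slot inDegree named integer vector over nodes.
#' @slot outDegree named integer vector over nodes.
#' @export
setClass("CircuitGraph",
  representation(
    nodes = "character",
    edges = "data.frame",
    inDegree = "integer",
    outDegree = "integer"
  )
)

setValidity("CircuitGraph", function(object) {
  msg <- NULL
  e <- object@edges
  if (!all(c("source", "target") %in% names(e)))
    msg <- c(msg, "edges must have 'source' and 'target' columns")
  else {
    if (!all(e$source %in% object@nodes) || !all(e$target %in% object@nodes))
      msg <- c(msg, "edge endpoints must be nodes")
    indeg <- vapply(object@nodes, function(v)
      length(unique(e$source[e$target == v])), integer(1))
    outdeg <- vapply(object@nodes, function(v)
      length(unique(e$target[e$source == v])), integer(1))
    if (!identical(unname(object@inDegree), unname(indeg)))
      msg <- c(msg, "inDegree inconsistent with edge set")
    if (!identical(unname(object@outDegree), unname(outdeg)))
      msg <- c(msg, "outDegree inconsistent with edge set")
  }
  if (is.null(msg)) TRUE else msg
})

#' Dyad density profile around motif centers
#'
#' Per-base counts of mono-nucleosome fragment midpoints (dyads) at signed
#' offsets relative to aligned motif centers (minus-strand motifs flipped).
#'
#' @slot offsets integer offsets `-window .. window` in bp.
#' @slot counts numeric dyad counts per offset, pooled over motifs.
#' @slot nMotifs number of motif centers aggregated.
#' @slot nFragments number of fragments supplied.
#' @export
setClass("DyadDensityProfile",
  representation(
    offsets = "integer",
    counts = "numeric",
    nMotifs = "integer",
    nFragments = "integer"
  )
)

#' Fitted FRAP recovery parameters
#'
#' Single-exponential recovery fit
#' \eqn{I(t) = floor + (plateau - floor)(1 - e^{-kt})} on the
#' double-normalised post-bleach curve.
#'
#' @slot plateau asymptotic normalised intensity.
#' @slot rate recovery rate k (per second).
#' @slot postBleachFloor normalised intensity immediately after bleach.
#' @slot mobileFraction (plateau - floor) / (1 - floor).
#' @slot tHalf half-time of recovery, ln(2)/k, seconds.
#' @slot converged whether the least-squares fit converged.
#' @slot message diagnostic message for non-converged fits.
#' @export
setClass("FRAPFit",
  representation(
    plateau = "numeric",
    rate = "numeric",
    postBleachFloor = "numeric",
    mobileFraction = "numeric",
    tHalf = "numeric",
    converged = "logical",
    message = "character"
  )
)

#' Segmented droplet set
#'
#' Droplets segmented from one grayscale image: centroid, area, mean
#' intensity and circularity per droplet.
#'
#' @slot droplets data.frame with columns `x`, `y` (centroid, px),
#'   `area` (px^2), `meanIntensity`, `circularity` in (0, 1].
#' @slot imageId identifier of the source image.
#' @slot channel channel label.
#' @export
setClass("DropletSet",
  representation(droplets = "data.frame", imageId = "character",
                 channel = "character")
)
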