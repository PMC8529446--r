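# ROSE-style super-enhancer identification: TSS exclusion, stitching,
# rank-curve inflection, SE/TE classification and gene assignment.

#' Remove TSS-proximal peaks
#'
#' Drops peaks whose center lies within `radius` bp (inclusive) of any
#' gene TSS on the same chromosome; all other peaks pass unchanged. With
#' no genes the filter is vacuous. The peak center is used because
#' histone peaks carry no summit in this pipeline.
#'
#' @param peaks `GRanges` peaks.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param radius exclusion radius in bp (default 2500).
#' @return filtered `GRanges`.
#' @export
excludeTssProximal <- function(peaks, genes, radius = 2500) {
  if (length(radius) != 1L || radius < 0) stop("radius must be >= 0")
  if (!length(peaks) || !length(genes)) return(peaks)
  centers <- start(peaks) + width(peaks) %/% 2L
  pchrom <- as.character(seqnames(peaks))
  gchrom <- as.character(seqnames(genes))
  tss <- geneTSS(genes)
  keep <- rep(TRUE, length(peaks))
  for (chr in unique(pchrom)) {
    ti <- sort(tss[gchrom == chr])
    if (!length(ti)) next
    pi <- which(pchrom == chr)
    j <- findInterval(centers[pi], ti)
    dLeft <- ifelse(j >= 1L, centers[pi] - ti[pmax(j, 1L)], Inf)
    dRight <- ifelse(j < length(ti), ti[pmin(j + 1L, length(ti))] - centers[pi], Inf)
    keep[pi] <- pmin(dLeft, dRight) > radius
  }
  peaks[keep]
}

#' Stitch enhancer peaks into candidate regions
#'
#' Merges TSS-filtered peaks within `gap` bp of one another (see
#' [mergeWithinGap()]) and records the constituent peaks and summed
#' signal per stitched region.
#'
#' @param peaks `GRanges` with `signal` (TSS-filtered).
#' @param gap maximum stitching distance in bp (default 12500).
#' @return `GRanges` of stitched regions with `totalSignal`,
#'   `nConstituents` and `revmap` metadata columns.
#' @export
stitchPeaks <- function(peaks, gap = 12500) {
  merged <- mergeWithinGap(peaks, gap)
  names(mcols(merged))[names(mcols(merged)) == "signal"] <- "totalSignal"
  merged
}

#' Slope-1 inflection point of the scaled rank curve
#'
#' Signals are sorted ascending; ranks are scaled to \eqn{[0, 1]} by
#' \eqn{(i-1)/(n-1)} and signals by division by the maximum. The discrete
#' slope at each index is the central difference of scaled signal over
#' scaled rank (one-sided at the ends). The cutoff is the smallest index
#' at which the slope exceeds 1 and stays above 1 at every later index —
#' the guard prevents noise spikes below the elbow from creating a
#' premature cutoff. Regions with scaled signal strictly above the cutoff
#' signal are super-enhancers; an all-equal signal vector has no cutoff
#' and yields no super-enhancers.
#'
#' @param signals numeric vector of non-negative region signals.
#' @return [SERankCurve-class].
#' @export
findInflection <- function(signals) {
  if (any(is.na(signals)) || any(signals < 0))
    stop("signals must be non-negative and non-missing")
  s <- sort(signals)
  n <- length(s)
  noCut <- function() new("SERankCurve", signal = s,
                          scaledRank = if (n > 1) (seq_len(n) - 1) / (n - 1) else rep(0, n),
                          scaledSignal = if (n && max(s) > 0) s / max(s) else s,
                          cutoffIndex = NA_integer_, cutoffSignal = NA_real_)
  if (n < 2L || length(unique(s)) < 2L) return(noCut())
  x <- (seq_len(n) - 1) / (n - 1)
  y <- s / max(s)
  slope <- numeric(n)
  slope[1] <- (y[2] - y[1]) / (x[2] - x[1])
  slope[n] <- (y[n] - y[n - 1]) / (x[n] - x[n - 1])
  if (n > 2L) {
    i <- 2:(n - 1)
    slope[i] <- (y[i + 1] - y[i - 1]) / (x[i + 1] - x[i - 1])
  }
  # slope > 1 here and at every later index
  persistent <- rev(cumprod(rev(slope > 1))) > 0
  if (!any(persistent)) return(noCut())
  ci <- which(persistent)[1]
  new("SERankCurve", signal = s, scaledRank = x, scaledSignal = y,
      cutoffIndex = as.integer(ci), cutoffSignal = y[ci])
}

#' Call super-enhancers from H3K27ac peaks
#'
#' Full ROSE-style composition: TSS-proximal peaks are excluded
#' (default radius 2.5 kb), the survivors stitched within 12.5 kb,
#' regions scored by the sum of constituent peak signals (or re-scored as
#' mean track coverage times region length when a coverage track is
#' supplied), and the slope-1 inflection of the scaled rank curve
#' separates super-enhancers (strictly above the cutoff) from typical
#' enhancers. Every region is assigned the gene with the TSS nearest its
#' midpoint.
#'
#' @param peaks `GRanges` H3K27ac peaks with `signal`.
#' @param genes `GRanges` gene models with `gene_id`.
#' @param track optional `RleList` coverage track for region re-scoring.
#' @param gap stitching distance in bp (default 12500).
#' @param tssRadius TSS exclusion radius in bp (default 2500).
#' @return [SECallSet-class].
#' @export
callSuperEnhancers <- function(peaks, genes, track = NULL,
                               gap = 12500, tssRadius = 2500) {
  filtered <- excludeTssProximal(peaks, genes, tssRadius)
  st <- stitchPeaks(filtered, gap)
  if (!length(st)) {
    calls <- GRanges()
    calls$totalSignal <- numeric(0)
    calls$nConstituents <- integer(0)
    calls$rank <- integer(0)
    calls$label <- character(0)
    calls$assignedGene <- character(0)
    return(new("SECallSet", calls = calls, curve = findInflection(numeric(0))))
  }
  if (!is.null(track))
    st$totalSignal <- meanCoverage(track, st) * width(st)
  curve <- findInflection(st$totalSignal)
  cutoff <- curve@cutoffSignal
  smax <- max(st$totalSignal)
  scaled <- if (smax > 0) st$totalSignal / smax else st$totalSignal
  label <- if (is.na(cutoff)) rep("TE", length(st)) else
    ifelse(scaled > cutoff, "SE", "TE")
  # rank 1 = highest signal; deterministic tie-break by coordinate
  ord <- order(-st$totalSignal, as.character(seqnames(st)), start(st))
  rank <- integer(length(st))
  rank[ord] <- seq_along(ord)
  mids <- start(st) + width(st) %/% 2L
  assigned <- nearestTSS(as.character(seqnames(st)), mids, genes)$gene_id
  st$rank <- rank
  st$label <- label
  st$assignedGene <- assigned
  mcols(st)$revmap <- NULL
  new("SECallSet", calls = st, curve = curve)
}

#' Base-pair Jaccard overlap of two SE sets
#'
#' Jaccard index of the merged base-pair sets of the SE-labelled regions
#' of two call sets: intersection bp over union bp. Two empty sets have
#' Jaccard 0 by convention.
#'
#' @param a,b [SECallSet-class] objects or `GRanges`.
#' @return numeric in \eqn{[0, 1]}.
#' @export
seOverlapJaccard <- function(a, b) {
  grA <- if (is(a, "SECallSet")) a@calls[a@calls$label == "SE"] else a
  grB <- if (is(b, "SECallSet")) b@calls[b@calls$label == "SE"] else b
  grA <- reduce(grA, ignore.strand = TRUE)
  grB <- reduce(grB, ignore.strand = TRUE)
  if (!length(grA) && !length(grB)) return(0)
  inter <- sum(width(GenomicRanges::intersect(grA, grB, ignore.strand = TRUE)))
  uni <- sum(width(reduce(c(grA, grB), ignore.strand = TRUE)))
  if (uni == 0) 0 else inter / uni
}

#' Write SE table and rank curve
#'
#' Emits the tab-separated SE table (0-based half-open coordinates) and a
#' two-column rank-curve TSV for plotting.
#'
#' @param x [SECallSet-class].
#' @param dir output directory (created if needed).
#' @return invisibly, the two file paths.
#' @export
writeSETable <- function(x, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  calls <- x@calls
  tab <- data.frame(chrom = as.character(seqnames(calls)),
                    start = start(calls) - 1L, end = end(calls),
                    rank = calls$rank,
                    total_signal = calls$totalSignal,
                    label = calls$label,
                    assigned_gene = calls$assignedGene)
  tab <- tab[order(tab$rank), ]
  f1 <- file.path(dir, "se_table.tsv")
  write.table(tab, f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "rank_curve.tsv")
  write.table(data.frame(scaled_rank = x@curve@scaledRank,
                         scaled_signal = x@curve@scaledSignal),
              f2, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(f1, f2))
}
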