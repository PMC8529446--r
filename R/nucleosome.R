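# ATAC-seq nucleosome phasing: mono-nucleosome fragment selection and
# nucleosome-spacing estimation from dyad density around motif centers.
# Fragment coordinates follow the fragment-file convention (0-based
# half-open); the dyad is the fragment midpoint with floor rounding.

#' Read paired-end fragments from BEDPE or fragment TSV
#'
#' Accepts a 3-column fragment table (chrom, start, end; 0-based
#' half-open) or 6+-column BEDPE (both mates on one chromosome; the
#' fragment spans the outermost coordinates).
#'
#' @param path input file.
#' @return data.frame with columns `chrom`, `start`, `end`, `length`.
#' @export
readFragments <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   stringsAsFactors = FALSE)
  if (ncol(df) >= 6 && is.character(df[[4]])) {
    if (any(df[[1]] != df[[4]]))
      stop("inter-chromosomal BEDPE records are not fragments")
    out <- data.frame(chrom = df[[1]],
                      start = pmin(df[[2]], df[[5]]),
                      end = pmax(df[[3]], df[[6]]),
                      stringsAsFactors = FALSE)
  } else {
    out <- data.frame(chrom = df[[1]], start = df[[2]], end = df[[3]],
                      stringsAsFactors = FALSE)
  }
  out$length <- out$end - out$start
  if (any(out$length <= 0)) stop("fragments must have positive length")
  out
}

#' Select mono-nucleosome-sized fragments
#'
#' Retains fragments with `minLen <= length <= maxLen`, both bounds
#' inclusive (defaults 180 and 247 bp).
#'
#' @param fragments data.frame from [readFragments()].
#' @param minLen,maxLen inclusive length bounds in bp.
#' @return filtered data.frame.
#' @export
filterMononucleosome <- function(fragments, minLen = 180, maxLen = 247) {
  if (minLen <= 0 || maxLen <= 0 || minLen > maxLen)
    stop("need 0 < minLen <= maxLen")
  len <- fragments$end - fragments$start
  fragments[len >= minLen & len <= maxLen, , drop = FALSE]
}

#' Dyad density around motif centers
#'
#' The dyad of a fragment is its midpoint, `floor((start + end) / 2)`.
#' For each motif center, dyads within +/- `window` bp accumulate at
#' offset `dyad - center`, with the sign flipped for minus-strand motifs
#' so that upstream/downstream are motif-oriented. Counts are pooled
#' over motifs.
#'
#' @param fragments data.frame of (filtered) fragments.
#' @param motifs data.frame with columns `chrom`, `pos` (center
#'   coordinate) and optional `strand` (`+`/`-`, default `+`).
#' @param window half-window in bp (default 1000).
#' @return [DyadDensityProfile-class].
#' @export
dyadDensity <- function(fragments, motifs, window = 1000) {
  if (is.null(motifs) || !nrow(motifs)) stop("no motif centers supplied")
  if (is.null(motifs$strand)) motifs$strand <- "+"
  offsets <- seq(-window, window)
  counts <- numeric(length(offsets))
  if (nrow(fragments)) {
    dyad <- (fragments$start + fragments$end) %/% 2L
    for (chr in unique(motifs$chrom)) {
      d <- sort(dyad[fragments$chrom == chr])
      if (!length(d)) next
      mi <- which(motifs$chrom == chr)
      for (k in mi) {
        lo <- findInterval(motifs$pos[k] - window - 1L, d) + 1L
        hi <- findInterval(motifs$pos[k] + window, d)
        if (lo > hi) next
        off <- d[lo:hi] - motifs$pos[k]
        if (motifs$strand[k] == "-") off <- -off
        keep <- abs(off) <= window
        counts <- counts + tabulate(off[keep] + window + 1L,
                                    nbins = length(offsets))
      }
    }
  }
  new("DyadDensityProfile", offsets = as.integer(offsets), counts = counts,
      nMotifs = nrow(motifs), nFragments = nrow(fragments))
}

#' Nucleosome spacing from a dyad density profile
#'
#' Counts are smoothed with a centered moving average of width
#' `smoothBp`; the upstream peak is the argmax over offsets strictly
#' below `-exclusion` and the downstream peak the argmax strictly above
#' `+exclusion` (the excluded center masks the nucleosome-free region at
#' the motif itself). Ties pick the offset of smallest absolute value.
#' Spacing is downstream minus upstream peak offset. A side with no
#' signal leaves the spacing undefined and flagged.
#'
#' @param profile [DyadDensityProfile-class].
#' @param exclusion central exclusion half-width in bp (default 30).
#' @param smoothBp moving-average width in bp, odd (default 11); 1
#'   disables smoothing.
#' @return list with `upOffset`, `downOffset`, `spacing`, `flag`
#'   ("ok" or "undefined"), and `smoothed` counts.
#' @export
nucleosomeSpacing <- function(profile, exclusion = 30, smoothBp = 11) {
  if (smoothBp %% 2 != 1 || smoothBp < 1) stop("smoothBp must be odd and >= 1")
  counts <- profile@counts
  offsets <- profile@offsets
  sm <- if (smoothBp > 1) {
    as.numeric(stats::filter(counts, rep(1 / smoothBp, smoothBp), sides = 2))
  } else counts
  pick <- function(side) {
    idx <- which(!is.na(sm) & side)
    if (!length(idx) || all(sm[idx] == 0)) return(NA_integer_)
    best <- idx[sm[idx] == max(sm[idx])]
    # smoothing flattens an isolated spike into a tied plateau: prefer the
    # raw-count maximum within the tie, then the smallest absolute offset
    best[order(-counts[best], abs(offsets[best]))][1]
  }
  iUp <- pick(offsets < -exclusion)
  iDown <- pick(offsets > exclusion)
  if (is.na(iUp) || is.na(iDown)) {
    return(list(upOffset = NA_integer_, downOffset = NA_integer_,
                spacing = NA_integer_, flag = "undefined", smoothed = sm))
  }
  list(upOffset = offsets[iUp], downOffset = offsets[iDown],
       spacing = offsets[iDown] - offsets[iUp], flag = "ok", smoothed = sm)
}

#' Write dyad profile and spacing summary
#'
#' @param profile [DyadDensityProfile-class].
#' @param spacing result of [nucleosomeSpacing()].
#' @param dir output directory.
#' @return invisibly, the written paths.
#' @export
writeNucleosomeOutputs <- function(profile, spacing, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f1 <- file.path(dir, "dyad_profile.tsv")
  write.table(data.frame(offset = profile@offsets,
                         raw_count = profile@counts,
                         smoothed = spacing$smoothed),
              f1, sep = "\t", quote = FALSE, row.names = FALSE)
  f2 <- file.path(dir, "spacing.json")
  jsonlite::write_json(spacing[c("upOffset", "downOffset", "spacing", "flag")],
                       f2, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(c(f1, f2))
}
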