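#' @importFrom GenomicRanges GRanges reduce seqnames start end width strand
#'   countOverlaps
#' @importFrom IRanges IRanges Views viewSums
#' @importFrom GenomeInfoDb seqlevels seqlengths
#' @importFrom S4Vectors Rle runValue queryHits subjectHits
#' @importFrom utils read.table write.table head tail
NULL

# ---- peak I/O -------------------------------------------------------------

.parseNumeric <- function(x, what, lineno) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) & !is.na(x))
  if (length(bad))
    stop(sprintf("parse error at line %d: non-numeric %s '%s'",
                 lineno[bad[1]], what, x[bad[1]]), call. = FALSE)
  v
}

#' Read peak calls from BED or narrowPeak files
#'
#' Reads BED3/BED6 or ENCODE 10-column narrowPeak into a `GRanges` with
#' metadata columns `name` and `signal`. File coordinates are 0-based
#' half-open and converted to the 1-based closed convention `GRanges`
#' uses. For narrowPeak the `signalValue` column (column 7) populates
#' `signal`; for BED with at least 5 columns the score column does; BED
#' with fewer columns gets signal 0. Peaks are returned sorted by
#' (chrom, start).
#'
#' @param path path to the peak file.
#' @param format `"BED"` or `"narrowPeak"`.
#' @return `GRanges` with `name` and `signal` metadata columns.
#' @export
readPeaks <- function(path, format = c("BED", "narrowPeak")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines)) {
    return(GRanges(name = character(0), signal = numeric(0)))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  minCols <- if (format == "narrowPeak") 10L else 3L
  if (any(nf < minCols))
    stop(sprintf("parse error at line %d: expected >= %d tab-separated columns, found %d",
                 lineno[which(nf < minCols)[1]], minCols, nf[which(nf < minCols)[1]]),
         call. = FALSE)
  col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_,
                            character(1))
  chrom <- col(1)
  start0 <- .parseNumeric(col(2), "start", lineno)
  end0 <- .parseNumeric(col(3), "end", lineno)
  bad <- which(start0 >= end0 | start0 < 0)
  if (length(bad))
    stop(sprintf("validation error at line %d: need 0 <= start < end, got [%s, %s)",
                 lineno[bad[1]], col(2)[bad[1]], col(3)[bad[1]]), call. = FALSE)
  nm <- col(4)
  nm[is.na(nm) | nm == "."] <- sprintf("peak_%d", which(is.na(nm) | nm == "."))
  str <- col(6)
  str[is.na(str) | !str %in% c("+", "-")] <- "*"
  signal <- if (format == "narrowPeak") {
    .parseNumeric(col(7), "signalValue", lineno)
  } else if (all(nf >= 5L)) {
    .parseNumeric(col(5), "score", lineno)
  } else rep(0, length(chrom))
  if (any(signal < 0))
    stop(sprintf("validation error at line %d: negative signal",
                 lineno[which(signal < 0)[1]]), call. = FALSE)
  gr <- GRanges(chrom, IRanges(start0 + 1, end0), strand = str,
                name = nm, signal = signal)
  gr[order(as.character(seqnames(gr)), start(gr))]
}

#' Write peaks to BED6 or narrowPeak
#'
#' Inverse of [readPeaks()]: emits tab-separated, newline-terminated
#' records with 0-based half-open coordinates. BED6 stores the signal in
#' the score column; narrowPeak stores it in `signalValue` with the
#' unused statistics columns set to -1.
#'
#' @param peaks `GRanges` with `name` and `signal` metadata columns.
#' @param path output path.
#' @param format `"BED"` or `"narrowPeak"`.
#' @export
writePeaks <- function(peaks, path, format = c("BED", "narrowPeak")) {
  format <- match.arg(format)
  str <- as.character(strand(peaks))
  str[str == "*"] <- "."
  df <- data.frame(chrom = as.character(seqnames(peaks)),
                   start = start(peaks) - 1L, end = end(peaks),
                   name = peaks$name, stringsAsFactors = FALSE)
  if (format == "BED") {
    df$score <- peaks$signal
    df$strand <- str
  } else {
    df$score <- 0L
    df$strand <- str
    df$signalValue <- peaks$signal
    df$pValue <- -1
    df$qValue <- -1
    df$peak <- -1L
  }
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# ---- signal tracks --------------------------------------------------------

#' Read a bedGraph coverage track
#'
#' Imports a 4-column bedGraph via `rtracklayer` and converts it to a
#' per-chromosome run-length list (`RleList`). Uncovered positions have
#' value 0.
#'
#' @param path bedGraph file path.
#' @return `RleList` keyed by chromosome.
#' @export
readBedGraphTrack <- function(path) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  if (any(gr$score < 0)) stop("negative coverage in bedGraph: ", path)
  GenomicRanges::coverage(gr, weight = "score")
}

#' Write a signal track as bedGraph
#'
#' @param track `RleList` as produced by [readBedGraphTrack()] or
#'   [makeSignalTrack()].
#' @param path output path.
#' @export
writeBedGraphTrack <- function(track, path) {
  gr <- as(track, "GRanges")
  gr <- gr[gr$score != 0]
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Build a signal track from interval/value pairs
#'
#' Convenience constructor (used heavily by the simulators and tests):
#' takes a `GRanges` with a `score` column and returns the corresponding
#' coverage `RleList`, with values added where intervals overlap.
#'
#' @param gr `GRanges` with numeric `score`.
#' @param seqlen optional named vector of chromosome lengths.
#' @return `RleList`.
#' @export
makeSignalTrack <- function(gr, seqlen = NULL) {
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqlengths(gr) <- seqlen
  }
  GenomicRanges::coverage(gr, weight = "score")
}

#' Mean per-base coverage over intervals
#'
#' Sum of per-base coverage over each query interval divided by its
#' length. Positions outside the track (unknown chromosome, or beyond the
#' covered end) count as 0, so fully uncovered intervals return 0.
#'
#' @param track `RleList` signal track.
#' @param gr `GRanges` query intervals.
#' @return numeric vector, one mean per query interval.
#' @export
meanCoverage <- function(track, gr) {
  if (any(width(gr) <= 0)) stop("query intervals must have positive width")
  out <- numeric(length(gr))
  chroms <- as.character(seqnames(gr))
  for (chr in unique(chroms)) {
    idx <- which(chroms == chr)
    if (!chr %in% names(track)) next
    rle <- track[[chr]]
    len <- length(rle)
    s <- pmax(start(gr)[idx], 1L)
    e <- pmin(end(gr)[idx], len)
    ok <- s <= e
    if (any(ok)) {
      v <- Views(rle, start = s[ok], end = e[ok])
      sums <- viewSums(v)
      out[idx[ok]] <- sums / width(gr)[idx[ok]]
    }
  }
  out
}

# ---- peak merging ---------------------------------------------------------

#' Merge peaks separated by at most a gap
#'
#' Coordinate-sorted peaks on the same chromosome whose separation
#' (end of the previous peak to start of the next, half-open sense) is
#' less than or equal to `gap` bp are replaced by one spanning interval;
#' a separation exactly equal to `gap` merges. The merged region's
#' `signal` is the sum of its constituents' signals, and `revmap` records
#' constituent indices.
#'
#' @param peaks `GRanges` with a `signal` metadata column (missing signal
#'   treated as 0).
#' @param gap maximum separation in bp (>= 0).
#' @return `GRanges` with metadata columns `signal`, `nConstituents` and
#'   `revmap` (IntegerList of constituent peak indices).
#' @export
mergeWithinGap <- function(peaks, gap) {
  if (length(gap) != 1L || is.na(gap) || gap < 0)
    stop("gap must be a single non-negative number")
  if (!length(peaks)) {
    out <- GRanges()
    out$signal <- numeric(0)
    out$nConstituents <- integer(0)
    out$revmap <- IRanges::IntegerList()
    return(out)
  }
  sig <- peaks$signal
  if (is.null(sig)) sig <- rep(0, length(peaks))
  merged <- reduce(peaks, min.gapwidth = gap + 1L, ignore.strand = TRUE,
                   with.revmap = TRUE)
  merged$signal <- vapply(merged$revmap, function(i) sum(sig[i]), numeric(1))
  merged$nConstituents <- lengths(merged$revmap)
  merged
}

# ---- gene models ----------------------------------------------------------

#' Read gene-level models from a GTF file
#'
#' Imports a GTF via `rtracklayer` (1-based inclusive coordinates, kept
#' as such in the returned `GRanges`), keeps `gene` records (or, when the
#' file carries no `gene` rows, collapses records per `gene_id` to their
#' span) and requires an explicit strand for every gene.
#'
#' @param path GTF file path.
#' @return `GRanges` with a `gene_id` column; TSS/TES derivable via
#'   [geneTSS()]/[geneTES()].
#' @export
readGeneModels <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("type" %in% names(mcols(gr)) && any(gr$type == "gene"))
    gr <- gr[gr$type == "gene"]
  if (is.null(gr$gene_id) || anyNA(gr$gene_id))
    stop("GTF records lack gene_id attributes: ", path)
  if (any(!as.character(strand(gr)) %in% c("+", "-")))
    stop("gene models require explicit +/- strand")
  out <- GRanges(seqnames(gr), IRanges(start(gr), end(gr)),
                 strand = strand(gr), gene_id = gr$gene_id)
  out[order(as.character(seqnames(out)), start(out))]
}

#' Write gene models as gene-level GTF
#'
#' @param genes `GRanges` with `gene_id`.
#' @param path output path.
#' @export
writeGeneModels <- function(genes, path) {
  attrs <- sprintf('gene_id "%s";', genes$gene_id)
  df <- data.frame(as.character(seqnames(genes)), "circuitSE", "gene",
                   start(genes), end(genes), ".",
                   as.character(strand(genes)), ".", attrs)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Transcription start / termination sites
#'
#' For a plus-strand gene the TSS is its leftmost base and the TES its
#' rightmost; for a minus-strand gene the reverse.
#'
#' @param genes `GRanges` with explicit strand.
#' @return integer vector of positions (1-based).
#' @export
geneTSS <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", start(genes), end(genes))
}

#' @rdname geneTSS
#' @export
geneTES <- function(genes) {
  ifelse(as.character(strand(genes)) == "+", end(genes), start(genes))
}

#' Nearest TSS to genomic positions
#'
#' For each query position, the gene whose TSS minimises the absolute
#' distance, with ties broken by lexicographically smallest `gene_id`.
#' The signed distance convention is TSS - position.
#'
#' @param chrom character vector of chromosomes.
#' @param pos integer vector of positions (same length).
#' @param genes `GRanges` gene models with `gene_id`.
#' @return data.frame with columns `gene_id` ("unassigned" when the
#'   chromosome carries no gene) and `distance` (NA when unassigned).
#' @export
nearestTSS <- function(chrom, pos, genes) {
  stopifnot(length(chrom) == length(pos))
  gchrom <- as.character(seqnames(genes))
  tss <- geneTSS(genes)
  ids <- genes$gene_id
  out_id <- rep("unassigned", length(pos))
  out_d <- rep(NA_real_, length(pos))
  for (chr in unique(chrom)) {
    qi <- which(chrom == chr)
    gi <- which(gchrom == chr)
    if (!length(gi)) next
    # order candidate genes by (|distance|, gene_id) per query
    for (q in qi) {
      d <- tss[gi] - pos[q]
      best <- gi[order(abs(d), ids[gi])][1]
      out_id[q] <- ids[best]
      out_d[q] <- tss[best] - pos[q]
    }
  }
  data.frame(gene_id = out_id, distance = out_d, stringsAsFactors = FALSE)
}

# ---- PFM I/O --------------------------------------------------------------

#' Read JASPAR-style position frequency matrices
#'
#' Parses a text file of one or more records of the form
#' \preformatted{>MA0000.1 TFNAME
#' A [ 10  2  0 ... ]
#' C [  1  8  0 ... ]
#' G [ ... ]
#' T [ ... ]}
#' (the base letters and brackets are optional). The TF name is the last
#' token of the header line.
#'
#' @param path PFM file path.
#' @param pseudocount pseudocount stored on each record (default 1).
#' @param background background base probabilities (default uniform).
#' @return named list of [PWMRecord-class] objects.
#' @export
readPFM <- function(path, pseudocount = 1, background = rep(0.25, 4)) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' headers found in PFM file: ", path)
  out <- list()
  bounds <- c(hdr, length(lines) + 1L)
  for (i in seq_along(hdr)) {
    block <- lines[(bounds[i] + 1L):(bounds[i + 1L] - 1L)]
    if (length(block) != 4L)
      stop("PFM record must have 4 matrix rows: ", lines[hdr[i]])
    toks <- strsplit(sub("^>", "", lines[hdr[i]]), "\\s+")[[1]]
    tf <- toks[length(toks)]
    rows <- lapply(block, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("\\[|\\]", "", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    if (length(unique(lengths(rows))) != 1L)
      stop("ragged PFM rows for ", tf)
    m <- do.call(rbind, rows)
    rownames(m) <- c("A", "C", "G", "T")
    out[[tf]] <- new("PWMRecord", tfName = tf, profile = m,
                     pseudocount = pseudocount, background = background)
  }
  out
}

#' Write PWM records in JASPAR-style text
#'
#' @param pwms list of [PWMRecord-class].
#' @param path output path.
#' @export
writePFM <- function(pwms, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p@tfName), con)
    for (b in c("A", "C", "G", "T")) {
      writeLines(sprintf("%s [ %s ]", b,
                         paste(format(p@profile[b, ], trim = TRUE),
                               collapse = " ")), con)
    }
  }
  invisible(path)
}
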