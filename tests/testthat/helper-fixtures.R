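suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(Biostrings)
})

# track from (chrom, start, end, value) rows, 1-based closed coordinates
trackFromRows <- function(...) {
  rows <- list(...)
  gr <- do.call(c, lapply(rows, function(r)
    GRanges(r[[1]], IRanges(as.integer(r[[2]]), as.integer(r[[3]])),
            score = as.numeric(r[[4]]))))
  makeSignalTrack(gr)
}

peaksGR <- function(chrom, start, end, signal = 0,
                    name = sprintf("p%d", seq_along(start)),
                    strand = "*") {
  GRanges(chrom, IRanges(start, end), strand = strand,
          name = name, signal = signal)
}

genesGR <- function(chrom, start, end, strand = "+",
                    gene_id = sprintf("g%d", seq_along(start)),
                    seqlen = NULL) {
  gr <- GRanges(chrom, IRanges(start, end), strand = strand,
                gene_id = gene_id)
  if (!is.null(seqlen)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlen)
    GenomeInfoDb::seqlengths(gr) <- seqlen
  }
  gr
}

# independent per-position, per-strand PWM rescoring oracle
bruteForceScan <- function(sequence, pwm, scoreThreshold) {
  lo <- pwmLogOdds(pwm)
  L <- ncol(lo)
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  res <- list()
  if (n >= L) {
    for (i in seq_len(n - L + 1)) {
      win <- chars[i:(i + L - 1)]
      sF <- 0
      for (j in seq_len(L)) {
        b <- match(win[j], c("A", "C", "G", "T"))
        sF <- if (is.na(b)) -Inf else sF + lo[b, j]
      }
      rcWin <- rev(unname(comp[win]))
      sR <- 0
      for (j in seq_len(L)) {
        b <- match(rcWin[j], c("A", "C", "G", "T"))
        sR <- if (is.na(b) || is.na(rcWin[j])) -Inf else sR + lo[b, j]
      }
      if (is.finite(sF) && sF >= scoreThreshold)
        res[[length(res) + 1]] <- data.frame(start = i, strand = "+",
                                             score = sF)
      if (is.finite(sR) && sR >= scoreThreshold)
        res[[length(res) + 1]] <- data.frame(start = i, strand = "-",
                                             score = sR)
    }
  }
  if (!length(res))
    return(data.frame(start = integer(0), strand = character(0),
                      score = numeric(0)))
  df <- do.call(rbind, res)
  df[order(df$start, df$strand), , drop = FALSE]
}

randomSeq <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                      replace = TRUE), collapse = "")

sharpPWM <- function(consensus, tfName = "TF") {
  m <- matrix(1, 4, nchar(consensus),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  idx <- match(strsplit(consensus, "")[[1]], c("A", "C", "G", "T"))
  for (j in seq_along(idx)) m[idx[j], j] <- 97
  new("PWMRecord", tfName = tfName, profile = m, pseudocount = 1,
      background = rep(0.25, 4))
}
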