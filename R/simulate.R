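# Seeded synthetic-data generators. Each generator returns its data
# together with the planted ground truth, and optionally writes the
# standard on-disk formats so the file parsers share the same test
# surface. Defaults mirror the analysis presets (12.5 kb stitching,
# promoter +/-500 bp, mono-nucleosome fragments 180-247 bp, FRAP
# acquisition at 1 s intervals over 100 s).

#' Simulate a genome with non-overlapping gene models
#'
#' Uniform-random sequence (optional) and non-overlapping genes with
#' log-uniform lengths and alternating strands, distributed round-robin
#' across chromosomes.
#'
#' @param nChroms number of chromosomes.
#' @param chromLen chromosome length in bp (recycled).
#' @param nGenes total number of genes.
#' @param seed integer seed.
#' @param sequence generate random sequence (`TRUE`) or coordinates only.
#' @param geneLengthRange log-uniform gene length range in bp
#'   (default 5-100 kb).
#' @param outDir optional directory to write `genome.fa` and
#'   `genes.gtf`.
#' @return list with `sequence` (`DNAStringSet` or NULL), `genes`
#'   (`GRanges` with `gene_id` and seqlengths), `seqlengths`.
#' @export
simGenome <- function(nChroms = 1, chromLen = 1e6, nGenes = 10, seed = 1,
                      sequence = TRUE, geneLengthRange = c(5e3, 1e5),
                      outDir = NULL) {
  stopifnot(nChroms > 0, all(chromLen > 0), nGenes >= 0)
  set.seed(seed)
  chromLen <- rep_len(as.integer(chromLen), nChroms)
  chroms <- sprintf("chr%d", seq_len(nChroms))
  seqlen <- setNames(chromLen, chroms)
  seqs <- NULL
  if (sequence) {
    seqs <- Biostrings::DNAStringSet(vapply(chromLen, function(L)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE),
            collapse = ""), character(1)))
    names(seqs) <- chroms
  }
  genes <- GRanges()
  if (nGenes > 0) {
    perChrom <- tabulate(rep_len(seq_len(nChroms), nGenes), nChroms)
    parts <- list()
    gid <- 0L
    for (ci in seq_len(nChroms)) {
      ng <- perChrom[ci]
      if (ng == 0) next
      lens <- round(exp(runif(ng, log(geneLengthRange[1]),
                              log(geneLengthRange[2]))))
      minGap <- 2000L
      if (sum(lens) + (ng + 1L) * minGap > chromLen[ci])
        stop("requested gene span exceeds chromosome length")
      free <- chromLen[ci] - sum(lens) - (ng + 1L) * minGap
      w <- runif(ng + 1L)
      extra <- floor(w / sum(w) * free)
      starts <- cumsum(c(0L, lens[-ng])) + cumsum(rep(minGap, ng)) +
        cumsum(extra[seq_len(ng)]) + 1L
      parts[[ci]] <- GRanges(chroms[ci], IRanges(starts, width = lens),
                             strand = rep(c("+", "-"), length.out = ng),
                             gene_id = sprintf("gene_%04d", gid + seq_len(ng)))
      gid <- gid + ng
    }
    genes <- suppressWarnings(do.call(c, parts[!vapply(parts, is.null, logical(1))]))
  }
  GenomeInfoDb::seqlevels(genes) <- chroms
  GenomeInfoDb::seqlengths(genes) <- seqlen
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(seqs))
      Biostrings::writeXStringSet(seqs, file.path(outDir, "genome.fa"))
    writeGeneModels(genes, file.path(outDir, "genes.gtf"))
  }
  list(sequence = seqs, genes = genes, seqlengths = seqlen)
}

#' Simulate an enhancer landscape with planted super-enhancers
#'
#' Typical enhancers are isolated peaks with log-normal signal
#' (meanlog 0, sdlog 0.5); super-enhancers are clusters of constituent
#' peaks within a 12.5 kb span whose summed signal is approximately
#' `seSignalRatio` times the median TE signal (with mild log-normal
#' spread), producing a hockey-stick rank curve by construction. All
#' peaks are placed clear of gene TSSs so they survive the 2.5 kb
#' exclusion.
#'
#' @param genome result of [simGenome()].
#' @param nTE,nSE numbers of typical and super enhancers.
#' @param seConstituents constituent peaks per SE (default 5).
#' @param seSignalRatio SE total over median TE signal (> 1, default
#'   20).
#' @param peakWidth constituent peak width in bp (default 1000).
#' @param seed integer seed.
#' @param outDir optional directory for `peaks.bed`,
#'   `signal.bedGraph`, `ground_truth.json`.
#' @return list with `peaks` (`GRanges`), `track` (`RleList`; peak
#'   signal spread uniformly over the peak so mean coverage x width
#'   equals the peak signal), and `truth` (planted SE/TE regions and
#'   signals).
#' @export
simEnhancerLandscape <- function(genome, nTE = 2000, nSE = 20,
                                 seConstituents = 5, seSignalRatio = 20,
                                 peakWidth = 1000, seed = 1, outDir = NULL) {
  if (seSignalRatio <= 1) stop("seSignalRatio must exceed 1")
  set.seed(seed)
  seqlen <- genome$seqlengths
  genes <- genome$genes
  stride <- 26000L
  slotWidth <- 12000L
  slots <- list()
  for (chr in names(seqlen)) {
    starts <- seq(5000L, seqlen[[chr]] - slotWidth - 5000L, by = stride)
    slots[[chr]] <- GRanges(chr, IRanges(starts, width = slotWidth))
  }
  slots <- suppressWarnings(do.call(c, unname(slots)))
  if (length(genes)) {
    tssGr <- GRanges(seqnames(genes), IRanges(geneTSS(genes), width = 1L))
    near <- countOverlaps(slots + 3500L, tssGr) > 0
    slots <- slots[!near]
  }
  need <- nTE + nSE
  if (length(slots) < need)
    stop("genome too small to place ", need, " enhancer regions")
  pick <- sample(length(slots), need)
  seSlots <- slots[pick[seq_len(nSE)]]
  teSlots <- slots[pick[nSE + seq_len(nTE)]]
  teSignal <- rlnorm(nTE, 0, 0.5)
  tePeaks <- GRanges(seqnames(teSlots),
                     IRanges(start(teSlots), width = peakWidth),
                     name = sprintf("TE_%d", seq_len(nTE)),
                     signal = teSignal)
  seTotals <- seSignalRatio * stats::median(teSignal) *
    exp(rnorm(nSE, 0, 0.15))
  sePeaks <- GRanges()
  if (nSE > 0) {
    strideC <- slotWidth %/% seConstituents
    parts <- lapply(seq_len(nSE), function(i) {
      starts <- start(seSlots)[i] + (seq_len(seConstituents) - 1L) * strideC
      w <- rlnorm(seConstituents, 0, 0.5)
      GRanges(seqnames(seSlots)[i], IRanges(starts, width = peakWidth),
              name = sprintf("SE_%d_c%d", i, seq_len(seConstituents)),
              signal = w / sum(w) * seTotals[i])
    })
    sePeaks <- suppressWarnings(do.call(c, parts))
  }
  peaks <- suppressWarnings(c(tePeaks, sePeaks))
  GenomeInfoDb::seqlevels(peaks) <- names(seqlen)
  GenomeInfoDb::seqlengths(peaks) <- seqlen
  peaks <- peaks[order(as.character(seqnames(peaks)), start(peaks))]
  seRegions <- if (nSE > 0) {
    GRanges(seqnames(seSlots),
            IRanges(start(seSlots),
                    start(seSlots) + (seConstituents - 1L) *
                      (slotWidth %/% max(seConstituents, 1L)) + peakWidth - 1L),
            totalSignal = seTotals)
  } else GRanges(totalSignal = numeric(0))
  trackGr <- peaks
  trackGr$score <- peaks$signal / width(peaks)
  track <- makeSignalTrack(trackGr, seqlen)
  truth <- list(plantedSE = seRegions, plantedTE = tePeaks,
                seTotals = seTotals, teSignals = teSignal)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writePeaks(peaks, file.path(outDir, "peaks.bed"), "BED")
    writeBedGraphTrack(track, file.path(outDir, "signal.bedGraph"))
    jsonlite::write_json(
      list(planted_se = data.frame(chrom = as.character(seqnames(seRegions)),
                                   start = start(seRegions) - 1L,
                                   end = end(seRegions),
                                   total_signal = seRegions$totalSignal),
           n_te = nTE, n_se = nSE, ratio = seSignalRatio),
      file.path(outDir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(peaks = peaks, track = track, truth = truth)
}

#' Plant a TF cross-binding circuit into genomic sequence
#'
#' For every adjacency entry (u, v) = 1, writes u's PWM consensus at a
#' random non-overlapping position inside a super-enhancer assigned to
#' v's gene, then scrubs any accidental background occurrence of a
#' consensus (either strand) outside the planted positions, so the
#' planted adjacency is exactly recoverable.
#'
#' @param sequence `DNAStringSet`.
#' @param seRegions `GRanges` with `assignedGene` naming the proximal
#'   TF of each SE.
#' @param adjacency named 0/1 matrix, rows = source TF, cols = target
#'   TF.
#' @param pwms named list of [PWMRecord-class] covering the adjacency
#'   names.
#' @param seed optional integer seed.
#' @param maxRetry retries for non-overlapping placement.
#' @return list with `sequence` (modified) and `truth` (adjacency and
#'   planted positions).
#' @export
plantCircuit <- function(sequence, seRegions, adjacency, pwms, seed = NULL,
                         maxRetry = 100) {
  if (!is.null(seed)) set.seed(seed)
  tfs <- rownames(adjacency)
  if (is.null(tfs) || !identical(tfs, colnames(adjacency)))
    stop("adjacency must be a square matrix with matching dimnames")
  if (!all(tfs %in% names(pwms))) stop("missing PWM for some TFs")
  if (!all(tfs %in% seRegions$assignedGene))
    stop("every TF needs an assigned SE region")
  cons <- vapply(pwms[tfs], pwmConsensus, character(1))
  planted <- list()
  occupied <- list() # per SE index: IRanges of planted spans
  for (v in tfs) {
    seIdx <- which(seRegions$assignedGene == v)[1]
    reg <- seRegions[seIdx]
    chrom <- as.character(seqnames(reg))
    for (u in tfs[adjacency[, v] == 1]) {
      L <- nchar(cons[[u]])
      if (L > width(reg)) stop("consensus longer than SE region")
      occ <- occupied[[as.character(seIdx)]]
      if (is.null(occ)) occ <- IRanges()
      for (try in seq_len(maxRetry)) {
        off <- sample.int(width(reg) - L + 1L, 1L)
        cand <- IRanges(off, off + L - 1L)
        if (!any(IRanges::overlapsAny(cand, occ))) break
        if (try == maxRetry) stop("could not place motif without overlap")
      }
      occupied[[as.character(seIdx)]] <- c(occ, cand)
      s <- start(reg) + off - 1L
      Biostrings::subseq(sequence[[chrom]], s, s + L - 1L) <- Biostrings::DNAString(cons[[u]])
      planted[[length(planted) + 1L]] <- data.frame(
        source = u, target = v, chrom = chrom, start = s,
        end = s + L - 1L, stringsAsFactors = FALSE)
    }
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(source = character(0), target = character(0),
               chrom = character(0), start = integer(0), end = integer(0))
  # scrub accidental background consensi (either strand)
  for (pass in seq_len(10)) {
    dirty <- FALSE
    for (u in tfs) {
      pat <- Biostrings::DNAString(cons[[u]])
      for (chrom in names(sequence)) {
        hits <- c(Biostrings::matchPattern(pat, sequence[[chrom]]),
                  Biostrings::matchPattern(Biostrings::reverseComplement(pat),
                                           sequence[[chrom]]))
        ok <- planted[planted$source == u & planted$chrom == chrom, ,
                      drop = FALSE]
        for (h in seq_along(hits)) {
          hs <- start(hits)[h]; he <- end(hits)[h]
          if (any(ok$start == hs & ok$end == he)) next
          repl <- paste(sample(c("A", "C", "G", "T"), he - hs + 1L,
                               replace = TRUE), collapse = "")
          Biostrings::subseq(sequence[[chrom]], hs, he) <-
            Biostrings::DNAString(repl)
          dirty <- TRUE
        }
      }
    }
    if (!dirty) break
  }
  list(sequence = sequence,
       truth = list(adjacency = adjacency, planted = planted))
}

#' Simulate a self-contained TF circuit genome
#'
#' Builds a toy single-chromosome genome with one gene and one proximal
#' super-enhancer per TF, sharp 12-bp PWMs (one distinct consensus per
#' TF), and plants the requested adjacency with [plantCircuit()].
#'
#' @param adjacency named 0/1 matrix (rows = source, cols = target).
#' @param seed integer seed.
#' @param seLength SE region width in bp (default 2000).
#' @param motifLength consensus length (default 12).
#' @param outDir optional directory for `genome.fa`, `genes.gtf`,
#'   `se_regions.bed`, `pwms.txt`.
#' @return list with `sequence`, `genes`, `seRegions`, `pwms`,
#'   `truth`.
#' @export
simCircuit <- function(adjacency, seed = 1, seLength = 2000,
                       motifLength = 12, outDir = NULL) {
  set.seed(seed)
  tfs <- rownames(adjacency)
  if (is.null(tfs)) stop("adjacency needs dimnames")
  n <- length(tfs)
  chromLen <- 20000L + n * 30000L
  seqset <- Biostrings::DNAStringSet(paste(
    sample(c("A", "C", "G", "T"), chromLen, replace = TRUE), collapse = ""))
  names(seqset) <- "chr1"
  geneStarts <- 20000L + (seq_len(n) - 1L) * 30000L
  genes <- GRanges("chr1", IRanges(geneStarts, width = 2000L), strand = "+",
                   gene_id = tfs)
  GenomeInfoDb::seqlengths(genes) <- c(chr1 = chromLen)
  seRegions <- GRanges("chr1",
                       IRanges(geneStarts - 10000L, width = seLength),
                       label = "SE", assignedGene = tfs,
                       totalSignal = 100)
  # one sharp, distinct consensus per TF
  repeat {
    consensi <- vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), motifLength, replace = TRUE),
            collapse = ""), character(1))
    if (!anyDuplicated(consensi)) break
  }
  pwms <- lapply(seq_len(n), function(i) {
    m <- matrix(1, 4, motifLength, dimnames = list(c("A", "C", "G", "T"), NULL))
    idx <- match(strsplit(consensi[i], "")[[1]], c("A", "C", "G", "T"))
    for (j in seq_len(motifLength)) m[idx[j], j] <- 97
    new("PWMRecord", tfName = tfs[i], profile = m, pseudocount = 1,
        background = rep(0.25, 4))
  })
  names(pwms) <- tfs
  pl <- plantCircuit(seqset, seRegions, adjacency, pwms)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    Biostrings::writeXStringSet(pl$sequence, file.path(outDir, "genome.fa"))
    writeGeneModels(genes, file.path(outDir, "genes.gtf"))
    sePk <- seRegions
    sePk$name <- tfs
    sePk$signal <- sePk$totalSignal
    writePeaks(sePk, file.path(outDir, "se_regions.bed"), "BED")
    writePFM(pwms, file.path(outDir, "pwms.txt"))
  }
  list(sequence = pl$sequence, genes = genes, seRegions = seRegions,
       pwms = pwms, truth = pl$truth)
}

#' Simulate a Pol II coverage track with planted pausing indices
#'
#' The promoter window (TSS +/- 500 bp) gets coverage `pi x bodyDepth`;
#' the remainder of the gene body is depressed so that the mean coverage
#' over the full body (TSS to TES) equals `bodyDepth` exactly — the
#' planted pausing index is therefore recovered exactly on the noiseless
#' track. Optional per-base Poisson resampling.
#'
#' @param genes `GRanges` with `gene_id`, explicit strand and
#'   seqlengths.
#' @param piPerGene numeric planted pausing index per gene (recycled;
#'   names matched to `gene_id` when present). Requires gene width
#'   > 500 x pi.
#' @param bodyDepth mean body coverage per bp (default 20).
#' @param noise `"none"` or `"poisson"`.
#' @param promoterHalfwidth promoter half-width in bp (default 500).
#' @param seed integer seed.
#' @param outDir optional directory for `polii.bedGraph` and
#'   `ground_truth.json`.
#' @return list with `track` (`RleList`) and `truth` (data.frame
#'   `gene_id`, `pi`).
#' @export
simPolIITrack <- function(genes, piPerGene, bodyDepth = 20,
                          noise = c("none", "poisson"),
                          promoterHalfwidth = 500, seed = 1, outDir = NULL) {
  noise <- match.arg(noise)
  set.seed(seed)
  if (any(piPerGene <= 0)) stop("planted pausing indices must be positive")
  pis <- if (!is.null(names(piPerGene)))
    piPerGene[genes$gene_id] else rep_len(piPerGene, length(genes))
  hw <- promoterHalfwidth
  L <- width(genes)
  if (any(L <= hw * pis))
    stop("gene too short for planted pi (need width > promoterHalfwidth * pi)")
  tss <- geneTSS(genes)
  plus <- as.character(strand(genes)) == "+"
  promStart <- ifelse(plus, tss - hw, tss - hw + 1L)
  promEnd <- ifelse(plus, tss + hw - 1L, tss + hw)
  inner <- bodyDepth * (L - hw * pis) / (L - hw)
  if (any(inner < 0)) stop("gene too short for planted pi")
  restStart <- ifelse(plus, start(genes) + hw, start(genes))
  restEnd <- ifelse(plus, end(genes), end(genes) - hw)
  segs <- c(GRanges(seqnames(genes), IRanges(promStart, promEnd),
                    score = pis * bodyDepth),
            GRanges(seqnames(genes), IRanges(restStart, restEnd),
                    score = inner))
  seqlen <- GenomeInfoDb::seqlengths(genes)
  if (anyNA(seqlen)) stop("genes must carry seqlengths")
  track <- makeSignalTrack(segs, seqlen)
  if (noise == "poisson") {
    noisy <- lapply(names(seqlen), function(chr) {
      rle <- track[[chr]]
      rv <- runValue(rle)
      rl <- S4Vectors::runLength(rle)
      vals <- lapply(seq_along(rv), function(i) {
        if (rv[i] == 0) Rle(0, rl[i]) else Rle(rpois(rl[i], rv[i]))
      })
      do.call(c, vals)
    })
    names(noisy) <- names(seqlen)
    track <- methods::as(noisy, "SimpleRleList")
  }
  truth <- data.frame(gene_id = genes$gene_id, pi = pis,
                      stringsAsFactors = FALSE)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    writeBedGraphTrack(track, file.path(outDir, "polii.bedGraph"))
    jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                         digits = NA)
  }
  list(track = track, truth = truth)
}

#' Simulate nucleosome-phased ATAC fragments
#'
#' Dyads are drawn from an equal mixture of Normal(-d, sigma) and
#' Normal(+d, sigma) around randomly chosen motif centers; fragment
#' lengths are uniform over the mono-nucleosome range and fragments are
#' centered on their dyad, so the fragment midpoint reproduces the drawn
#' dyad exactly.
#'
#' @param motifs data.frame with `chrom`, `pos`, `strand`, or NULL to
#'   auto-place `nMotifs` plus-strand motifs on chr1.
#' @param nMotifs motifs to auto-place when `motifs` is NULL.
#' @param flankOffset planted flanking-nucleosome offset d in bp
#'   (default 93, i.e. spacing 186).
#' @param fuzz positional fuzz sigma in bp (default 20).
#' @param nFragments number of fragments (default 50000).
#' @param lenRange inclusive fragment length range (default 180-247).
#' @param seed integer seed.
#' @param outDir optional directory for `fragments.tsv` and
#'   `ground_truth.json`.
#' @return list with `fragments` (data.frame, 0-based half-open),
#'   `motifs`, `truth` (`spacing = 2 * flankOffset`).
#' @export
simATACFragments <- function(motifs = NULL, nMotifs = 10, flankOffset = 93,
                             fuzz = 20, nFragments = 50000,
                             lenRange = c(180, 247), seed = 1,
                             outDir = NULL) {
  if (fuzz < 0) stop("fuzz must be >= 0")
  set.seed(seed)
  if (is.null(motifs))
    motifs <- data.frame(chrom = "chr1",
                         pos = 50000L * seq_len(nMotifs),
                         strand = "+", stringsAsFactors = FALSE)
  frags <- data.frame(chrom = character(0), start = integer(0),
                      end = integer(0), length = integer(0))
  if (nFragments > 0) {
    idx <- sample.int(nrow(motifs), nFragments, replace = TRUE)
    side <- sample(c(-1L, 1L), nFragments, replace = TRUE)
    dyad <- as.integer(round(rnorm(nFragments,
                                   motifs$pos[idx] + side * flankOffset,
                                   fuzz)))
    len <- sample(seq(lenRange[1], lenRange[2]), nFragments, replace = TRUE)
    start <- dyad - len %/% 2L
    frags <- data.frame(chrom = motifs$chrom[idx], start = start,
                        end = start + len, length = len,
                        stringsAsFactors = FALSE)
  }
  truth <- list(flankOffset = flankOffset, spacing = 2L * flankOffset,
                fuzz = fuzz)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(frags[, c("chrom", "start", "end")],
                file.path(outDir, "fragments.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
    jsonlite::write_json(truth, file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(fragments = frags, motifs = motifs, truth = truth)
}

#' Simulate a raw FRAP trace
#'
#' True normalised recovery
#' \eqn{I(t) = floor + (plateau - floor)(1 - e^{-kt})} (1 before the
#' bleach at t = 0), multiplied into raw ROI and reference channels that
#' share an acquisition photobleaching decay, plus a constant background
#' and optional Gaussian noise per channel. [frapNormalize()] cancels
#' the decay exactly in the noiseless case.
#'
#' @param floorVal post-bleach floor of the true curve.
#' @param plateau recovery plateau (`floorVal <= plateau <= 1`).
#' @param k recovery rate per second.
#' @param prebleachN number of pre-bleach points (default 5, at
#'   t = -5..-1 s).
#' @param duration post-bleach duration in s (default 100).
#' @param step sampling interval in s (default 1).
#' @param photobleachRate acquisition bleaching rate per second.
#' @param noiseSd Gaussian noise sd, relative to each channel's scale.
#' @param background constant background intensity.
#' @param roiScale,refScale raw intensity scales of ROI and reference.
#' @param seed integer seed.
#' @param outDir optional directory for `trace.tsv` and
#'   `ground_truth.json`.
#' @return list with `trace` (data.frame `time_s`, `roi`,
#'   `background`, `reference`) and `truth`.
#' @export
simFRAPTrace <- function(floorVal = 0.2, plateau = 0.9, k = 0.1,
                         prebleachN = 5, duration = 100, step = 1,
                         photobleachRate = 0, noiseSd = 0,
                         background = 50, roiScale = 1000, refScale = 800,
                         seed = 1, outDir = NULL) {
  if (floorVal > plateau || plateau > 1) stop("need floor <= plateau <= 1")
  if (k < 0 || photobleachRate < 0 || noiseSd < 0)
    stop("rates and noise must be >= 0")
  set.seed(seed)
  times <- c(seq(-prebleachN * step, -step, by = step),
             seq(0, duration, by = step))
  true <- ifelse(times < 0, 1,
                 floorVal + (plateau - floorVal) * (1 - exp(-k * times)))
  decay <- exp(-photobleachRate * (times - times[1]))
  n <- length(times)
  trace <- data.frame(
    time_s = times,
    roi = background + roiScale * true * decay +
      rnorm(n, 0, noiseSd * roiScale),
    background = rep(background, n),
    reference = background + refScale * decay +
      rnorm(n, 0, noiseSd * refScale))
  truth <- list(floorVal = floorVal, plateau = plateau, k = k,
                mobileFraction = if (floorVal < 1)
                  (plateau - floorVal) / (1 - floorVal) else 0,
                trueCurve = true, photobleachRate = photobleachRate,
                noiseSd = noiseSd)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    write.table(trace, file.path(outDir, "trace.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    jsonlite::write_json(truth[c("floorVal", "plateau", "k",
                                 "mobileFraction")],
                         file.path(outDir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  list(trace = trace, truth = truth)
}

.renderDisk <- function(img, cx, cy, r, intensity) {
  xr <- max(1L, floor(cx - r - 1)):min(nrow(img), ceiling(cx + r + 1))
  yr <- max(1L, floor(cy - r - 1)):min(ncol(img), ceiling(cy + r + 1))
  d <- sqrt(outer((xr - cx)^2, (yr - cy)^2, "+"))
  cov <- pmin(pmax(r + 0.5 - d, 0), 1)
  img[xr, yr] <- img[xr, yr] + intensity * cov
  img
}

#' Simulate a droplet image with planted disks
#'
#' Renders antialiased disks at rejection-sampled non-overlapping
#' centers on a constant background with Gaussian noise. First matrix
#' index is x, second y, matching the centroid convention of
#' [segmentDroplets()].
#'
#' @param width,height image dimensions in px.
#' @param nDroplets number of disks.
#' @param radiusRange uniform radius range in px.
#' @param intensity disk intensity above background.
#' @param background background level.
#' @param noiseSd Gaussian noise sd.
#' @param allowOverlap permit overlapping disks.
#' @param seed integer seed.
#' @param outDir optional directory for `droplets.png` (intensities
#'   clamped to \eqn{[0,1]}) and `ground_truth.json`.
#' @return list with `image` (matrix) and `truth` (data.frame `x`,
#'   `y`, `r`).
#' @export
simDropletImage <- function(width = 256, height = 256, nDroplets = 50,
                            radiusRange = c(4, 8), intensity = 1,
                            background = 0.1, noiseSd = 0.02,
                            allowOverlap = FALSE, seed = 1, outDir = NULL) {
  set.seed(seed)
  centers <- .sampleDiskCenters(width, height, nDroplets, radiusRange,
                                allowOverlap)
  img <- matrix(background, nrow = width, ncol = height)
  for (i in seq_len(nrow(centers)))
    img <- .renderDisk(img, centers$x[i], centers$y[i], centers$r[i],
                       intensity)
  if (noiseSd > 0) img <- img + matrix(rnorm(length(img), 0, noiseSd),
                                       nrow = width)
  img <- pmax(img, 0)
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    png::writePNG(t(pmin(img, 1)), file.path(outDir, "droplets.png"))
    jsonlite::write_json(centers, file.path(outDir, "ground_truth.json"),
                         digits = NA)
  }
  list(image = img, truth = centers)
}

.sampleDiskCenters <- function(width, height, n, radiusRange, allowOverlap,
                               maxTries = 10000) {
  centers <- data.frame(x = numeric(0), y = numeric(0), r = numeric(0))
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(maxTries)) {
      r <- runif(1, radiusRange[1], radiusRange[2])
      x <- runif(1, r + 2, width - r - 1)
      y <- runif(1, r + 2, height - r - 1)
      if (allowOverlap || !nrow(centers) ||
          all(sqrt((centers$x - x)^2 + (centers$y - y)^2) >
              centers$r + r + 4)) {
        centers <- rbind(centers, data.frame(x = x, y = y, r = r))
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not pack ", n, " non-overlapping droplets")
  }
  centers
}

#' Simulate a two-channel droplet image pair with known coincidence
#'
#' Channel A carries `nA` droplets; a fraction `coincidence` of them
#' reappear at the same centers in channel B (plus optional B-only
#' droplets), so [colocalize()] applied A-vs-B recovers `coincidence`.
#'
#' @param coincidence fraction of A droplets present in B.
#' @param nA droplets in channel A.
#' @param nBOnly additional B-only droplets.
#' @param width,height,radiusRange,intensity,background,noiseSd,seed as
#'   [simDropletImage()].
#' @return list with `imageA`, `imageB`, `truth`.
#' @export
simDropletPair <- function(coincidence = 0.75, nA = 40, nBOnly = 0,
                           width = 256, height = 256,
                           radiusRange = c(4, 8), intensity = 1,
                           background = 0.1, noiseSd = 0.02, seed = 1) {
  set.seed(seed)
  nShared <- round(coincidence * nA)
  centers <- .sampleDiskCenters(width, height, nA + nBOnly, radiusRange,
                                allowOverlap = FALSE)
  aCenters <- centers[seq_len(nA), ]
  bCenters <- rbind(aCenters[seq_len(nShared), , drop = FALSE],
                    centers[nA + seq_len(nBOnly), , drop = FALSE])
  render <- function(cs) {
    img <- matrix(background, nrow = width, ncol = height)
    for (i in seq_len(nrow(cs)))
      img <- .renderDisk(img, cs$x[i], cs$y[i], cs$r[i], intensity)
    if (noiseSd > 0)
      img <- img + matrix(rnorm(length(img), 0, noiseSd), nrow = width)
    pmax(img, 0)
  }
  list(imageA = render(aCenters), imageB = render(bCenters),
       truth = list(coincidence = nShared / nA, aCenters = aCenters,
                    bCenters = bCenters))
}
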