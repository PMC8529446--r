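# Core regulatory circuitry: PWM scanning, dinucleotide-shuffle motif
# enrichment, the directed TF->TF binding graph with IN/OUT degree
# indices, autoregulatory cliques, and SE-occupancy clustering.

.BASES <- c("A", "C", "G", "T")

#' PWM log-odds matrix
#'
#' Converts a frequency profile to per-position log2 odds against the
#' background: columns are normalised to probabilities with a
#' background-weighted pseudocount, then `log2(p / background)`.
#'
#' @param pwm [PWMRecord-class].
#' @return 4 x L numeric matrix (rows A, C, G, T), in bits.
#' @export
pwmLogOdds <- function(pwm) {
  m <- pwm@profile
  p <- sweep(m + pwm@pseudocount * pwm@background, 2,
             colSums(m) + pwm@pseudocount, "/")
  log2(p / pwm@background)
}

#' @rdname pwmLogOdds
#' @export
pwmMaxScore <- function(pwm) sum(apply(pwmLogOdds(pwm), 2, max))

#' @rdname pwmLogOdds
#' @export
pwmConsensus <- function(pwm) {
  paste(.BASES[apply(pwmLogOdds(pwm), 2, which.max)], collapse = "")
}

.encodeSeq <- function(sequence) {
  chars <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  match(chars, .BASES) # N and anything else -> NA
}

.scanStrand <- function(enc, lo) {
  L <- ncol(lo)
  n <- length(enc)
  if (n < L) return(numeric(0))
  npos <- n - L + 1L
  score <- numeric(npos)
  for (j in seq_len(L)) {
    v <- lo[, j][enc[j:(j + npos - 1L)]]
    score <- score + v # NA (from N) propagates
  }
  score[is.na(score)] <- -Inf
  score
}

#' Scan a sequence with a PWM on both strands
#'
#' Scores every position on both strands with the log-odds matrix of
#' `pwm` and returns hits at or above the score threshold, sorted by
#' position. Windows containing N score `-Inf` and never match. A motif
#' longer than the sequence yields no hits.
#'
#' @param sequence character or `DNAString` over A/C/G/T/N.
#' @param pwm [PWMRecord-class].
#' @param scoreThreshold absolute log-odds threshold in bits; default is
#'   `thresholdFrac` times the maximal attainable score.
#' @param thresholdFrac fraction of the maximum score used when
#'   `scoreThreshold` is NULL (default 0.8).
#' @return data.frame with columns `tf`, `start`, `end` (1-based,
#'   inclusive, forward-strand coordinates), `strand`, `score`.
#' @export
scanMotif <- function(sequence, pwm, scoreThreshold = NULL,
                      thresholdFrac = 0.8) {
  lo <- pwmLogOdds(pwm)
  L <- ncol(lo)
  if (is.null(scoreThreshold)) scoreThreshold <- thresholdFrac * pwmMaxScore(pwm)
  if (!is.finite(scoreThreshold)) stop("scoreThreshold must be finite")
  enc <- .encodeSeq(sequence)
  empty <- data.frame(tf = character(0), start = integer(0), end = integer(0),
                      strand = character(0), score = numeric(0))
  if (length(enc) < L) return(empty)
  fwd <- .scanStrand(enc, lo)
  # reverse strand: score the forward encoding with the reverse-complement
  # matrix (complement rows, reverse columns)
  loRC <- lo[4:1, L:1, drop = FALSE]
  rev <- .scanStrand(enc, loRC)
  hitF <- which(fwd >= scoreThreshold)
  hitR <- which(rev >= scoreThreshold)
  if (!length(hitF) && !length(hitR)) return(empty)
  out <- data.frame(
    tf = pwm@tfName,
    start = c(hitF, hitR),
    end = c(hitF, hitR) + L - 1L,
    strand = c(rep("+", length(hitF)), rep("-", length(hitR))),
    score = c(fwd[hitF], rev[hitR]),
    stringsAsFactors = FALSE)
  out[order(out$start, out$strand), , drop = FALSE]
}

# ---- dinucleotide shuffling (Altschul-Erickson) ---------------------------

#' Dinucleotide-preserving sequence shuffle
#'
#' Altschul-Erickson shuffle: generates a uniform random sequence with
#' exactly the same dinucleotide (and hence mononucleotide) counts as the
#' input, via a random Eulerian path on the dinucleotide multigraph.
#' Uses the current RNG state.
#'
#' @param sequence character sequence.
#' @return shuffled character sequence of the same length.
#' @export
shuffleDinucleotide <- function(sequence) {
  s <- strsplit(toupper(as.character(sequence)), "", fixed = TRUE)[[1]]
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  from <- s[-n]
  to <- s[-1L]
  edges <- split(to, factor(from, levels = verts))
  last <- s[n]
  # choose a random last-edge per vertex (except the terminal vertex) such
  # that following last edges from every vertex reaches the terminal vertex
  nonTerm <- setdiff(verts, last)
  repeat {
    lastEdge <- vapply(nonTerm, function(v) {
      outs <- edges[[v]]
      outs[sample.int(length(outs), 1L)]
    }, character(1))
    ok <- TRUE
    for (v in nonTerm) {
      seen <- character(0)
      cur <- v
      while (cur != last) {
        if (cur %in% seen || !(cur %in% nonTerm)) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- lastEdge[[cur]]
      }
      if (!ok) break
    }
    if (ok) break
  }
  # shuffle remaining out-edges, appending the designated last edge
  order_out <- lapply(verts, function(v) {
    outs <- edges[[v]]
    if (v %in% nonTerm) {
      i <- match(lastEdge[[v]], outs)
      rest <- outs[-i]
      c(if (length(rest) > 1L) rest[sample.int(length(rest))] else rest,
        outs[i])
    } else {
      if (length(outs) > 1L) outs[sample.int(length(outs))] else outs
    }
  })
  names(order_out) <- verts
  ptr <- setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1L] <- s[1L]
  cur <- s[1L]
  for (i in 2:n) {
    nxt <- order_out[[cur]][ptr[[cur]]]
    ptr[[cur]] <- ptr[[cur]] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}

#' Empirical motif enrichment against a dinucleotide-shuffled null
#'
#' The statistic is the total motif hit count over the supplied
#' sequences; the null distribution is the same statistic on
#' dinucleotide-shuffled copies. The empirical p-value is
#' `(1 + #(null >= observed)) / (1 + nShuffles)`. An empty sequence list
#' returns p = 1.
#'
#' @param sequences character vector of (SE) sequences.
#' @param pwm [PWMRecord-class].
#' @param nShuffles number of shuffled replicates (>= 99).
#' @param seed optional integer seed for reproducibility.
#' @param scoreThreshold,thresholdFrac passed to [scanMotif()].
#' @return list with `p`, `observed`, `null` (numeric vector of null
#'   counts).
#' @export
motifEnrichment <- function(sequences, pwm, nShuffles = 199, seed = NULL,
                            scoreThreshold = NULL, thresholdFrac = 0.8) {
  if (nShuffles < 99) stop("nShuffles must be >= 99")
  if (!is.null(seed)) set.seed(seed)
  if (!length(sequences))
    return(list(p = 1, observed = 0L, null = integer(0)))
  obs <- sum(vapply(sequences, function(s)
    nrow(scanMotif(s, pwm, scoreThreshold, thresholdFrac)), integer(1)))
  if (obs == 0L)
    return(list(p = 1, observed = 0L,
                null = rep(0L, nShuffles)))
  null <- vapply(seq_len(nShuffles), function(i) {
    sum(vapply(sequences, function(s)
      nrow(scanMotif(shuffleDinucleotide(s), pwm, scoreThreshold,
                     thresholdFrac)), integer(1)))
  }, integer(1))
  p <- (1 + sum(null >= obs)) / (1 + nShuffles)
  list(p = p, observed = obs, null = null)
}

#' Benjamini-Hochberg motif enrichment over a PWM collection
#'
#' Runs [motifEnrichment()] per TF, applies BH correction across TFs and
#' flags enrichment at the given FDR (default 0.01).
#'
#' @param sequences character vector of SE sequences.
#' @param pwms named list of [PWMRecord-class].
#' @param nShuffles,seed,thresholdFrac see [motifEnrichment()].
#' @param fdr FDR threshold (default 0.01).
#' @return data.frame with columns `tf`, `observed`, `p`, `padj`,
#'   `enriched`.
#' @export
motifEnrichmentSet <- function(sequences, pwms, nShuffles = 199, seed = NULL,
                               thresholdFrac = 0.8, fdr = 0.01) {
  if (!is.null(seed)) set.seed(seed)
  res <- lapply(pwms, function(p)
    motifEnrichment(sequences, p, nShuffles, seed = NULL,
                    thresholdFrac = thresholdFrac))
  df <- data.frame(tf = vapply(pwms, function(p) p@tfName, character(1)),
                   observed = vapply(res, function(r) r$observed, numeric(1)),
                   p = vapply(res, function(r) r$p, numeric(1)),
                   stringsAsFactors = FALSE, row.names = NULL)
  df$padj <- stats::p.adjust(df$p, method = "BH")
  df$enriched <- df$padj <= fdr
  df
}

# ---- circuit graph --------------------------------------------------------

.seRegionsOf <- function(seCalls) {
  gr <- if (is(seCalls, "SECallSet")) seCalls@calls else seCalls
  if (is.null(gr$label)) gr$label <- rep("SE", length(gr))
  gr[gr$label == "SE"]
}

.extractSeq <- function(genome, chrom, s, e) {
  if (!chrom %in% names(genome)) stop("chromosome not in genome: ", chrom)
  len <- length(genome[[chrom]])
  as.character(Biostrings::subseq(genome[[chrom]],
                                  max(1L, s), min(len, e)))
}

#' Build the directed TF-to-TF circuitry graph
#'
#' Nodes are the transcription factors whose gene is assigned at least
#' one super-enhancer ("SE-driven"). An edge (u, v) is added when
#' [scanMotif()] finds at least one hit of u's PWM inside any SE assigned
#' to v's gene. A TF without a PWM keeps its node but gains no outgoing
#' edges (with a warning). Optionally, TFs whose motif is not enriched
#' over the SE sequences (dinucleotide-shuffle null, BH FDR) are denied
#' outgoing edges.
#'
#' @param seCalls [SECallSet-class] (or `GRanges` with `label` and
#'   `assignedGene`).
#' @param tfGenes `GRanges` of TF gene models with `gene_id`.
#' @param pwms named list of [PWMRecord-class] keyed by TF name.
#' @param genome `DNAStringSet` of chromosome sequences.
#' @param thresholdFrac motif score threshold as a fraction of the
#'   maximal log-odds (default 0.8).
#' @param enrichment optional result of [motifEnrichmentSet()]; when
#'   supplied, only enriched TFs contribute edges.
#' @return [CircuitGraph-class].
#' @export
buildCircuit <- function(seCalls, tfGenes, pwms, genome,
                         thresholdFrac = 0.8, enrichment = NULL) {
  se <- .seRegionsOf(seCalls)
  if (is.null(se$assignedGene))
    stop("SE calls must carry gene assignments")
  tfIds <- sort(unique(tfGenes$gene_id))
  nodes <- tfIds[tfIds %in% se$assignedGene]
  edges <- data.frame(source = character(0), target = character(0),
                      n_hits = integer(0), best_score = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(nodes)) {
    seSeq <- lapply(nodes, function(v) {
      regs <- se[se$assignedGene == v]
      vapply(seq_along(regs), function(i)
        .extractSeq(genome, as.character(seqnames(regs))[i],
                    start(regs)[i], end(regs)[i]), character(1))
    })
    names(seSeq) <- nodes
    scanners <- nodes[nodes %in% names(pwms)]
    missing <- setdiff(nodes, scanners)
    if (length(missing))
      warning("TF(s) without a PWM retained with no outgoing edges: ",
              paste(missing, collapse = ", "))
    if (!is.null(enrichment))
      scanners <- scanners[scanners %in% enrichment$tf[enrichment$enriched]]
    rows <- list()
    for (u in scanners) {
      for (v in nodes) {
        hits <- do.call(rbind, lapply(seSeq[[v]], function(s)
          scanMotif(s, pwms[[u]], thresholdFrac = thresholdFrac)))
        if (!is.null(hits) && nrow(hits)) {
          rows[[length(rows) + 1L]] <- data.frame(
            source = u, target = v, n_hits = nrow(hits),
            best_score = max(hits$score), stringsAsFactors = FALSE)
        }
      }
    }
    if (length(rows)) edges <- do.call(rbind, rows)
  }
  indeg <- vapply(nodes, function(v)
    length(unique(edges$source[edges$target == v])), integer(1))
  outdeg <- vapply(nodes, function(v)
    length(unique(edges$target[edges$source == v])), integer(1))
  new("CircuitGraph", nodes = nodes, edges = edges,
      inDegree = setNames(as.integer(indeg), nodes),
      outDegree = setNames(as.integer(outdeg), nodes))
}

#' Call CRC membership from degree indices
#'
#' A TF belongs to the core regulatory circuitry when its degree exceeds
#' the threshold (strictly greater than, default 150). Under the default
#' `"sum"` rule the total degree (IN + OUT) is compared; under `"both"`
#' each index must exceed the threshold separately.
#'
#' @param graph [CircuitGraph-class].
#' @param threshold degree threshold (default 150).
#' @param rule `"sum"` (default) or `"both"`.
#' @return data.frame sorted by total degree descending (ties by gene
#'   id) with columns `tf`, `in_degree`, `out_degree`, `total_degree`,
#'   `is_crc`.
#' @export
callCRC <- function(graph, threshold = 150, rule = c("sum", "both")) {
  rule <- match.arg(rule)
  nodes <- graph@nodes
  indeg <- as.integer(graph@inDegree)
  outdeg <- as.integer(graph@outDegree)
  total <- indeg + outdeg
  isCrc <- if (rule == "sum") total > threshold else
    (indeg > threshold & outdeg > threshold)
  df <- data.frame(tf = nodes, in_degree = indeg, out_degree = outdeg,
                   total_degree = total, is_crc = isCrc,
                   stringsAsFactors = FALSE)
  df[order(-df$total_degree, df$tf), , drop = FALSE]
}

#' Self-loop TFs and fully interconnected autoregulatory cliques
#'
#' Self-loop TFs are nodes with an edge onto their own SE. Cliques are
#' maximal cliques of the undirected graph containing an edge \{u, v\}
#' exactly when both (u, v) and (v, u) exist, restricted to self-loop
#' nodes, reported largest first (ties ordered lexicographically).
#'
#' @param graph [CircuitGraph-class].
#' @return list with `selfLoopTFs` (character) and `cliques` (list of
#'   character vectors).
#' @export
autoregulatoryCliques <- function(graph) {
  e <- graph@edges
  selfLoop <- sort(unique(e$source[e$source == e$target]))
  if (!length(selfLoop))
    return(list(selfLoopTFs = character(0), cliques = list()))
  nonSelf <- e[e$source != e$target, , drop = FALSE]
  key <- paste(nonSelf$source, nonSelf$target)
  revKey <- paste(nonSelf$target, nonSelf$source)
  recip <- nonSelf[key %in% revKey, , drop = FALSE]
  recip <- recip[recip$source %in% selfLoop & recip$target %in% selfLoop, ,
                 drop = FALSE]
  g <- igraph::graph_from_data_frame(
    recip[recip$source < recip$target, c("source", "target"), drop = FALSE],
    directed = FALSE, vertices = data.frame(name = selfLoop))
  cl <- igraph::max_cliques(g)
  cliques <- lapply(cl, function(x) sort(igraph::V(g)$name[as.integer(x)]))
  ord <- order(-lengths(cliques),
               vapply(cliques, function(x) paste(x, collapse = ","), character(1)))
  list(selfLoopTFs = selfLoop, cliques = cliques[ord])
}

# ---- occupancy clustering -------------------------------------------------

#' Binary SE-locus occupancy matrix across samples
#'
#' Columns are the overlap-merged union of all samples' SE regions; a
#' sample occupies a locus when one of its SEs overlaps it by at least
#' 1 bp.
#'
#' @param seSets named list of [SECallSet-class] or `GRanges`.
#' @return list with `matrix` (samples x loci, 0/1) and `loci`
#'   (`GRanges`).
#' @export
occupancyMatrix <- function(seSets) {
  if (is.null(names(seSets)) || any(!nzchar(names(seSets))))
    stop("seSets must be a named list")
  regs <- lapply(seSets, .seRegionsOf)
  all <- suppressWarnings(do.call(c, unname(lapply(regs, GenomicRanges::granges))))
  loci <- reduce(all, ignore.strand = TRUE)
  m <- t(vapply(regs, function(r)
    as.integer(countOverlaps(loci, r, ignore.strand = TRUE) > 0),
    integer(length(loci))))
  rownames(m) <- names(seSets)
  list(matrix = m, loci = loci)
}

.jaccardDist <- function(m) {
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i >= j) next
    inter <- sum(m[i, ] & m[j, ])
    uni <- sum(m[i, ] | m[j, ])
    d[i, j] <- d[j, i] <- if (uni == 0) 0 else 1 - inter / uni
  }
  stats::as.dist(d)
}

#' Hierarchical clustering of samples by SE-locus occupancy
#'
#' Builds the binary occupancy matrix over merged SE loci, computes
#' pairwise Jaccard distance (1 - Jaccard) between samples and clusters
#' them agglomeratively with average linkage. Samples are pre-sorted by
#' name so leaf order is deterministic under distance ties.
#'
#' @param seSets named list of [SECallSet-class] or `GRanges` (>= 2).
#' @param linkage linkage method; only `"average"` is offered.
#' @return list with `hclust`, `dist`, `matrix`, `loci`, `newick`.
#' @export
occupancyCluster <- function(seSets, linkage = "average") {
  linkage <- match.arg(linkage, "average")
  if (length(seSets) < 2L) stop("need at least 2 samples")
  seSets <- seSets[order(names(seSets))]
  om <- occupancyMatrix(seSets)
  d <- .jaccardDist(om$matrix)
  hc <- stats::hclust(d, method = linkage)
  nwk <- ape::write.tree(ape::as.phylo(hc))
  list(hclust = hc, dist = d, matrix = om$matrix, loci = om$loci,
       newick = nwk)
}

#' Genome-wide peak co-occupancy counts
#'
#' A peak of `a` is co-occupied when it overlaps at least one peak of
#' `b` by >= 1 bp. Returns the number of co-occupied peaks of `a`, the
#' `a`-only count, and the `b`-only count (peaks of `b` overlapped by no
#' peak of `a`).
#'
#' @param a,b `GRanges` peak sets on the same genome.
#' @return named integer vector `c(overlap, a_only, b_only)`.
#' @export
peakCooccupancy <- function(a, b) {
  ov <- sum(countOverlaps(a, b, ignore.strand = TRUE) > 0)
  c(overlap = ov,
    a_only = length(a) - ov,
    b_only = sum(countOverlaps(b, a, ignore.strand = TRUE) == 0))
}

#' Write circuitry outputs
#'
#' Edge list, degree/CRC table, clique list, occupancy matrix and Newick
#' dendrogram, all tab-separated (Newick as plain text).
#'
#' @param graph [CircuitGraph-class].
#' @param dir output directory.
#' @param threshold,rule passed to [callCRC()].
#' @param clustering optional result of [occupancyCluster()].
#' @return invisibly, the written file paths.
#' @export
writeCircuitTables <- function(graph, dir, threshold = 150, rule = "sum",
                               clustering = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  f <- file.path(dir, "edges.tsv")
  write.table(graph@edges, f, sep = "\t", quote = FALSE, row.names = FALSE)
  paths <- c(paths, f)
  f <- file.path(dir, "degrees.tsv")
  write.table(callCRC(graph, threshold, rule), f, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(paths, f)
  cl <- autoregulatoryCliques(graph)
  f <- file.path(dir, "cliques.txt")
  writeLines(vapply(cl$cliques, paste, character(1), collapse = "\t"), f)
  paths <- c(paths, f)
  if (!is.null(clustering)) {
    f <- file.path(dir, "occupancy_matrix.tsv")
    write.table(clustering$matrix, f, sep = "\t", quote = FALSE)
    paths <- c(paths, f)
    f <- file.path(dir, "dendrogram.nwk")
    writeLines(clustering$newick, f)
    paths <- c(paths, f)
  }
  invisible(paths)
}
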