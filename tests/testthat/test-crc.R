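test_that("scanMotif finds the consensus at maximal score and skips N", {
  p <- sharpPWM("ACGTTGCA")
  hits <- scanMotif(pwmConsensus(p), p)
  expect_equal(nrow(hits), 1)
  expect_equal(hits$start, 1)
  expect_equal(hits$score, pwmMaxScore(p), tolerance = 1e-12)

  expect_equal(nrow(scanMotif(strrep("N", 100), p)), 0)
  # motif longer than sequence
  expect_equal(nrow(scanMotif("ACG", p)), 0)
})

test_that("scanMotif equals exhaustive per-position rescoring", {
  set.seed(21)
  p <- sharpPWM("ACGTACGA")
  th <- 0.8 * pwmMaxScore(p)
  for (rep in 1:5) {
    s <- randomSeq(1000)
    # plant a couple of consensus copies so the hit set is non-trivial
    substr(s, 101, 108) <- pwmConsensus(p)
    substr(s, 512, 519) <- pwmConsensus(p)
    mine <- scanMotif(s, p, scoreThreshold = th)
    oracle <- bruteForceScan(s, p, th)
    expect_equal(mine$start, oracle$start)
    expect_equal(mine$strand, oracle$strand)
    expect_equal(mine$score, oracle$score, tolerance = 1e-9)
  }
})

test_that("dinucleotide shuffle preserves dinucleotide counts", {
  dinucCounts <- function(s) {
    ch <- strsplit(s, "")[[1]]
    table(paste0(ch[-length(ch)], ch[-1]))
  }
  set.seed(9)
  for (rep in 1:5) {
    s <- randomSeq(400)
    sh <- shuffleDinucleotide(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(substr(sh, 1, 1), substr(s, 1, 1))
    expect_equal(substr(sh, 400, 400), substr(s, 400, 400))
    expect_equal(as.list(dinucCounts(sh)), as.list(dinucCounts(s)))
  }
  # shuffles differ from the input (overwhelmingly) for long sequences
  set.seed(10)
  expect_false(shuffleDinucleotide(randomSeq(500)) == shuffleDinucleotide(randomSeq(500)))
})

test_that("motifEnrichment flags planted motifs and is seed-deterministic", {
  set.seed(33)
  p <- sharpPWM("TTGACGTCAA", "PLANTED")
  seqs <- replicate(10, randomSeq(600))
  # plant 5 copies per sequence (50 total)
  for (i in seq_along(seqs)) for (off in seq(50, 450, by = 100))
    substr(seqs[i], off, off + 9) <- pwmConsensus(p)
  res <- motifEnrichment(seqs, p, nShuffles = 199, seed = 101)
  expect_lte(res$p, 0.01)
  res2 <- motifEnrichment(seqs, p, nShuffles = 199, seed = 101)
  expect_identical(res$p, res2$p)

  # no hits anywhere: p = 1
  none <- motifEnrichment(c("AAAAAAAAAAAAAAAAAAAA"), p, nShuffles = 99)
  expect_equal(none$p, 1)
  # empty input: p = 1
  expect_equal(motifEnrichment(character(0), p, nShuffles = 99)$p, 1)
})

test_that("motifEnrichmentSet applies BH across TFs at FDR 0.01", {
  set.seed(44)
  planted <- sharpPWM("ACGTAGCTTGCA", "HIT")
  absent <- sharpPWM("TTTTACGCGTAC", "MISS")
  seqs <- replicate(6, randomSeq(500))
  for (i in seq_along(seqs)) for (off in c(41, 201, 361))
    substr(seqs[i], off, off + 11) <- pwmConsensus(planted)
  tab <- motifEnrichmentSet(seqs, list(HIT = planted, MISS = absent),
                            nShuffles = 199, seed = 7)
  expect_true(tab$enriched[tab$tf == "HIT"])
  expect_false(tab$enriched[tab$tf == "MISS"])
})

test_that("buildCircuit recovers a planted complete circuit exactly", {
  tfs <- c("TFA", "TFB", "TFC")
  adj <- matrix(1L, 3, 3, dimnames = list(tfs, tfs))
  sim <- simCircuit(adj, seed = 3)
  gr <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
  expect_setequal(circuitNodes(gr), tfs)
  expect_equal(unname(inDegree(gr)), c(3L, 3L, 3L))
  expect_equal(unname(outDegree(gr)), c(3L, 3L, 3L))
  cl <- autoregulatoryCliques(gr)
  expect_setequal(cl$selfLoopTFs, tfs)
  expect_equal(cl$cliques[[1]], tfs)

  # degree conservation over distinct ordered pairs
  expect_equal(sum(inDegree(gr)), nrow(circuitEdges(gr)))
  expect_equal(sum(outDegree(gr)), nrow(circuitEdges(gr)))
})

test_that("planted sparse adjacencies are recovered edge-for-edge", {
  tfs <- c("TFA", "TFB", "TFC", "TFD")
  set.seed(12)
  adj <- matrix(0L, 4, 4, dimnames = list(tfs, tfs))
  adj[cbind(c(1, 2, 3, 1, 4), c(1, 3, 2, 4, 4))] <- 1L
  sim <- simCircuit(adj, seed = 12)
  gr <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
  got <- matrix(0L, 4, 4, dimnames = list(tfs, tfs))
  e <- circuitEdges(gr)
  got[cbind(match(e$source, tfs), match(e$target, tfs))] <- 1L
  expect_equal(got, adj)

  # identity adjacency: only self-loops
  simI <- simCircuit(diag(1L, 3, 3) |>
                       `dimnames<-`(list(tfs[1:3], tfs[1:3])), seed = 5)
  grI <- buildCircuit(simI$seRegions, simI$genes, simI$pwms, simI$sequence)
  eI <- circuitEdges(grI)
  expect_true(all(eI$source == eI$target))
  expect_equal(nrow(eI), 3)
  # a node with only a self-loop forms a singleton clique
  clI <- autoregulatoryCliques(grI)
  expect_equal(lengths(clI$cliques), c(1L, 1L, 1L))
})

test_that("zero adjacency yields an edgeless graph and empty CRC set", {
  tfs <- c("TFA", "TFB", "TFC")
  sim <- simCircuit(matrix(0L, 3, 3, dimnames = list(tfs, tfs)), seed = 4)
  gr <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
  expect_equal(nrow(circuitEdges(gr)), 0)
  expect_true(all(inDegree(gr) == 0L))
  crc <- callCRC(gr)
  expect_false(any(crc$is_crc))
  expect_length(autoregulatoryCliques(gr)$cliques, 0)
})

test_that("TFs without an SE are excluded; TFs without a PWM keep nodes", {
  tfs <- c("TFA", "TFB", "TFC")
  adj <- matrix(1L, 3, 3, dimnames = list(tfs, tfs))
  sim <- simCircuit(adj, seed = 6)
  # drop TFC's SE: TFC is no longer SE-driven
  keep <- sim$seRegions[sim$seRegions$assignedGene != "TFC"]
  gr <- buildCircuit(keep, sim$genes, sim$pwms, sim$sequence)
  expect_setequal(circuitNodes(gr), c("TFA", "TFB"))

  # remove TFB's PWM: node retained, no outgoing edges, warning logged
  expect_warning(
    gr2 <- buildCircuit(sim$seRegions, sim$genes,
                        sim$pwms[c("TFA", "TFC")], sim$sequence),
    "TFB")
  expect_true("TFB" %in% circuitNodes(gr2))
  expect_equal(unname(outDegree(gr2)["TFB"]), 0L)
})

test_that("callCRC applies the strict >150 total-degree rule", {
  mkGraph <- function(indeg, outdeg) {
    # synthetic graph object with prescribed degrees via direct slots
    nodes <- names(indeg)
    edges <- do.call(rbind, lapply(nodes, function(v) {
      rbind(
        if (indeg[[v]] > 0)
          data.frame(source = sprintf("src%s_%d", v, seq_len(indeg[[v]])),
                     target = v, n_hits = 1L, best_score = 1)
        else NULL,
        if (outdeg[[v]] > 0)
          data.frame(source = v,
                     target = sprintf("tgt%s_%d", v, seq_len(outdeg[[v]])),
                     n_hits = 1L, best_score = 1)
        else NULL)
    }))
    allNodes <- sort(unique(c(nodes, edges$source, edges$target)))
    indegAll <- vapply(allNodes, function(v)
      length(unique(edges$source[edges$target == v])), integer(1))
    outdegAll <- vapply(allNodes, function(v)
      length(unique(edges$target[edges$source == v])), integer(1))
    new("CircuitGraph", nodes = allNodes, edges = edges,
        inDegree = indegAll, outDegree = outdegAll)
  }
  g <- mkGraph(c(hub = 100L, edge_case = 75L), c(hub = 51L, edge_case = 75L))
  crc <- callCRC(g, threshold = 150)
  expect_true(crc$is_crc[crc$tf == "hub"])        # 151 > 150
  expect_false(crc$is_crc[crc$tf == "edge_case"]) # exactly 150
  # "both" rule requires each index to clear the threshold
  crcBoth <- callCRC(g, threshold = 50, rule = "both")
  expect_true(crcBoth$is_crc[crcBoth$tf == "hub"])
  crcBoth2 <- callCRC(g, threshold = 90, rule = "both")
  expect_false(crcBoth2$is_crc[crcBoth2$tf == "hub"]) # out 51 < 90

  # empty graph
  empty <- new("CircuitGraph", nodes = character(0),
               edges = data.frame(source = character(0),
                                  target = character(0)),
               inDegree = integer(0), outDegree = integer(0))
  expect_equal(nrow(callCRC(empty)), 0)
})

test_that("adding an edge never removes a TF from the CRC set", {
  tfs <- c("TFA", "TFB", "TFC")
  set.seed(15)
  adj <- matrix(rbinom(9, 1, 0.5), 3, 3, dimnames = list(tfs, tfs))
  diag(adj) <- 1L
  sim <- simCircuit(adj, seed = 15)
  g1 <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
  before <- callCRC(g1, threshold = 3)
  # add every remaining edge
  adj2 <- adj; adj2[] <- 1L
  sim2 <- simCircuit(adj2, seed = 15)
  g2 <- buildCircuit(sim2$seRegions, sim2$genes, sim2$pwms, sim2$sequence)
  after <- callCRC(g2, threshold = 3)
  expect_true(all(before$tf[before$is_crc] %in% after$tf[after$is_crc]))
})

test_that("a reciprocation-free chain yields no multi-node cliques", {
  tfs <- c("TFA", "TFB", "TFC")
  adj <- matrix(0L, 3, 3, dimnames = list(tfs, tfs))
  diag(adj) <- 1L
  adj["TFA", "TFB"] <- 1L
  adj["TFB", "TFC"] <- 1L
  sim <- simCircuit(adj, seed = 8)
  gr <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
  cl <- autoregulatoryCliques(gr)
  expect_true(all(lengths(cl$cliques) == 1L))
})

test_that("occupancy clustering recovers planted sample groups", {
  mkSample <- function(idx) {
    GRanges("chr1", IRanges(idx * 100000 + 1, width = 5000), label = "SE")
  }
  shared1 <- 1:16; shared2 <- 31:46
  sets <- list(
    t1 = mkSample(c(shared1, 60)), t2 = mkSample(c(shared1, 61)),
    t3 = mkSample(c(shared1[1:14], 62, 63)),
    u1 = mkSample(c(shared2, 70)), u2 = mkSample(c(shared2, 71)),
    u3 = mkSample(c(shared2[1:14], 72, 73)))
  cl <- occupancyCluster(sets)
  grp <- stats::cutree(cl$hclust, k = 2)
  expect_equal(length(unique(grp[c("t1", "t2", "t3")])), 1)
  expect_equal(length(unique(grp[c("u1", "u2", "u3")])), 1)
  expect_false(grp[["t1"]] == grp[["u1"]])
  # distance matrix: symmetric, zero diagonal, in [0,1]
  dm <- as.matrix(cl$dist)
  expect_equal(dm, t(dm))
  expect_true(all(diag(dm) == 0))
  expect_true(all(dm >= 0 & dm <= 1))
  # newick string parses back to the same leaves
  expect_setequal(ape::read.tree(text = cl$newick)$tip.label, names(sets))
})

test_that("occupancy edge cases: identical and empty samples", {
  a <- GRanges("chr1", IRanges(c(1, 50001), width = 2000), label = "SE")
  cl <- occupancyCluster(list(s1 = a, s2 = a))
  expect_equal(max(cl$hclust$height), 0)
  # zero-SE sample vs non-empty: distance 1
  cl2 <- occupancyCluster(list(s1 = a, s2 = GRanges()))
  expect_equal(as.matrix(cl2$dist)["s1", "s2"], 1)
})

test_that("peakCooccupancy partitions both peak sets", {
  a <- peaksGR("chr1", c(1, 201), c(100, 300))
  b <- peaksGR("chr1", 91, 110, name = "b1")
  expect_equal(unname(peakCooccupancy(a, b)), c(1, 1, 0))
  expect_equal(unname(peakCooccupancy(a, a)), c(2, 0, 0))
  disjoint <- peaksGR("chr2", 1, 100)
  expect_equal(suppressWarnings(unname(peakCooccupancy(a, disjoint))),
               c(0, 2, 1))
})
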