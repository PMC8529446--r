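test_that("excludeTssProximal tests the peak center against the radius", {
  genes <- genesGR("chr1", 10000, 15000, strand = "+", gene_id = "g1")
  mk <- function(center) peaksGR("chr1", center - 500, center + 499,
                                 signal = 1)
  # center exactly at the TSS: removed
  expect_length(excludeTssProximal(mk(10000), genes), 0)
  # center 2500 away: removed (<= radius); 2501 away: retained
  expect_length(excludeTssProximal(mk(12500), genes), 0)
  expect_length(excludeTssProximal(mk(12501), genes), 1)
  # vacuous without genes
  expect_length(excludeTssProximal(mk(10000), GRanges()), 1)
})

test_that("stitchPeaks records constituents and summed signal", {
  # one isolated peak maps to itself
  one <- peaksGR("chr1", 100, 600, signal = 2.5)
  st1 <- stitchPeaks(one)
  expect_equal(c(start(st1), end(st1), st1$totalSignal), c(100, 600, 2.5))

  # five peaks with signals 1..5 inside the gap collapse to total 15
  pk <- peaksGR("chr1", seq(1, by = 3000, length.out = 5),
                seq(1000, by = 3000, length.out = 5), signal = 1:5)
  st <- stitchPeaks(pk)
  expect_length(st, 1)
  expect_equal(st$totalSignal, 15)
  expect_equal(st$nConstituents, 5L)

  # two clusters 13 kb apart stay separate at the 12.5 kb gap
  far <- peaksGR("chr1", c(1, 14001), c(1000, 15000), signal = c(1, 1))
  expect_length(stitchPeaks(far), 2)
})

test_that("findInflection matches a brute-force scan of the scaled curve", {
  bruteCutoff <- function(s) {
    s <- sort(s)
    n <- length(s)
    if (length(unique(s)) < 2) return(NA_integer_)
    x <- (seq_len(n) - 1) / (n - 1)
    y <- s / max(s)
    sl <- vapply(seq_len(n), function(i) {
      lo <- max(i - 1, 1); hi <- min(i + 1, n)
      (y[hi] - y[lo]) / (x[hi] - x[lo])
    }, numeric(1))
    ok <- vapply(seq_len(n), function(i) all(sl[i:n] > 1), logical(1))
    if (!any(ok)) NA_integer_ else which(ok)[1]
  }

  # degenerate flat curve: no cutoff, 0 SEs
  flat <- findInflection(rep(3, 50))
  expect_true(is.na(flat@cutoffIndex))

  # 99 regions of signal 1 plus one of signal 100: exactly one region above
  s <- c(rep(1, 99), 100)
  cv <- findInflection(s)
  expect_equal(cv@cutoffIndex, bruteCutoff(s))
  expect_equal(sum(cv@scaledSignal > cv@cutoffSignal), 1)

  # perfect diagonal: slope never exceeds 1, no SEs
  diag <- findInflection(as.numeric(1:200))
  expect_true(is.na(diag@cutoffIndex))

  # random heavy-tailed curves agree with the brute-force oracle
  set.seed(11)
  for (rep in 1:5) {
    s <- c(rlnorm(300, 0, 0.5), runif(5, 30, 60))
    cv <- findInflection(s)
    expect_equal(cv@cutoffIndex, bruteCutoff(s))
  }
})

test_that("cutoff signal lies strictly inside the scaled signal range", {
  set.seed(3)
  for (rep in 1:10) {
    s <- c(rlnorm(100, 0, 0.5), runif(3, 20, 40))
    cv <- findInflection(s)
    if (!is.na(cv@cutoffIndex)) {
      expect_gt(cv@cutoffSignal, min(cv@scaledSignal))
      expect_lt(cv@cutoffSignal, max(cv@scaledSignal))
    }
  }
})

test_that("callSuperEnhancers recovers every planted SE on the landscape", {
  genome <- simGenome(nChroms = 4, chromLen = 15e6, nGenes = 80, seed = 1,
                      sequence = FALSE)
  land <- simEnhancerLandscape(genome, nTE = 2000, nSE = 20,
                               seSignalRatio = 20, seed = 1)
  calls <- callSuperEnhancers(land$peaks, genome$genes)
  se <- seCalls(calls)[seCalls(calls)$label == "SE"]
  hit <- countOverlaps(land$truth$plantedSE, se) > 0
  expect_true(all(hit)) # 100% recall of planted regions
  # every planted SE outranks every unplanted region among the calls
  planted <- countOverlaps(seCalls(calls), land$truth$plantedSE) > 0
  expect_true(max(seCalls(calls)$rank[planted]) <= 20)
  # determinism: identical input, identical output
  calls2 <- callSuperEnhancers(land$peaks, genome$genes)
  expect_identical(seCalls(calls2), seCalls(calls))
})

test_that("SE/TE labels are invariant to uniform signal scaling", {
  set.seed(5)
  n <- 200
  starts <- seq(1, by = 30000, length.out = n)
  pk <- peaksGR("chr1", starts, starts + 999,
                signal = c(rlnorm(n - 4, 0, 0.5), runif(4, 25, 40)))
  g <- genesGR("chr1", 7e6, 7e6 + 5000, gene_id = "g1")
  base <- seCalls(callSuperEnhancers(pk, g))
  pk2 <- pk
  pk2$signal <- pk$signal * 37.5
  scaled <- seCalls(callSuperEnhancers(pk2, g))
  expect_equal(scaled$label, base$label)
})

test_that("raising the signal of a called SE never demotes it", {
  set.seed(6)
  n <- 150
  starts <- seq(1, by = 30000, length.out = n)
  pk <- peaksGR("chr1", starts, starts + 999,
                signal = c(rlnorm(n - 3, 0, 0.5), runif(3, 20, 30)))
  g <- genesGR("chr1", 6e6, 6e6 + 5000, gene_id = "g1")
  calls <- seCalls(callSuperEnhancers(pk, g))
  seIdx <- which(calls$label == "SE")
  skip_if(length(seIdx) == 0)
  target <- seIdx[1]
  # find the constituent peak and double its signal
  pkIdx <- which(start(pk) == start(calls)[target])
  pk$signal[pkIdx] <- pk$signal[pkIdx] * 2
  recalls <- seCalls(callSuperEnhancers(pk, g))
  again <- which(start(recalls) == start(calls)[target])
  expect_equal(recalls$label[again], "SE")
})

test_that("no surviving peaks yields an empty call set without error", {
  genes <- genesGR("chr1", 10000, 15000, gene_id = "g1")
  pk <- peaksGR("chr1", 9800, 10200, signal = 5) # center at TSS
  calls <- callSuperEnhancers(pk, genes)
  expect_length(seCalls(calls), 0)
})

test_that("SE gene assignment uses the nearest TSS to the midpoint", {
  genes <- genesGR("chr1", c(2e5, 9e5), c(2.1e5, 9.1e5), strand = "+",
                   gene_id = c("NEAR", "FAR"))
  pk <- peaksGR("chr1", c(240001, 243001), c(241000, 244000),
                signal = c(50, 50))
  bg <- peaksGR("chr1", seq(5e5, by = 30000, length.out = 60),
                seq(5e5, by = 30000, length.out = 60) + 999,
                signal = rep(1, 60),
                name = sprintf("bg%d", 1:60))
  calls <- seCalls(callSuperEnhancers(c(pk, bg), genes))
  se <- calls[calls$label == "SE"]
  expect_equal(unique(se$assignedGene), "NEAR")
})

test_that("seOverlapJaccard computes base-pair Jaccard", {
  a <- GRanges("chr1", IRanges(1, 100))
  b <- GRanges("chr1", IRanges(51, 150))
  expect_equal(seOverlapJaccard(a, a), 1)
  expect_equal(suppressWarnings(
    seOverlapJaccard(a, GRanges("chr2", IRanges(1, 100)))), 0)
  expect_equal(seOverlapJaccard(a, b), 50 / 150)
  expect_equal(seOverlapJaccard(GRanges(), GRanges()), 0)
})

test_that("SE table writer emits ranked rows and the rank curve", {
  genome <- simGenome(nChroms = 1, chromLen = 8e6, nGenes = 10, seed = 2,
                      sequence = FALSE)
  land <- simEnhancerLandscape(genome, nTE = 150, nSE = 5, seed = 2)
  calls <- callSuperEnhancers(land$peaks, genome$genes)
  d <- withr::local_tempdir()
  paths <- writeSETable(calls, d)
  tab <- read.delim(paths[1])
  expect_equal(tab$rank, seq_len(nrow(tab)))
  expect_true(all(diff(tab$total_signal) <= 0))
  curve <- read.delim(paths[2])
  expect_equal(nrow(curve), length(seCalls(calls)))
})
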