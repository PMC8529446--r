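test_that("generators are bit-reproducible under a fixed seed", {
  g1 <- simGenome(nChroms = 2, chromLen = 1e6, nGenes = 6, seed = 5,
                  geneLengthRange = c(5e3, 2e4))
  g2 <- simGenome(nChroms = 2, chromLen = 1e6, nGenes = 6, seed = 5,
                  geneLengthRange = c(5e3, 2e4))
  expect_identical(as.character(g1$sequence), as.character(g2$sequence))
  expect_identical(g1$genes, g2$genes)

  l1 <- simEnhancerLandscape(g1, nTE = 50, nSE = 3, seed = 9)
  l2 <- simEnhancerLandscape(g2, nTE = 50, nSE = 3, seed = 9)
  expect_identical(l1$peaks, l2$peaks)

  a1 <- simATACFragments(nFragments = 500, seed = 3)
  a2 <- simATACFragments(nFragments = 500, seed = 3)
  expect_identical(a1$fragments, a2$fragments)

  f1 <- simFRAPTrace(noiseSd = 0.02, seed = 4)
  f2 <- simFRAPTrace(noiseSd = 0.02, seed = 4)
  expect_identical(f1$trace, f2$trace)

  d1 <- simDropletImage(nDroplets = 10, seed = 6)
  d2 <- simDropletImage(nDroplets = 10, seed = 6)
  expect_identical(d1$image, d2$image)
})

test_that("simGenome respects gene geometry constraints", {
  g <- simGenome(nChroms = 2, chromLen = 5e5, nGenes = 10, seed = 1,
                 sequence = FALSE, geneLengthRange = c(5e3, 2e4))
  genes <- g$genes
  expect_equal(length(genes), 10)
  expect_true(all(width(genes) >= 5e3 & width(genes) <= 2e4))
  # non-overlapping within each chromosome
  expect_equal(sum(width(reduce(genes, ignore.strand = TRUE))),
               sum(width(genes)))
  # strands alternate
  expect_true(all(as.character(strand(genes)) %in% c("+", "-")))
  expect_gt(sum(strand(genes) == "+"), 0)
  expect_gt(sum(strand(genes) == "-"), 0)

  # no genes: sequence only
  g0 <- simGenome(nChroms = 1, chromLen = 1e4, nGenes = 0, seed = 1)
  expect_length(g0$genes, 0)
  expect_equal(Biostrings::width(g0$sequence), 1e4)

  # infeasible packing
  expect_error(simGenome(nChroms = 1, chromLen = 1e4, nGenes = 5, seed = 1,
                         geneLengthRange = c(5e3, 6e3)),
               "exceeds chromosome")
})

test_that("simGenome writes parseable FASTA and GTF", {
  d <- withr::local_tempdir()
  g <- simGenome(nChroms = 1, chromLen = 5e4, nGenes = 3, seed = 8,
                 geneLengthRange = c(2e3, 5e3), outDir = d)
  fa <- Biostrings::readDNAStringSet(file.path(d, "genome.fa"))
  expect_equal(as.character(fa), as.character(g$sequence))
  back <- readGeneModels(file.path(d, "genes.gtf"))
  expect_equal(back$gene_id, g$genes$gene_id)
  expect_equal(start(back), start(g$genes))
})

test_that("enhancer landscape geometry supports exact recovery conditions", {
  g <- simGenome(nChroms = 2, chromLen = 8e6, nGenes = 20, seed = 4,
                 sequence = FALSE)
  land <- simEnhancerLandscape(g, nTE = 200, nSE = 10, seConstituents = 5,
                               seed = 4)
  # SE cluster totals match the truth to floating tolerance
  st <- stitchPeaks(excludeTssProximal(land$peaks, g$genes))
  ov <- findOverlaps(land$truth$plantedSE, st)
  expect_equal(length(ov), 10)
  expect_equal(st$totalSignal[subjectHits(ov)],
               land$truth$seTotals[queryHits(ov)], tolerance = 1e-9)
  # every peak survives TSS exclusion by construction
  expect_equal(length(excludeTssProximal(land$peaks, g$genes)),
               length(land$peaks))
  # track re-scoring reproduces peak-sum scores
  expect_equal(meanCoverage(land$track, st) * width(st), st$totalSignal,
               tolerance = 1e-6)

  # single-constituent SEs are single wide peaks, still recovered
  land1 <- simEnhancerLandscape(g, nTE = 200, nSE = 5, seConstituents = 1,
                                seed = 5)
  calls <- callSuperEnhancers(land1$peaks, g$genes)
  se <- seCalls(calls)[seCalls(calls)$label == "SE"]
  expect_true(all(countOverlaps(land1$truth$plantedSE, se) > 0))
})

test_that("an SE-free landscape yields no super-enhancer calls", {
  g <- simGenome(nChroms = 2, chromLen = 8e6, nGenes = 20, seed = 6,
                 sequence = FALSE)
  land <- simEnhancerLandscape(g, nTE = 300, nSE = 0, seed = 6)
  calls <- callSuperEnhancers(land$peaks, g$genes)
  labels <- seCalls(calls)$label
  # the lognormal background has no planted elbow; any slope-1 cutoff can
  # only sit inside the distribution's own upper tail, so at most a few
  # per cent of regions end up above it
  expect_lt(sum(labels == "SE") / length(labels), 0.10)
})

test_that("plantCircuit guarantees planted consensi and scrubs strays", {
  tfs <- c("TFA", "TFB")
  adj <- matrix(c(1L, 1L, 0L, 1L), 2, 2, dimnames = list(tfs, tfs))
  sim <- simCircuit(adj, seed = 13)
  for (i in seq_len(nrow(sim$truth$planted))) {
    row <- sim$truth$planted[i, ]
    got <- as.character(Biostrings::subseq(sim$sequence[[row$chrom]],
                                           row$start, row$end))
    expect_equal(got, pwmConsensus(sim$pwms[[row$source]]))
  }
  # no consensus occurrences outside the planted positions
  for (tf in tfs) {
    pat <- Biostrings::DNAString(pwmConsensus(sim$pwms[[tf]]))
    hits <- Biostrings::matchPattern(pat, sim$sequence[[1]])
    planted <- sim$truth$planted[sim$truth$planted$source == tf, ]
    expect_setequal(start(hits), planted$start)
  }
})

test_that("FRAP and ATAC generators agree with their analytic truths", {
  # noiseless, bleach-free trace: raw normalisation is the true curve
  sim <- simFRAPTrace(photobleachRate = 0, noiseSd = 0, seed = 2)
  nrm <- frapNormalize(sim$trace)
  expect_equal(nrm$intensity, sim$truth$trueCurve, tolerance = 1e-12)

  # zero fragments: empty set and all-zero downstream profile
  a0 <- simATACFragments(nFragments = 0, seed = 1)
  expect_equal(nrow(a0$fragments), 0)
  prof <- dyadDensity(a0$fragments, a0$motifs)
  expect_true(all(prof@counts == 0))

  # fragment midpoints reproduce the drawn dyads exactly: lengths in range
  a <- simATACFragments(nFragments = 2000, seed = 7)
  expect_true(all(a$fragments$length >= 180 & a$fragments$length <= 247))
})

test_that("droplet image generator plants countable disks", {
  # zero droplets: pure noise segments to nothing at default settings
  d0 <- simDropletImage(nDroplets = 0, seed = 3)
  expect_equal(nrow(droplets(segmentDroplets(d0$image))), 0)

  # packing failure surfaces as an error
  expect_error(simDropletImage(width = 40, height = 40, nDroplets = 50,
                               seed = 1), "pack")

  # written PNG round-trips to the clamped image
  dir <- withr::local_tempdir()
  sim <- simDropletImage(nDroplets = 8, seed = 9, outDir = dir)
  img <- png::readPNG(file.path(dir, "droplets.png"))
  expect_equal(dim(img), c(256, 256))
})
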