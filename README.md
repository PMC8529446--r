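# circuitSE

Regulatory-genomics and condensate-quantification toolkit for studies
of transcription-factor **core regulatory circuitry (CRC)** — the small
set of super-enhancer-driven transcription factors that bind their own
and each other's super-enhancers, forming an interconnected
autoregulatory loop. Such circuits (e.g. HOXB8/FOSL1 in metastatic
osteosarcoma) drive aberrant transcription and assemble liquid-like
condensates; dissecting them requires a chain of analyses that this
package implements as one tested, seedable pipeline:

- **Super-enhancer (SE) calling** in the ROSE style: H3K27ac peaks are
  stitched within 12.5 kb, peaks within 2.5 kb of a TSS are excluded,
  regions are ranked by signal, and the classification cutoff is the
  point where the slope of the scaled signal-vs-rank curve exceeds 1 —
  regions above it are SEs, the rest typical enhancers (TEs).
- **CRC inference**: a directed TF→TF graph with an edge (u, v) when
  u's binding motif (position weight matrix, log-odds scanning on both
  strands) hits inside an SE assigned to v. For each TF the **IN
  degree** counts distinct SE-driven TFs binding its proximal SE and
  the **OUT degree** its distinct targets; a TF is a CRC member when
  IN + OUT > 150. Motif enrichment is tested against a
  dinucleotide-shuffled null at FDR 0.01; autoregulatory cliques and
  SE-occupancy sample clustering (average linkage, Jaccard distance)
  are included.
- **RNA Pol II pausing index** (traveling ratio): mean Pol II coverage
  in the TSS ± 500 bp promoter window over mean coverage across the
  gene body, plus scaled-body metagene profiles and binned signal
  matrices.
- **ATAC-seq nucleosome phasing**: mono-nucleosome fragments
  (180–247 bp) are reduced to dyads (fragment midpoints); spacing is
  the distance between the upstream and downstream dyad-density maxima
  around motif centers.
- **Condensate quantification**: FRAP double normalisation
  (background-subtracted ROI over reference, scaled to pre-bleach
  mean) with single-exponential recovery fits
  `I(t) = floor + (plateau − floor)(1 − e^(−kt))` reporting the mobile
  fraction and t1/2; droplet segmentation/counting on fluorescence
  images; compound-screen relative droplet numbers against a DMSO
  control; two-channel colocalization; and the xenograft caliper
  volume `length × width² / 2`.
- **Synthetic data with planted truth**: seeded generators for every
  input (enhancer landscapes, planted circuits, Pol II tracks with
  known pausing indices, phased fragment libraries, FRAP traces,
  droplet images), so each stage is verifiable end-to-end with no
  external data.

The methods vignette (`vignettes/regulatory-circuitry.Rmd`) documents
the models, parameter defaults, numerical choices and limitations.

## Worked example

Call super-enhancers on a simulated landscape of 2000 typical
enhancers plus 20 planted SE clusters, then recover a planted 3-TF
circuit:

```r
library(circuitSE)

genome <- simGenome(nChroms = 4, chromLen = 15e6, nGenes = 80,
                    seed = 1, sequence = FALSE)
land   <- simEnhancerLandscape(genome, nTE = 2000, nSE = 20, seed = 1)
calls  <- callSuperEnhancers(land$peaks, genome$genes)
calls
#> SECallSet: 2020 stitched regions (34 SE, 1986 TE)
#> SERankCurve over 2020 regions
#> cutoff at rank 1986/2020, scaled signal 0.1406
```

All 20 planted clusters are recovered and hold the top 20 ranks (the
handful of additional SE labels are the extreme upper tail of the
log-normal background crossing the slope-1 cutoff — see the vignette's
discussion of heavy-tailed backgrounds):

```r
head(as.data.frame(seCalls(calls)[seCalls(calls)$rank <= 3]))
#>   seqnames    start      end totalSignal nConstituents rank label
#> 1     chr1   941000   951599    23.76543             5    2    SE
#> 2     chr4  2839000  2849599    22.73991             5    3    SE
#> 3     chr4 13005000 13015599    23.81509             5    1    SE
```

```r
tfs   <- c("TFA", "TFB", "TFC")
sim   <- simCircuit(matrix(1L, 3, 3, dimnames = list(tfs, tfs)), seed = 1)
graph <- buildCircuit(sim$seRegions, sim$genes, sim$pwms, sim$sequence)
graph
#> CircuitGraph: 3 SE-driven TFs, 9 edges (3 self-loops)
#> top total degree: TFA=6, TFB=6, TFC=6
callCRC(graph, threshold = 5)
#>    tf in_degree out_degree total_degree is_crc
#> 1 TFA         3          3            6   TRUE
#> 2 TFB         3          3            6   TRUE
#> 3 TFC         3          3            6   TRUE
```

Every TF binds all three proximal SEs (self-loops included), so each
node has IN = OUT = 3 and the circuit is one fully interconnected
autoregulatory clique. A FRAP trace generated with rate k = 0.1/s,
floor 0.2 and plateau 0.9 fits back to exactly those parameters:

```r
frapFit(frapNormalize(simFRAPTrace(k = 0.1, noiseSd = 0, seed = 1)$trace))
#> FRAPFit: k = 0.1 /s (t1/2 = 6.93 s), plateau = 0.900, floor = 0.200,
#>          mobile fraction = 0.875
```

A config-driven multi-stage run (`runPipeline()`, or
`inst/scripts/run_pipeline.R` from the shell) writes per-stage outputs
plus an MD5 manifest; reruns with the same config and seed are
bit-identical.

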