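# ivdSCT

Compartment transcriptomics of the intervertebral disc from single-cell
RNA-seq.

## The problem

The healthy human intervertebral disc has two transcriptionally distinct
compartments — the gelatinous nucleus pulposus (NP) and the fibrous annulus
fibrosus (AF) — and understanding which genes distinguish them underpins
work on disc degeneration. Single-cell RNA-seq of cultured NP and AF cells
from a small number of donors poses a specific analytical problem: cells
are shallow (~10,000–12,000 UMI), donors are sequenced in separate batches,
and per-cell tests are underpowered and miscalibrated. `ivdSCT` implements
a complete, tested pipeline for this design, for bioinformaticians who want
the procedure reproducible end to end:

* **Pooled pseudo-cell permutation DE** — within each (compartment, donor)
  sample, cells are randomly pooled into groups of *g* = 20 and summed;
  each gene is tested with a closed-form negative-binomial likelihood-ratio
  test (var = μ + φμ², common φ estimated by a moment median; φ = 0
  degrades exactly to Poisson); the procedure is repeated *R* = 10 times
  and log₂ fold changes and −log₁₀ *p* are averaged; BH FDR < 0.05 calls
  significance.
* **Gene-set over-representation** — upper-tail hypergeometric
  *p* = Σᵢ₌ₖ C(K,i)C(N−K,n−i)/C(N,n) with BH correction, plus matrisome
  landscape classification (core matrisome / matrisome-associated × six
  categories), metabolic-pathway mapping and TF-list annotation.
* **Interaction networks** — STRING-style tables filtered at combined
  score > 0.7, NetworkAnalyzer-convention topology metrics, and a
  from-scratch deterministic MCODE (k-core vertex weighting, seeded
  breadth-first growth, haircut); complexes scored as density × nodes.
* **Regulon analysis** — NES > 3 filtering and signature-TF selection by
  maximal target coverage of a query gene set.
* **Cross-platform comparison** — two-layer Venn partitions, microarray
  DEG filtering (p < 0.05, |logFC| > 1), average-rank Spearman correlation
  of fold changes, and ΔΔCt fold-change arithmetic.
* **Synthetic data** — a generator that emulates the two-donor,
  two-compartment design (NB counts, log-normal gene means and library
  sizes, planted fold changes spanning ~2–50×) plus fixture generators for
  every downstream stage, so the whole pipeline is testable without any
  external data.

## Worked example

```r
library(ivdSCT)

cfg <- simulationConfig(nGenes = 1000, cellsPerSample = 100, nDonors = 2,
                        deFraction = 0.1, seed = 1)
sce <- simulateCounts(cfg)                      # SingleCellExperiment
de  <- runPermutedDE(sce, poolSize = 20, nPermutations = 10, seed = 1)
de
#> DEResult: 1000 genes tested (0 dropped as unexpressed)
#>   significant at q < 0.05: 101 (47 NP-high, 54 AF-high)
#>   pool size 20, 10 permutations, seed 1
```

100 of the 1000 simulated genes carry a true compartment effect; 101 are
called at q < 0.05, recovering 97% of the planted genes. The strongest
hits show the permutation-averaged evidence:

```r
tab <- deTable(de)
head(tab[order(tab$q), ], 3)
#>         gene meanLog2FC meanNegLog10P combinedP         q significant direction
#>    GENE00287       4.23           308 2.23e-308 2.23e-305        TRUE   NP-high
#>    GENE00545       3.47           306 3.63e-307 1.81e-304        TRUE   NP-high
#>    GENE00931       3.20           286 3.48e-287 1.16e-284        TRUE   NP-high
```

`meanLog2FC` is the permutation-averaged log₂ fold change (positive =
NP-high), `combinedP` the back-transform of the averaged −log₁₀ *p*, and
`q` its BH adjustment. Downstream, a dense complex planted in a synthetic
interaction table is detected and scored by MCODE:

```r
fix <- simulateInteractionTable(0, planted = list(c(26, 311/325)), seed = 1)
net <- buildNetwork(fix$table, scoreThreshold = 0.7)
mcodeFindComplexes(net)[[1]]
#> McodeComplex: 26 genes, 311 interactions, score 24.9 (seed CL1_G11)
```

A 26-gene complex with 311 interactions has density 311/325, hence score
(2·311/(26·25))·26 = 24.9 — the hallmark score of the dense AF
cell-cycle-type complex this analysis is designed to surface. The whole
chain can also be driven from one config via `runPipeline()`, which writes
per-stage TSVs and a JSON manifest; see the methods vignette
(`vignettes/methods.Rmd`) for the model, parameter and calibration details.

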