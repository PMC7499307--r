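---
title: "Methods: pooled pseudo-cell differential expression and downstream network analysis"
author: "ivdSCT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pooled pseudo-cell differential expression and downstream network analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ivdSCT)
```

# Scope and model

`ivdSCT` analyses two-compartment single-cell RNA-seq designs of the kind
used to contrast the nucleus pulposus (NP) and annulus fibrosus (AF) of the
human intervertebral disc: two compartments, a small number of donors
sequenced in separate batches, a few hundred cells per sample, and on the
order of 12,000 detected genes. The package covers the whole downstream
path — pooled pseudo-cell differential expression, gene-set and matrisome
annotation, interaction-network topology and molecular-complex detection,
regulon-based transcription-factor selection, and cross-platform
comparison — together with a synthetic-data generator so that every stage
can be exercised and verified without access to patient data.

## Pseudo-cell pooling and the permutation average

Single cells of cultured disc compartments are shallow (roughly
10,000–12,000 UMI per cell), so per-cell differential expression is noisy.
The core procedure instead forms *pseudo-cells*: within each
(compartment, donor) sample, cells are randomly partitioned into disjoint
groups of $g = 20$ and each group's counts are summed. With $n$ cells in a
sample, $\lfloor n/g \rfloor$ pseudo-cells are formed and the remainder
cells sit out that round; because each of $R = 10$ rounds re-draws the
partition, all cells contribute across rounds. Every round yields per-gene
estimates, and the round-wise $\log_2$ fold changes and $-\log_{10} p$
values are averaged; the combined p value is the back-transform
$10^{-\overline{-\log_{10} p}}$, Benjamini–Hochberg q values are computed
on the combined p values, and genes with $q < 0.05$ are called
differentially expressed.

Averaging on the $-\log_{10}$ scale follows the procedure the pipeline
models; because the rounds re-use the same cells the averaged evidence is
highly correlated between rounds, so the average stabilises rather than
sharpens the per-gene evidence (the permutation-stability test verifies
exactly this: the between-run standard deviation of the averaged
$-\log_{10} p$ shrinks as $R$ grows). FDR control is applied once, to the
combined p values, not per round.

## The negative-binomial likelihood-ratio test

Pseudo-cell counts are modelled as negative binomial with
$\mathrm{var} = \mu + \phi\mu^2$. For a fixed dispersion $\phi$ the
maximum-likelihood estimate of a group's mean is its sample mean, so the
two-group likelihood-ratio test (separate NP and AF means against a common
mean) is closed-form; the statistic is referred to $\chi^2_1$, and
$\phi = 0$ reduces exactly to the Poisson LRT — both facts are pinned by
tests against direct `dpois()`/`dnbinom()` evaluation. Fold changes are
$\log_2((\bar y_{NP} + c)/(\bar y_{AF} + c))$ with prior count $c = 0.5$.

The common dispersion is estimated per round by the method of moments:
per-gene $\hat\phi_g = \max(0, (s^2_g - \bar y_g)/\bar y_g^2)$ pooled
within groups, then the median over genes with mean above 1. This is
deliberately simpler than Cox–Reid tagwise shrinkage: at pseudo-bulk depth
(about 20 × 11,000 UMI per pseudo-cell) the moment median is stable, and
its simplicity makes it directly testable (Poisson data recover
$\hat\phi \approx 0$, data generated at $\phi = 0.3$ recover
$\hat\phi \in [0.2, 0.4]$).

## Normalization: why the default is median-of-ratios

Pseudo-cell profiles must be depth-normalized before testing. Three modes
are provided and the choice matters more than it may appear:

* `"ratio"` (default) — each pseudo-cell is divided by its
  median-of-ratios size factor (median over genes of the ratio to the
  geometric-mean reference profile). Values stay on the count scale and
  the factor is robust to composition shifts.
* `"median"` — total-count scaling to the median pseudo-cell library.
* `"cpm"` — literal counts per million.

Two measured failure modes motivated the default. First, CPM inflates
pseudo-cell values several-fold (a 220,000-count pseudo-cell becomes
1,000,000), and a *single* common dispersion cannot describe the inflated
mean–variance relation at both ends of the expression range: on a
2,000-gene global-null simulation at $\phi = 0.3$ the CPM mode shows an
overall type-I error of 0.10 at nominal 0.05, concentrated in the
weakly expressed tertile (0.23). On the count scale the same procedure
measures 0.05. Second, any total-count scaling (CPM or median-library) is
composition-sensitive: when a planted minority of genes is strongly
NP-upregulated it consumes a visible share of the NP library, every null
gene acquires a small negative apparent fold change, and the false
discovery proportion at $q<0.05$ rises to ~0.4 with all false positives
called AF-high. The median-of-ratios factor ignores the shifted minority
and restores FDR control (measured FDP 0.04 at recall 0.98 on the planted
benchmark). TMM would achieve the same end but is deliberately out of
scope; median-of-ratios is the package's own, equally standard, estimator.

## Enrichment, matrisome and pathway annotation

Over-representation uses the upper-tail (cumulative) hypergeometric
probability, computed in log space via `phyper()` and verified against
exhaustive enumeration of all draws for every parameter combination with
$N \le 12$. The default universe is the set of genes detected in the DE
analysis rather than the whole genome: a genome background overstates
enrichment for any platform that does not detect all genes. BH correction
is applied across tested sets.

The matrisome landscape splits significant genes by direction and then by
division and category (core matrisome: ECM glycoproteins, collagens,
proteoglycans; matrisome-associated: ECM-affiliated proteins, ECM
regulators, secreted factors); the partition is validated to be exhaustive
and mutually exclusive, with unclassified genes counted separately.
Pathway mapping (glycolysis, TCA cycle, electron transport chain,
pyruvate metabolism, or any supplied sets) is a plain intersection that
deliberately allows a gene to appear in several pathways, with fold
changes exported on the $\log_{10}$ scale for heatmaps.

## Interaction networks and MCODE

Interaction tables are STRING-style (gene pair plus combined score in
$[0,1]$, with the 0–1000 dialect rescaled on read). The network keeps
edges with score strictly above 0.7 — the conventional high-confidence
cut-off — and drops isolated nodes. Topology metrics follow the
NetworkAnalyzer conventions: mean local clustering coefficient with
degree-<2 nodes contributing 0, Freeman degree centralization
$\sum_i (d_{max}-d_i)/((n-1)(n-2))$, heterogeneity as population SD of
degree over mean degree, characteristic path length over connected
ordered pairs, and diameter/radius from eccentricities of the largest
component when the graph is disconnected (a disconnected graph otherwise
has no finite diameter). Edge weights are used only for the score filter;
topology and complex detection treat the graph as unweighted.

Molecular-complex detection is a from-scratch MCODE: each vertex is
weighted by $k \times$ density of the highest $k$-core of its closed
neighbourhood; complexes grow breadth-first from the highest-weight
unseen seed, admitting neighbours with weight at least
$(1 - 0.2) \times$ the seed weight; a haircut removes members with
in-complex degree below 2; complexes lacking a 2-core are discarded; and
each complex is scored as density × node count (a 26-node complex with
311 interactions scores 24.9; a 7-node complex with 20 interactions
scores 6.7). Ties in seed selection are broken lexicographically so
detection is deterministic — graphical tools leave this order
session-dependent, which is unacceptable for a tested pipeline. Vertex
weights are verified against exhaustive subset search on small graphs.

## Regulons and signature transcription factors

The package consumes a precomputed regulon table (TF, target, NES) rather
than re-implementing motif scanning, which requires external PWM
collections; the reproducible part of the analysis is the selection
logic. Associations with NES strictly above 3 are kept, and the signature
TF for a gene set (typically the top complex) is the TF covering the most
query genes, with ties broken by higher NES then name. Because "most
significant" could also mean highest NES, the result carries both
orderings in its ranking table.

## Cross-platform comparison

Venn partitions are computed on two layers (detected and significant),
with the "novel" count defined as significant-in-A minus
significant-in-common. Microarray-style tables are filtered at
$p < 0.05$ and $|logFC| > 1$ (strict inequalities); the absolute value is
the default because a one-sided reading discards the down-regulated half,
but a `signed` flag restores the literal reading. Fold-change concordance
uses average-rank Spearman correlation with the t-approximation for the p
value, verified against `cor.test()`. A ΔΔCt utility
($FC = 2^{-\Delta\Delta Ct}$) supports qPCR-style confirmation
arithmetic.

# The synthetic-data generator

`simulateCounts()` emulates the study design the package targets: two
compartments × two donors with per-sample cell counts defaulting to
535/719 and 190/291, ~12,000 genes, negative-binomial counts
($\mathrm{var} = \mu + \phi\mu^2$, shared $\phi = 0.3$), log-normal
baseline gene abundances (sdlog 1.5), log-normal per-cell library sizes
centred near 11,000 UMI (sdlog 0.25), and a planted 18% of genes carrying
a true compartment effect whose $|\log_2 FC|$ magnitudes (normal with
location 2, scale 1, floored at 0.25) span roughly 2–50-fold. Each cell's
expected total equals its drawn library size. Donor batches can receive a
log-scale mean shift, off by default since no batch model is part of the
emulated design. Dropout arises only through the NB zero mass — no extra
zero inflation is modelled.

What the generator does *not* emulate: UMI chemistry and read-level
error, ambient RNA, doublets, cell-cycle or other latent structure,
gene–gene correlation, and mean-dependent dispersion. Passing tests
therefore demonstrate that the procedures are correct and calibrated
under the NB design they assume, not that real disc data satisfy that
design.

Companion generators plant recoverable structure for each downstream
stage: dense network components of requested size and density (connected
by construction, scores above the 0.7 filter), gene sets with one
oversampled from a DEG list, regulon tables with one TF covering a
requested target set, and paired DE tables sharing true fold changes with
platform-specific noise and detection dropout.

# Numerical and design choices

* Strict inequalities wherever the emulated filters state them
  (score > 0.7, NES > 3, p < 0.05, |logFC| > 1, q < 0.05).
* Genes with zero counts everywhere are dropped before testing with a
  reported count; genes zero in both compartments within a round get
  $p = 1$, $\log_2 FC = 0$ for that round.
* Pooling in round $r$ is seeded from a deterministic child seed of
  (run seed, $r$): runs are reproducible end-to-end, rounds draw
  independent partitions, and generators restore the caller's RNG state.
* Compartment grouping for the test is AF vs NP with pooling inside
  (compartment, donor) samples; donor is not a model covariate, matching
  the two-sample design the procedure emulates.
* `McodeComplex` scores are stored exactly and rounded to one decimal
  only for display; `scoreCluster(K_n) = n` exactly.
* Gene symbols are canonicalized (uppercase, trimmed) at every boundary
  because matrisome tables, TF lists and STRING exports mix conventions.

# Problem sizes used by the test-suite benchmarks

The statistical guarantees are verified on simulations sized to be
decisive yet quick: the global-null calibration uses 2,000 genes and 500
cells per compartment (two donors), the planted-recovery benchmark 1,000
genes with 50 four-fold genes, both with pool 20 and $R = 10$; the
determinism check runs the full pipeline twice at 1,000 genes × 400
cells. Topology and MCODE oracles use exhaustive recomputation on graphs
of up to 12 nodes, where enumeration is exact.

# Known limitations

* The common-dispersion model ignores mean–dispersion trends; strongly
  overdispersed individual genes are tested anticonservatively relative
  to a tagwise model.
* The LRT is asymptotic; at very small pseudo-cell counts per group
  (few cells or large pools) calibration degrades.
* Per-cell offsets inside the NB likelihood are not supported; depth is
  removed by per-pseudo-cell scaling before testing, which is exact only
  up to the scaling approximation.
* MCODE implementations differ in minor conventions (loop handling,
  fluff); the scores reported here are pinned to the
  density × node-count definition.

# A minimal end-to-end run

```{r pipeline, eval = FALSE}
res <- runPipeline(list(
  seed = 1,
  simulate = list(nGenes = 1000, cellsPerSample = 100, nDonors = 2,
                  deFraction = 0.1),
  de = list(nPermutations = 10)
), outdir = "run1")
res$de
res$topology$density
```
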