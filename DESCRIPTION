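Package: ivdSCT
Title: Compartment Transcriptomics of the Intervertebral Disc from
    Single-Cell RNA-Seq
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Differential-expression and downstream network analysis for
    two-compartment single-cell RNA-seq designs, modelled on the nucleus
    pulposus (NP) versus annulus fibrosus (AF) architecture of the human
    intervertebral disc. Implements pooled pseudo-cell permutation
    differential expression with negative-binomial likelihood-ratio tests,
    hypergeometric gene-set over-representation, matrisome landscape
    classification, score-filtered protein-protein interaction networks with
    topology metrics and MCODE molecular-complex detection, regulon
    filtering and signature transcription-factor selection, cross-platform
    comparison of differential-expression tables, and a synthetic-data
    generator that emulates the two-donor, two-compartment study design so
    that every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    Matrix,
    igraph,
    S4Vectors,
    SummarizedExperiment,
    SingleCellExperiment,
    jsonlite,
    yaml,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
biocViews: SingleCell, Transcriptomics, DifferentialExpression,
    GeneSetEnrichment, Network, GraphAndNetwork
RoxygenNote: 7.3.3
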