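Package: stateatlas
Title: Automated Interpretation of Chromatin-State Annotations and a
    Conservation-Associated Activity Encyclopedia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the downstream, fully automated half of semi-automated
    genome annotation (SAGA) workflows. Takes per-cell-type chromatin-state
    annotations (Segway/ChromHMM-style integer state labels at fixed
    resolution) together with histone-mark signal tracks, gene models,
    conservation (phyloP), expression, and variant positions, and provides:
    per-state feature extraction (signal means and gene-component
    enrichments); a random-forest classifier that maps states into a unified
    vocabulary of interpretation terms with a low-confidence rule; a
    conservation-associated activity score (CAAS) per state and per genomic
    position; extraction of a cell type-agnostic encyclopedia of maximal
    high-scoring segments; conservation-associated activity plots; and
    evaluation procedures (meta-gene profiles, annotation-overlap matrices,
    expression predictiveness by ridge regression, and SNP enrichment
    curves). A synthetic-data generator emulates all required inputs so the
    entire pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    randomForest,
    ggplot2,
    patchwork,
    stats,
    utils,
    methods,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
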