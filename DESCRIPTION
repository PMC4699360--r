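Package: dietlong
Title: Cohort-Design-Aware Differential Expression and Longevity-Network
    Analysis for Diet-Switch Studies
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for transcriptome analyses of diet-switch longevity
    cohorts: a negative-binomial exact-test differential expression engine
    with TMM normalisation and Benjamini-Hochberg FDR control,
    direction-aware set algebra over per-cohort gene lists (shared
    diet profiles, dietary-memory genes, longevity genes), cross-species
    longevity-network overlap analysis (LAG cores plus first-order PPI
    partners, ortholog mapping with inparalog score thresholds, one-tailed
    Fisher enrichment), qPCR relative-quantification formulas, and a
    synthetic-data generator with planted ground truth so every stage is
    testable end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Matrix,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    optparse
biocViews: RNASeq, DifferentialExpression, Normalization, Network,
    GeneSetEnrichment
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
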