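Package: challengeomics
Title: Integrative Transcriptomics of Placebo-Controlled Food Challenge Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: An end-to-end analysis pipeline for longitudinal whole-blood
    RNA-seq from double-blind placebo-controlled food challenge (crossover)
    studies. Provides count normalization with precision weights, a per-gene
    linear mixed-model likelihood-ratio screen for Time-by-Challenge
    interaction effects, signature-based leukocyte deconvolution with
    permutation p-values, weighted coexpression module detection with
    gene-set enrichment, score-based causal Bayesian network learning with
    eQTL orientation priors, and key driver analysis with hierarchical path
    levels. A synthetic-data generator emulating the crossover design makes
    every stage testable without access to cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    edgeR,
    limma,
    DESeq2,
    lme4,
    e1071,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
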