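Package: AccessTF
Title: Transcription Factor Binding Site Prediction from Chromatin
    Accessibility and Rubric-Based Factor Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Implements a Bayesian network model that predicts in-vivo
    transcription factor binding at genome-wide motif matches by combining
    a logistic prior on motif quality, distance to the nearest
    transcription start site and evolutionary conservation with
    negative-binomial emissions for DNase-seq tag counts around each
    motif, fitted by expectation-maximization. On top of the per-motif
    posterior binding probabilities, a four-criterion scoring rubric
    (TFScore) rank-orders transcription factors by their predicted
    importance for a biological transition, integrating differential
    chromatin accessibility, motif enrichment near differentially
    expressed gene clusters, factor up-regulation and relative expression
    within motif families. Includes time-course differential expression
    calling with permutation-based false discovery rate estimation and
    K-means trajectory clustering, ROC/precision-recall evaluation
    against ChIP-seq peak labels, readers and writers for the standard
    genomic text formats involved, and a seeded synthetic-data generator
    that emulates every input so the full pipeline is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomicRanges,
    SummarizedExperiment,
    rtracklayer,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
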