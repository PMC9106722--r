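Package: pausekit
Title: RNA Polymerase II Pausing, Single-Cell Covariance and Signature-Based
    Survival Stratification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying RNA polymerase II promoter-proximal
    pausing from coverage tracks (traveling-ratio scoring with bins-per-million
    normalization, ranked condition-difference curves, tangent-slope-1 knee
    cutpoints and pause/pause-release gene classification), for detecting
    condition-specific shifts in single-cell gene-gene covariance around an
    anchor gene, and for stratifying patient cohorts by rank-based gene
    signature scores using maximally selected log-rank cutpoints, quadrant
    group assignment and Kaplan-Meier/log-rank testing. Includes seeded
    synthetic-data generators with planted ground truth for every analysis
    track and a config-driven pipeline runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    Matrix,
    survival,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
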