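Package: agewaves
Title: Age-Associated Transcriptome Dynamics in Immune-Cell Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for studying how peripheral immune transcriptomes change
    across the human lifespan. Implements per-gene linear age models with
    Type II sum-of-squares tests, LOESS trajectory estimation with
    hierarchical shape clustering, sliding-window differential expression
    along age (DE-SWAN) with crest detection, empirical-Bayes batch
    adjustment and its quality-control metrics, binned-control gene-set
    scoring and rank-sum differential expression for single cells,
    cell-type proportion/age correlation, Rockwood-style frailty
    classification, and T-cell receptor repertoire clonality indices
    (Gini coefficient, entropy-based clonal expansion, and clone-sharing
    transition potential). Ships a synthetic-cohort generator with known
    ground truth (trajectory archetypes, batch location/scale effects,
    cell-level matrices, and power-law or geometric clonotype tables) so
    every stage can be exercised end-to-end with parameter recovery, plus a
    configurable pipeline runner with reproducible seeding and a run
    manifest.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    sva,
    yaml
Suggests:
    testthat (>= 3.0.0),
    car,
    cluster,
    mclust,
    jsonlite,
    tools
Config/testthat/edition: 3
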