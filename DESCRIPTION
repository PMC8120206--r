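Package: neoscape
Title: Neoantigen Landscape Analysis for Paired Primary and Metastatic Tumors
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Downstream analysis of predicted tumor neoantigens in cohorts
    with paired primary and metastatic samples. Implements neoantigen calling
    and affinity/stability classification from epitope prediction tables,
    cancer-cell-fraction based clonality tracking of mutations between paired
    samples, neoantigen-depletion odds-ratio statistics at the copy-number and
    transcriptional level, intratumor-heterogeneity (MATH) and genome
    instability (wGII) indices, an eight-axis immunogram of the
    cancer-immunity cycle, tumor microenvironment immune typing, and a
    probability-gated random-forest molecular subtype classifier. Ships a
    seed-deterministic synthetic cohort generator with planted depletion,
    immunogenicity-biased neoantigen reduction and three-subtype expression
    structure for parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
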