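Package: gutage
Title: Gut Microbiome and Serum Metabolome Analysis of Aging Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for linking the gut metagenome to the serum metabolome in
    aging cohorts. Implements canopy-based co-abundance clustering of gene
    profiles into co-abundance gene groups (CAGs) and metagenomic species
    (MGSs), rule-based taxonomic annotation from alignment best-hit tables,
    enterotyping and beta-diversity statistics, PERMANOVA effect-size
    decomposition with redundancy removal, Q2-driven forward-selection random
    forests for predicting metabolites from MGS abundances, bidirectional
    causal mediation screening (microbe to metabolite to age), clinical
    formulas (four-branch CKD-EPI eGFR, qPCR telomere T/S ratio), and a
    synthetic cohort generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    cluster,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    MASS,
    purrr,
    randomForest,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vegan
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
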