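Package: pdacsubtype
Title: Molecular Subtyping of Pancreatic Ductal Adenocarcinoma from Bulk
    Expression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for unsupervised molecular subtyping of
    pancreatic ductal adenocarcinoma (PDAC) from bulk RNA-seq expression.
    Provides consensus clustering with stability curves and the gap statistic
    for choosing the number of subtypes; a gene-signature subtype classifier
    built from a SAM differential filter, AUC-based marker ranking and
    nearest-shrunken-centroid (PAM) training; concordance analysis between
    subtyping systems via hypergeometric enrichment and a Jaccard-weighted
    subtype network; species-split patient-derived-xenograft (PDX) compartment
    analysis with dedicated epithelial and stromal classifiers; and the
    supporting survival and clinical association statistics. A synthetic-cohort
    generator emulates the statistical structure the pipeline assumes so every
    stage is testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    survival,
    sva,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    cluster,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
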