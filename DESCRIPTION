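Package: fusionscreen
Title: Reference-Gene Correlation Screening and Drug-Target
    Prioritization for Fusion-Positive Cancer Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for characterizing gene-fusion expression subtypes in
    bulk tumor transcriptomes, modeled on the PTPRK-RSPO3 fusion subtype
    of colorectal cancer. Implements a case-control resampled Pearson
    correlation screen against a reference gene (median absolute
    correlation across repeated control draws) with permutation-based
    calibration of the selection cutoff, hypergeometric
    over-representation analysis with Benjamini-Hochberg FDR control and
    collapsing of enriched pathways into curated cancer meta-pathways,
    cancer-gene annotation, and construction of a direction-aware
    actionable drug-target network from CIViC- and OncoKB-style evidence
    tables. A synthetic-cohort generator with planted correlation
    modules, fixture pathway databases and drug knowledgebases makes the
    whole pipeline testable at desk scale without any external download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
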