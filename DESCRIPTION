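Package: tissuespec
Title: Tissue-Specificity Classification of Expression Profiles and
    Diagnostic Evaluation of Immunohistochemistry Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies genes of a multi-tissue FPKM expression matrix into
    tissue-specificity categories (enriched, group-enriched, enhanced,
    expressed-in-all, mixed, not detected) relative to a target tissue,
    computes tissue-specific scores and a combinatorial group-enrichment
    search, summarises inter-sample correlation structure on a log2 scale,
    and builds the tissue co-enrichment network implied by group-enriched
    genes. A companion module evaluates candidate tissue biomarkers scored
    by immunohistochemistry against histology with two-by-two contingency
    statistics (Pearson chi-square, likelihood-ratio G, phi), sensitivity,
    specificity and ROC AUC. Seeded simulators generate expression matrices
    with planted category structure and staining cohorts with known
    diagnostic properties so every stage of the pipeline can be validated
    against ground truth.
License: MIT
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
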