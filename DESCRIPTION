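Package: liquidcascade
Title: Liquid-Biopsy Cancer Detection and Typing with Boosted-Tree Cascades
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Multi-analyte liquid-biopsy classification pipeline for cancer
    detection and cancer-type assignment from protein biomarker panels, a
    cfDNA mutation (omega) score and clinical covariates. Implements
    correlation plus mutual-information feature reduction, iterative
    gain-importance feature selection with gradient-boosted trees,
    random-search hyperparameter tuning, balanced-accuracy-weighted
    cross-validation ensembling, a multi-level binary cascade for typing,
    a full confusion-matrix/ROC metric suite, an assay cost model, and a
    seeded synthetic-cohort generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
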