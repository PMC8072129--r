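Package: fldscreen
Title: Fatty Liver Disease Screening from Routine Physical Examination Records
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible pipeline for non-invasive fatty liver disease (FLD)
    screening from routine physical-examination tables: supervised ChiMerge
    discretization of age against the ultrasound label, median imputation
    stratified by age bin and sex, genetic-programming synthesis of composite
    biomarker features with Spearman rank-correlation fitness, and a
    gradient-boosted tree classifier evaluated by ROC AUC, split-count feature
    importance, incremental-feature curves and false-negative profiling.
    Includes a seeded synthetic cohort generator emulating the statistical
    structure of hospital examination records, so the whole pipeline is
    testable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    withr,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
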