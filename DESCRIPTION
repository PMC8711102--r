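Package: rfcourse
Title: Domain-Wise Random Forest Prediction of Clinical Course with
    Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Tools for predicting two-year recovery outcomes in psychiatric
    cohorts from mixed-type baseline questionnaire and biomarker items.
    Implements matched-fold repeated stratified cross-validation of random
    forest classifiers per predictor domain (clinical, psychological,
    sociodemographic, biological, lifestyle), leakage-safe train-fold
    median/mode imputation with skip-pattern ("not applicable") recoding,
    label-permutation significance tests of mean AUC, paired sign-flip
    comparison of domains on matched folds, permutation variable importance
    with per-iteration FDR correction and consistency selection, subgroup
    and transfer-label evaluation, and a synthetic mixed-type cohort
    generator with planted domain-concentrated signal for end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    ranger,
    stats,
    utils,
    withr
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
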