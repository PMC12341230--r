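Package: afstream
Title: Atrial Fibrillation Risk Stratification After Stroke from Continuous ECG Monitoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to predict atrial fibrillation detected after acute ischaemic
    stroke from continuous electrocardiogram monitoring at the stroke-unit
    bedside. Provides a synthetic stroke-unit cohort generator (labelled beat
    streams, AF alarm intervals, lead-II-like raw ECG, clinical covariates),
    beat-stream cleaning and eligibility rules (AF excision with buffer,
    ectopic-beat removal, short-gap interpolation, 5-minute RR segmentation,
    5.12-second raw-ECG segmentation), a 19-feature heart-rate-variability bank
    with hourly aggregation, ensemble classifiers under patient-level nested
    cross-validation, a small 1-D convolutional network for raw-ECG segments,
    Bayesian odds-product fusion of model probabilities, an AS5F-style clinical
    benchmark, and an evaluation layer with bootstrap ROC-AUC confidence
    intervals, fold-wise DeLong tests aggregated by Fisher's method, and
    specificity-anchored clinical thresholds.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    ranger,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
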