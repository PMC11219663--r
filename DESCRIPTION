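Package: ihpredict
Title: Early Prediction of Intracranial Hypertension from Neuromonitoring Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Pipeline for forecasting intracranial hypertension (IH) and severe
    IH in traumatic brain injury patients from the first six hours of invasive
    intracranial pressure monitoring. Provides a synthetic cohort simulator with
    planted ground truth, 12-second epoch resampling and moving-average
    smoothing of ICP/MAP/CPP/pulse-amplitude channels, cerebrovascular indices
    (PRx, RAP) as moving Pearson correlations, nonlinear complexity features
    (sample entropy, Lempel-Ziv complexity), threshold-duration event labeling,
    and a random-forest workflow with recursive feature elimination,
    cross-validated hyperparameter search, variance-inflation screening,
    Youden-index cutoffs, fivefold cross-validation, and permutation/Gini
    feature importances.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    randomForest,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
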