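Package: hrstress
Title: Day-Long Wearable Heart-Rate Signal Processing and Daily Stress Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for asking whether day-long heart-rate
    streams from wrist wearables can indicate day-level mental stress.
    Irregular timestamped readings are assembled into participant-days,
    filtered by an hour-coverage rule, regularized to fixed-length day
    vectors by per-minute maximum resampling, carry-forward/backward gap
    filling and window-maximum downsampling, and transformed into raw,
    Fourier half-spectrum and Morlet-wavelet (with per-day PCA) feature
    modalities. Classifiers are compared under balanced class weights or
    SMOTE, with or without PCA, using repeated stratified ten-fold
    cross-validation, and modalities are compared with a Kruskal-Wallis /
    Dunn-Bonferroni / one-sample t-test framework. A synthetic
    wearable-stream generator with circadian structure, adaptive sampling
    density, activity bursts and configurable stress effects makes the
    whole pipeline testable without confidential study data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    glmnet,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xgboost
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
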