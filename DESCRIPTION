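Package: cinephys
Title: Physiological Markers and Prediction of Short-Film Ratings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multimodal psychophysiological feature extraction and
    rating-prediction pipeline for film-viewing experiments. Simulates a
    synthetic cohort (18-channel EEG, photoplethysmography, facial EMG,
    electrodermal activity) with planted, configurable effect structure;
    extracts EEG band-power, engagement, arousal and valence indices,
    eleven signal complexity and entropy measures, a full
    heart-rate-variability feature set, facial-EMG means and skin
    conductance response statistics, all rest-baseline corrected; runs
    genre comparisons, trialwise feature-rating correlations with
    Benjamini-Hochberg correction, and a leave-one-film-out
    cross-validated prediction of integer film ratings (regression and
    binary classification) with outlier masking, chained-equation
    imputation and impurity-importance feature selection inside each fold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    signal,
    ranger,
    xgboost,
    e1071,
    rpart,
    class,
    pROC,
    data.table,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
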