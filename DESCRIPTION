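Package: dyadsync
Title: Dyadic Physiological Synchrony and Engagement Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidy pipeline for estimating conversational engagement of a
    dyad from the two participants' peripheral physiology. Ingests
    multichannel recordings (ECG, skin conductance, respiration, skin
    temperature), detects physiological events (R-waves, breaths, skin
    conductance responses), extracts per-interval individual features
    (time-domain heart-rate variability, electrodermal and respiratory
    summaries) and dyadic synchrony features (dynamic time warping distance,
    nonlinear interdependence, band-averaged magnitude-squared coherence,
    zero-lag cross-correlation), and estimates self-reported engagement with
    leave-interval-out and leave-dyad-out crossvalidated tree-based
    regression against median baselines. Includes a calibrated synthetic
    dyad-cohort generator with known latent engagement for end-to-end
    validation, plus descriptive statistics (one-way random-effects
    intraclass correlation, median/IQR summaries, trait-error Spearman
    correlations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    signal,
    rpart,
    randomForest,
    xgboost,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
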