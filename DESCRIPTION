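Package: affectlearn
Title: Sensor-Based Prediction of Affective Learning States and Outcomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Analysis pipeline for predicting self-reported affective learning
    states and outcomes from consumer-grade wearable sensor data. Simulates
    learning sessions with embedded experience sampling, EEG band-power
    streams (5 electrodes x 5 canonical bands) and electrodermal activity;
    emulates on-device FFT band-power preprocessing; masks questionnaire
    response windows and segments streams around each experience sample;
    extracts summary features and spectral indices (beta/alpha, engagement,
    hemispheric laterality); and evaluates ridge and gradient-boosting
    regressors against mean-of-others baselines under leave-one-out and
    leave-one-proband-out cross-validation, with paired t-test and effect
    size comparisons and Cronbach's alpha scale reliability.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
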