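Package: enoseCP
Title: Conformal Prediction for Electronic-Nose Sensor-Array Classification
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Reliability-aware classification of multichannel gas-sensor
    (electronic nose) recordings. Simulates metal-oxide sensor response
    curves with first-order reaction kinetics, performs baseline
    normalisation, extracts per-sensor transient features (maximum
    response, integral response, and exponential-moving-average
    derivative maxima), and classifies feature vectors with inductive
    and bootstrap-aggregated conformal predictors built on support
    vector machine or random forest nonconformity scores. Evaluation
    tools cover stratified cross-validation, forced-prediction accuracy,
    calibration (validity) and efficiency curves, and per-prediction
    confidence and credibility indicators.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    randomForest,
    jsonlite,
    withr,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
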