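Package: mcdtscreen
Title: Motor-Cognitive Dual-Task Screening from Wearable Inertial Sensors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for motor-and-cognitive
    dual-task (MCDT) screening of mild cognitive impairment from wearable
    inertial measurement units. Generates synthetic cohorts of tri-axial
    accelerometer and gyroscope recordings for finger-tapping, toe-tapping
    and 10-m walking tasks under graded cognitive load (counting backwards),
    conditions the signals with zero-phase Butterworth filtering, segments
    tap cycles and gait strides, extracts tapping and gait kinematic
    features, computes per-feature dual-task cost, screens features with
    nonparametric group tests and Spearman correlation against MMSE, and
    fits age-adjusted logistic regression models evaluated by ROC/AUC and
    Youden-optimal operating points.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    pracma,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    ggplot2,
    readr
Config/testthat/edition: 3
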