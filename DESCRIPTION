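Package: throwsense
Title: Throw Detection, Signal Features, and Workload Models from Wrist-Worn IMU Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An analysis pipeline for quantifying handball throwing workload
    from a wrist-worn inertial measurement unit (IMU). Resamples multi-rate
    9-DoF recordings onto uniform grids, detects peak-rotation throw events by
    thresholding the gyroscope y-axis, extracts a 201-feature windowed signal
    inventory per throw, classifies approach and wind-up type and predicts
    peak ball velocity under leave-one-subject-out cross-validation with four
    model families, and compares models and accelerometer measurement ranges
    with Greenhouse-Geisser-corrected repeated-measures ANOVA and
    Holm-adjusted contrasts. A seeded multi-rate IMU simulator generates
    sessions with ground-truth events, labels, and velocities so every stage
    is testable without access to raw athlete data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    yaml,
    randomForest,
    e1071,
    xgboost
Suggests:
    testthat (>= 3.0.0),
    car,
    jsonlite,
    withr
Config/testthat/edition: 3
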