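Package: claudigait
Title: Smartphone IMU Gait Analysis for Detecting Intermittent Claudication
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for detecting the onset of intermittent
    claudication from pocket-smartphone inertial sensor logs. Reads irregular
    9-axis IMU CSV logs, resamples them onto a uniform 50 Hz grid, low-pass
    filters the channels, estimates phone orientation by Madgwick
    accelerometer-gyroscope-magnetometer fusion and rotates acceleration into
    an Earth-fixed frame, detects heel contacts and toe-offs by singular
    spectrum analysis of the vertical and anterior-posterior acceleration,
    slices walks into overlapping 10 s windows, extracts 155 time- and
    frequency-domain gait features per window, and trains tree-ensemble
    classifiers under record-wise and patient-wise train/test splits. A
    synthetic pocket-IMU gait simulator with full ground truth makes every
    stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    zoo,
    jsonlite,
    yaml,
    pROC,
    rlang,
    xgboost,
    randomForest,
    ranger
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
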