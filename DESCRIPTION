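Package: gaitrec
Title: Human Gait Activity Recognition from Wearable Sensor Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for recognizing human gait activities and freezing-of-gait
    episodes from lower-limb wearable sensor recordings sampled at 40 Hz
    (accelerometer, gyroscope, complementary-filter fusion angles and
    strain-gauge muscle channels). Provides complementary-filter sensor
    fusion, min-max feature normalization, analytic-Morlet continuous
    wavelet featurization (27 log-spaced bins over 0.2-20 Hz per channel),
    a synthetic labelled gait-recording generator, nine per-sample
    classifiers behind one train/predict contract - including a causal
    convolutional-recurrent network and its attention variant with five
    parallel convolution streams merged by learnable additive weights -
    and the standard evaluation protocols: leave-one-segment-out
    cross-validation, sensor-group ablation, chronological 60/40
    freezing-of-gait detection and detection-delay measurement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    e1071,
    jsonlite,
    nnet,
    rpart,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
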