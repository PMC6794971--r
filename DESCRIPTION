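Package: mindcnn
Title: State-of-Mind Classification from Wearable Biosignals with a
    Multichannel 1-D Convolutional Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting affective state (baseline, amusement, stress,
    meditation, recovery) from multimodal wearable recordings. Converts raw
    chest-worn ADC streams (ECG, EMG, respiration) and wrist-worn streams
    (blood volume pulse, triaxial accelerometer) to SI units, harmonizes
    heterogeneous sampling rates via a 700 Hz common grid with 70-sample block
    aggregation to 10 Hz, engineers peak-based minute features and subject-level
    accelerometer statistics, and classifies samples with a five-channel 1-D
    convolutional neural network whose kernel length adapts to each channel's
    feature count. Includes randomized 70/20/10 and leave-one-subject-out
    cross-validation regimes, Adam/RMSprop/SGD optimizers, Gaussian-process
    sequential model-based hyperparameter optimization with an
    expected-improvement acquisition, per-class evaluation reports, and a
    synthetic multimodal recording generator so the full pipeline runs without
    any external dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    lhs,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
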