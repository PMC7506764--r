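Package: imurehab
Title: Exercise Recognition and Repetition Counting from a Wrist-Worn Inertial Sensor
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for recognizing local-muscular-endurance rehabilitation
    exercises and counting repetitions from a single wrist-worn 6-axis inertial
    sensor (3D accelerometer + 3D gyroscope). Provides a seeded synthetic
    wrist-IMU trial generator with known ground-truth repetition counts; sliding
    window segmentation with a 48-dimensional time/frequency feature extractor
    and PCA retention at 99% accumulated variance; a grid-searched SVM/kNN/
    random-forest/MLP classification harness with per-class precision, recall
    and F1 evaluation; a Savitzky-Golay peak-detection repetition counter with
    dominant-axis selection and threshold cut-offs; deterministic rasterization
    of 4-second six-channel windows into fixed-size grayscale images with binary
    Peak/NoPeak labelling; and a compact AlexNet-style convolutional network
    engine for multiclass and binary classification with a transition-halving
    repetition counter. Includes a command-line entry point for simulation,
    featurization, training, evaluation and counting.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    e1071,
    class,
    randomForest,
    nnet,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
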