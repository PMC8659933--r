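Package: armasym
Title: Bilateral Wrist Accelerometry Analysis for Detecting Unilateral Arm Paresis
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of bilateral wrist-worn triaxial
    accelerometer recordings for the detection of unilateral arm paresis,
    the hallmark motor deficit of stroke. Provides a synthetic cohort
    generator for 24-hour bilateral recordings with graded one-sided
    attenuation, the full preprocessing chain (per-axis Butterworth
    high-pass filtering, vector magnitude, moving-average smoothing,
    decimation, gravity normalisation, inter-arm synchronisation and
    tail trimming), sliding-window segmentation with arm-swap
    augmentation, fourteen between-arm asymmetry features, classical
    classifiers (RBF support vector machine, k-nearest neighbours,
    random forest) and a reference one-dimensional convolutional
    network, subject-level cross-validated grid search with four-fold
    ensembling, ROC/AUC evaluation, and Friedman plus post-hoc Nemenyi
    model comparison with critical-difference diagrams.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    class,
    e1071,
    graphics,
    jsonlite,
    randomForest,
    signal,
    stats,
    tools,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
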