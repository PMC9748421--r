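Package: palpebral
Title: Non-Invasive Hemoglobin Estimation from Eyelid Images by Label
    Distribution Learning
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale, fully tested implementation of a two-stage
    pipeline that estimates blood hemoglobin concentration from eye
    photographs. Stage one restricts the image to the palpebral
    conjunctiva (the causal, Hb-bearing region) via a binary mask;
    stage two regresses hemoglobin with a compact convolutional network
    whose output is a probability distribution over a discrete support
    grid of candidate Hb values, trained with a Kullback-Leibler
    divergence plus L1 composite loss (label distribution learning).
    Because clinical eyelid datasets are private, the package ships a
    synthetic eye-image simulator with ground-truth masks and a
    controllable confounding structure, SMOTE-style balancing for the
    skewed continuous label, instance-mask evaluation metrics
    (AP/AR/mIoU), regression metrics with bootstrap confidence
    intervals, feature-engineering baselines, and an ablation pipeline
    contrasting masked, cropped, and whole-image inputs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    png,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    rpart,
    e1071,
    caret,
    randomForest,
    xgboost
Config/testthat/edition: 3
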