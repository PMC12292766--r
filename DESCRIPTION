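Package: coxmorph
Title: Landmark-Based Coxal Bone Morphometrics and Sex Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for sex estimation from 3D coxal (hip) bone landmarks.
    Defines a 34-landmark schema with readers for long-format CSV and MeshLab
    PickedPoints files, computes a battery of 33 standard coxal measurements
    (linear distances, vertex angles, and point-to-line heights) and all 561
    interlandmark distances, imputes missing landmarks by iterative
    Bayesian-ridge regression, quantifies intraobserver landmarking error via
    technical errors of measurement (TEM/rTEM), runs normality-gated group
    comparisons for sex, laterality, and age, and trains regularized logistic
    regression and linear support vector machine sex classifiers with
    stratified splits, repeated cross-validation, and recursive feature
    elimination. A calibrated synthetic cohort generator reproduces published
    dimorphic summary statistics for end-to-end testing of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    minpack.lm,
    glmnet,
    e1071,
    ranger,
    xml2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
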