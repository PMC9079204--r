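Package: scintigrade
Title: Automated Perugini Grading of Cardiac Uptake in Bone Scintigraphy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: End-to-end pipeline for automated detection and Perugini-grade
    classification of transthyretin-amyloidosis (ATTR) cardiac uptake in 2D
    bone scintigraphy. Provides a seeded synthetic phantom generator for
    whole-body and planar thoracic studies, anatomically informed thoracic
    cropping with log-transform and pixel-wise z-score normalization, two
    compact convolutional network architectures (with and without residual
    skip connections) plus canonical comparison backbones, stratified
    cross-validated training with augmentation and inverse-frequency class
    weights, ROC/precision/recall evaluation including a bone-metastasis
    subgroup analysis, and maximum-activation-map interpretability.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    pROC,
    jsonlite,
    png,
    tiff,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
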