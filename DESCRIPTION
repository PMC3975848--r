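Package: vmil
Title: Predicting Visuomotor Learning State from Pre-Trial EEG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools to test whether trial-to-trial motor performance
    (normalized time-to-target) can be predicted from EEG recorded before
    movement onset. Provides a synthetic multi-subject EEG generator with a
    latent learning curve that jointly drives behavior and cortical
    oscillatory power, common-average referencing and Butterworth filtering,
    pooled PCA followed by second-order blind identification (SOBI) via
    joint approximate diagonalization of time-lagged covariance matrices,
    automated artifact-component rejection, per-trial log-bandpower
    features, cross-subject random-forest prediction under
    leave-one-subject-out cross-validation, a modified coefficient of
    determination for low-pass-filtered targets, a group-level
    trial-permutation test, and model-interpretation procedures
    (out-of-bag permutation variable importance and value-substitution
    influence curves).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    signal,
    ranger,
    jsonlite,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
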