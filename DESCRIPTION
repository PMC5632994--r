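Package: ipcorr
Title: Sample Selection Bias Correction for Classifiers Trained on
    Stratified Two-Phase Case-Control Samples
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for training binary classifiers on stratified samples from
    two-phase case-control studies and predicting on unbiased populations.
    Implements seven bias-correction strategies built on integer
    inverse-probability (IP) weights: no correction, IP oversampling, IP
    bagging, costing, stratified SMOTE, stochastic IP oversampling and
    parametric IP bagging. The last two restore the within-stratum covariance
    structure that plain replication destroys, either by adding calibrated
    Gaussian noise to replicated observations or by a stratum-wise parametric
    bootstrap of size n'. Corrections plug into logistic regression (with or
    without two-way interactions), a kernel-density naive Bayes classifier and
    a random forest whose per-tree resampling step is replaced by the
    correction itself. A simulation module generates synthetic populations
    with rare outcome and rare exposure, draws two-phase stratified samples,
    and evaluates classifier-correction combinations by AUC with linear-model
    and DeLong comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    pROC,
    purrr,
    ranger,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
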