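Package: jadestack
Title: Stacked Ensemble Identification of Stimulus-Evoked Time Series
    with Adaptive Differential Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Nonlinear system identification of stimulus-evoked
    single-input/single-output biomedical time series (such as cortical
    EEG responses to periodic wrist-joint perturbations) with a stacked
    generalization ensemble: five diverse base regressors are
    grid-searched by signal-wise cross-validation over a lagged NARX
    design matrix with engineered input features, their out-of-fold
    predictions feed a Cubist-style rule-based meta-learner, and the
    meta-learner's committees/neighbors hyperparameters are tuned by
    self-adaptive differential evolution (JADE, current-to-pbest/1 with
    an optional external archive) maximising cross-validated variance
    accounted for. Includes one-step and recursive multi-step
    prediction, VAF/RMSE metrics with Friedman and Nemenyi
    critical-difference model comparison, a residual-whiteness check, a
    multisine-driven synthetic benchmark generator with a known
    achievable noise floor, and packaged reference result tables.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    kernlab,
    nnet,
    stats,
    utils,
    xgboost
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
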