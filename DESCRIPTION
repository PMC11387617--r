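Package: distillsurv
Title: Sparse Survival Models via Teacher-Student Knowledge Distillation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits sparse right-censored survival models by knowledge
    distillation (pre-conditioning): a semiparametric teacher model (Cox
    proportional hazards with Breslow or Efron tie corrections, or
    kernel-smoothed profile-likelihood accelerated failure time and
    extended hazards models) is fitted first, and an elastic-net linear
    student is then regressed on the teacher's linear predictors along a
    regularization path. Includes cross-validated selection of the
    regularization hyperparameter by the minimum, one-standard-error and
    penalized cross-validated likelihood rules, in-house baseline
    cumulative-hazard and survival-function estimators, survival metrics
    (Harrell's, Uno's and Antolini's concordance, Brier and integrated
    Brier scores with inverse-probability-of-censoring weights), a
    synthetic-data generator with Weibull baselines, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    survival,
    glmnet
Config/testthat/edition: 3
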