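---
title: "Methods: sparse survival models by teacher-student distillation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sparse survival models by teacher-student distillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

Sparse linear survival models — a Cox model with a lasso or elastic-net
penalty being the canonical example — select a subset of predictors while
modelling time to event. Penalized partial-likelihood fits are, however,
sensitive to the regularization hyperparameter: small changes in the
penalty move the solution between badly underfitted and densely
overfitted models, and the penalty that minimizes cross-validation error
need not be the penalty a practitioner wants.

`distillsurv` takes the two-step *knowledge distillation*
(pre-conditioning) route instead:

1. a flexible, well-performing **teacher** is fitted to the
   right-censored training data by maximum likelihood;
2. the teacher's linear predictors *on the training rows* become the
   response of an ordinary elastic-net linear regression — the
   **student** — fitted along a full regularization path.

Because the student solves a least-squares problem against an
uncensored, continuous target, its path is cheap, stable, and (when the
teacher is good) its predictive performance converges to the teacher's as
regularization is relaxed. Estimation (the teacher) and feature selection
(the student) are thereby separated.

# Data model

A dataset is `n` triples `(t_i, delta_i, x_i)` with strictly positive
follow-up times, a binary event indicator (1 = event, 0 = right
censored) and `p` numeric covariates. `surv_dataset()` validates and
stores rows in ascending time order with events preceding censored
records at tied times, so risk sets `R(t) = {j : t_j >= t}` are suffixes
of the stored order and include subjects censored exactly at an event
time. Left truncation, interval censoring, time-varying covariates,
competing risks and case weights are out of scope.

# Teacher families

## Cox proportional hazards

The log partial likelihood is implemented with both the Breslow and the
Efron correction for tied event times; for `d` tied events the Efron
denominator removes `(l-1)/d` of the tied subjects' weight from the
`l`-th factor. Risk sums are computed after subtracting `max(eta)` from
the linear predictor, so arbitrarily large predictors cannot overflow.
The two corrections coincide exactly on tie-free data, and the gradient
entries always sum to zero (each event contributes +1, each distinct
event time removes its event count through the risk weights) — both
properties are asserted in the test suite.

## Smoothed accelerated failure time and extended hazards

The extended hazards (EH) model is parameterized as

    lambda(t | x) = lambda0(t * exp(x' b1)) * exp(x' b2),

containing the Cox model (`b1 = 0`) and the accelerated failure time
(AFT) model (`b1 = b2`) as exact special cases; both reductions are
tested as identities. With residuals `e_i = log t_i + x_i' b1`, the
kernel-smoothed profile log-likelihood is

    (1/n) * sum over events i of [ x_i'(b2 - b1)
        + log( (1/(n a)) sum over events j of phi((e_j - e_i)/a) )
        - log( (1/n) sum over all j of exp(x_j'(b2 - b1))
                                       * Phi((e_j - e_i)/a) ) ]

with `phi`/`Phi` the standard normal density and CDF and `a > 0` the
bandwidth. A derivation note on the linear term: the EH event
contribution is `delta [log lambda0(r) + x' b2]` on the transformed time
`r = t exp(x' b1)`; writing `lambda0` through the hazard of the
log-scale residual gives `log lambda0(r) = log mu(e) - log r`, and
`x' b2 - log r = x'(b2 - b1) - log t`, whose parameter-free part is
dropped. Writing the linear term as `x' b2` alone (a form sometimes seen
with the Cox case in mind, where the two coincide) adds a spurious
`sum(delta * x' b1)` that makes the objective unbounded for AFT/EH; with
the `x'(b2 - b1)` term every event's risk sum contains its own weight
`exp(v_i) * Phi(0)`, which caps the objective. The package uses the
bounded form; its exact analytic gradients (including the kernel
chain-rule terms through the residuals in both sums) are verified against
central finite differences family-by-family.

**Self-term.** The `j = i` term of the kernel density sum is included by
default (`include_self = TRUE`): it bounds the density factor below by
`phi(0)/(n a)`, so the likelihood is finite — and, with the linear term
above, bounded above — at any finite parameter value. The switch is
exposed for users who prefer the leave-one-out density.

**Bandwidth.** Default `a = 1.30 * n^(-1/5)`: the standard `n^(-1/5)`
rate for kernel estimation of a density-like object; the constant 1.30
is a package default chosen once to be of order one on log-time scales
typical of survival data, and is user-overridable everywhere.

## Fitting and high-dimensional teachers

`fit_teacher()` maximizes the family objective by BFGS with analytic
gradients from a zero start, followed by a Newton refinement that uses a
finite-difference Jacobian of the analytic gradient; convergence is
declared when the gradient max-norm falls below `tol` (default `1e-7`),
otherwise the fit is returned flagged with a warning. For `p >= n` the
user must enable exactly one of:

* a **PCA reduction** (`reduction`): the teacher is fitted on
  principal-component scores of the standardized covariates — by default
  the smallest rank explaining 90% of variance, capped at
  `min(n - 1, 64)` — and coefficients are composed back to the raw
  feature scale, or
* a **ridge penalty** (`ridge`), added as `ridge * ||beta||^2 / 2` to the
  negative log-likelihood.

The PCA route is what the package's own high-dimensional experiments
use. Zero-variance features receive unit scale with a warning rather
than an error.

# Baselines and survival functions

All survival-function estimation is in-house. For Cox fits the baseline
cumulative hazard uses Breslow increments `d_t / sum_{R(t)} exp(eta_j)`
(Nelson–Aalen at `eta = 0`) or their Efron tie-corrected analogue; the
tie rule used for fitting is reused by default. For AFT/EH the baseline
lives on the transformed scale `r_i = t_i exp(eta1_i)` and is a
Breslow-type estimator with risk weights `exp(eta2_j - eta1_j)`.
Survival predictions compose right-continuous step functions:
`S(t|x) = exp(-H0(t) exp(eta))` for Cox and
`S(t|x) = exp(-H0(t exp(eta1)) exp(eta2 - eta1))` for AFT/EH, clamped to
`[0, 1]` after exponentiation. Step functions jump *at* event times, are
0 before the first knot, and are evaluated right-continuously; no
smoothing between knots is applied, and the default evaluation grid is
the distinct event times of the fitting data.

# The student and its regularization path

The student solves

    min over (b0, b)  (1/(2n)) ||y - b0 - X b||^2
                      + lambda (alpha ||b||_1 + (1 - alpha)/2 ||b||_2^2)

by cyclic soft-thresholded coordinate descent (compiled; glmnet-style
active-set iteration with a confirming full sweep) on internally
standardized features, with coefficients returned on the original scale.
The grid of `L = 100` penalties descends geometrically from
`lambda_max = max_j |<x_j, y - mean(y)>| / (n alpha)` — the smallest
penalty whose solution is exactly empty — to `eps * lambda_max`
(`eps = 0.01` when `n > p`, else `0.05`). `lambda_max` carries a `1e-9`
relative nudge so the head of the path stays on the all-zero side of the
KKT boundary under floating-point rounding; KKT residuals are checked at
every path point. Path fits are warm-started from the previous penalty.

For EH teachers, which emit a pair of linear predictors, two independent
students share one grid (the element-wise larger of the two single-target
grids, so both paths start empty); the model's reported active-set size
is the size of the union of the two supports.

# Cross-validation and selecting the penalty

`kd_cross_validate()` repeats a k-fold split (default 5 folds, 5
repeats), stratified by the event indicator and driven by a single seed.
Within each fold the **teacher is refitted on the training folds** and
its training-row predictions are distilled; the penalty grid is computed
once on the full data so path indices align across folds. Held-out
scores are teacher-family log-likelihoods of the student's predictions,
in one of three forms:

* `vvh` (default): the Verweij–van Houwelingen contrast
  `loglik(eta, all rows) - loglik(eta, training rows)`, the established
  remedy for the instability of small-fold partial likelihoods;
* `basic`: the log-likelihood of the held-out fold alone;
* `linear_predictor`: held-out predictions pooled across folds and
  scored once per repeat.

Three selection rules are applied to the per-penalty mean scores (ties
always break toward the sparser model):

* **min** — the maximizer of the mean score;
* **1se** — the largest penalty within one standard error of the best;
* **pcvl** — the maximizer of
  `mean(l) - N(l) * (mean(l_min) - mean(l_null)) / N(l_min)`, the
  cross-validated score penalized per active coefficient.

A structural property of pcvl worth knowing: the penalized profile is
*equal by construction* at the null index and at the min index, so pcvl
returns either an interior index (when the score gain is concave in the
active-set size) or the null model (when the gain is near-linear, in
which case no intermediate sparsity level earns its coefficients); it
never returns the min index itself.

`fit_kd()` refits teacher and student on all rows at the selected
penalty and re-estimates the baseline *from the student's own linear
predictors* under the teacher family's semantics, so the returned sparse
model is a self-contained survival model.

# Evaluation metrics

Harrell's concordance counts pairs `(i, j)` with `t_i < t_j` and subject
`i` an event (plus event-vs-censored pairs tied on time); risk-score
ties earn 1/2; event-event pairs tied on time are incomparable. Uno's
concordance reweights pairs by `G(t_i-)^-2`, where `G` is the reverse
Kaplan–Meier estimate of the censoring survival fitted on a stated
reference (training) split, truncated at a horizon `tau` defaulting to
the largest test event time. Antolini's concordance compares whole
survival curves at the earlier subject's event time. The Brier score at
`t` is the IPCW-weighted squared error between predicted survival and
observed status, and the integrated Brier score is its trapezoidal
average over (by default) the distinct test event times between the 5th
and 95th percentiles of test follow-up — clipping the grid avoids the
unstable tails of the inverse-probability weights. Subjects with a zero
IPCW weight are dropped from the affected time point with a warning.
All pairwise metrics are validated against brute-force pair/loop
implementations at machine precision.

# The synthetic-data generator

`simulate_survival()` draws standard-normal covariates with optional
exchangeable correlation, then inverts the family's closed-form survival
function under a Weibull baseline (shape `k`, scale `s`):

* Cox: `S(t|x) = exp(-(t/s)^k e^{x'b})`
* EH: `S(t|x) = exp(-((t e^{x'b1})/s)^k e^{x'(b2-b1)})`
* AFT: EH with `b1 = b2`.

The Weibull baseline is chosen because all three families then have
exact inverse-transform samplers. Censoring is exponential and
independent of covariates; its rate is calibrated by bisection so the
expected censored fraction matches the request (achieved rates land
within a few percent at moderate `n`). Defaults — shape 1.5, scale 1,
30% censoring, uncorrelated covariates — describe a mildly increasing
hazard typical of chronic-disease cohorts and are fixed once as the
package's reference conditions.

What the generator does *not* emulate: the heavy-tailed,
block-correlated covariance of real transcriptomic data, covariate-
dependent censoring, measurement error, and batch structure. Tests
passing on these simulations therefore demonstrate correctness of the
estimators and the pipeline under the stated generating models, not
performance on any particular clinical dataset.

# Problem sizes used in the checks

The packaged checks run parameter recovery at `n = 4000` (5 Cox
covariates, 3 AFT covariates, 30% censoring), distillation convergence
at `n = 500, p = 100` with five true signals, selection-rule behavior
over 20 seeds at `n = 120, p = 20`, and metric/solver oracles at
`n <= 200`; these sizes give stable Monte-Carlo behavior while keeping a
full run in the order of a minute or two.

# Known limitations

* The EH maximum-likelihood surface is not concave; fits far from the
  scale of the defaults may require an initial value or a small ridge.
* pcvl can return the empty model when the cross-validated gain is
  near-linear in the active-set size (see above) — this is the rule's
  honest answer, not a failure mode.
* The 1se rule frequently selects very sparse, sometimes empty, models
  on flat score profiles; users wanting a fixed sparsity level should
  read it off the path directly instead.
* Alpha (the elastic-net mix) is a single user-set value; tuning it is
  deliberately out of scope.
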