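# Evaluation metrics: Harrell's, Uno's (IPCW) and Antolini's
# (time-dependent) concordance, and the (integrated) Brier score with
# inverse-probability-of-censoring weights.
#
# Pair conventions (the dominant ones in the field, stated here because
# they vary between implementations): a pair (i, j) is comparable when
# t_i < t_j and subject i had the event, or when t_i == t_j, i had the
# event and j was censored; pairs tied on time with both events are
# incomparable. Ties in the predicted risk score count 1/2.

#' Kaplan-Meier estimate of the censoring survival function
#'
#' Reverse Kaplan-Meier: the roles of events and censorings are swapped,
#' giving the IPCW weight function G(t) used by Uno's concordance and the
#' Brier score. The at-risk set at a time includes every subject whose
#' follow-up reaches it.
#'
#' @param data a [surv_dataset()] (typically the training split).
#' @return A [step_function()] with `left_value = 1`, non-increasing in
#'   `[0, 1]`.
#' @export
censoring_distribution <- function(data) {
  stopifnot(inherits(data, "surv_dataset"))
  tt <- data$time
  cens <- 1 - data$event
  new_grp <- !duplicated(tt)
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  n_at_risk <- (data$n:1)[first]
  d_cens <- as.vector(rowsum(cens, grp))
  keep <- d_cens > 0
  if (!any(keep)) {
    return(step_function(numeric(0), numeric(0), left_value = 1))
  }
  surv <- cumprod(1 - d_cens[keep] / n_at_risk[keep])
  step_function(tt[first][keep], surv, left_value = 1)
}

# comparability and concordance masks shared by the pairwise metrics
pair_masks <- function(time, event) {
  comp <- (outer(time, time, "<") & event) |
    (outer(time, time, "==") & outer(event, 1 - event, "*") == 1)
  diag(comp) <- FALSE
  comp
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs whose predicted risk orders them
#' correctly, counting risk ties 1/2 (see the pair conventions above).
#'
#' @param eta predicted risk score (higher = shorter expected survival).
#' @param time,event follow-up times and event indicators, aligned to
#'   `eta`.
#' @return Scalar in `[0, 1]`.
#' @export
harrell_c <- function(eta, time, event) {
  stopifnot(length(eta) == length(time), length(time) == length(event))
  comp <- pair_masks(time, event)
  npairs <- sum(comp)
  if (npairs == 0) stop("no comparable pairs", call. = FALSE)
  conc <- outer(eta, eta, ">")[comp]
  ties <- outer(eta, eta, "==")[comp]
  (sum(conc) + 0.5 * sum(ties)) / npairs
}

#' Uno's IPCW concordance
#'
#' Concordance reweighted by the inverse squared censoring survival
#' `G(t_i-)^-2` estimated on a training split, restricted to event times
#' before the horizon `tau`. With no censoring in the training split it
#' reduces exactly to [harrell_c()] restricted to `t_i < tau`.
#'
#' @param train_data a [surv_dataset()] used to estimate the censoring
#'   distribution.
#' @param test_data a [surv_dataset()] being evaluated.
#' @param eta_test risk scores aligned to the canonical rows of
#'   `test_data`.
#' @param tau truncation horizon; default the largest test event time.
#' @return Scalar concordance.
#' @export
uno_c <- function(train_data, test_data, eta_test, tau = NULL) {
  stopifnot(inherits(test_data, "surv_dataset"))
  G <- censoring_distribution(train_data)
  tt <- test_data$time; ev <- test_data$event
  if (is.null(tau)) tau <- max(tt[ev == 1])
  Gm <- eval_step(G, tt, left_limit = TRUE)
  w <- ifelse(ev == 1 & tt < tau, 1 / Gm^2, 0)
  if (any(!is.finite(w))) {
    warning("G(t-) = 0 for some event times; those pairs are excluded")
    w[!is.finite(w)] <- 0
  }
  # pairs: t_i < t_j, i an event before tau (ties on eta count 1/2)
  lt <- outer(tt, tt, "<")
  W <- matrix(w, length(tt), length(tt)) * lt
  conc <- outer(eta_test, eta_test, ">") + 0.5 * outer(eta_test, eta_test, "==")
  den <- sum(W)
  if (den == 0) stop("no comparable pairs", call. = FALSE)
  sum(W * conc) / den
}

#' Antolini's time-dependent concordance
#'
#' Uses the whole predicted survival curve: a pair with `t_i < t_j` and
#' subject i an event is concordant when `S_i(t_i) < S_j(t_i)`; ties in
#' the evaluated survival count 1/2. For proportional-hazards predictions
#' (curves that never cross) it equals [harrell_c()] on the linear
#' predictor.
#'
#' @param surv a `surv_curve_matrix` whose rows align with the canonical
#'   rows of `test_data`.
#' @param test_data a [surv_dataset()].
#' @return Scalar concordance.
#' @export
antolini_c <- function(surv, test_data) {
  stopifnot(inherits(surv, "surv_curve_matrix"),
            inherits(test_data, "surv_dataset"))
  tt <- test_data$time; ev <- test_data$event
  n <- length(tt)
  Sti <- eval_surv_matrix(surv, tt)   # n x n: S_k(t_i) in column i
  comp <- (outer(tt, tt, "<") & ev)
  diag(comp) <- FALSE
  npairs <- sum(comp)
  if (npairs == 0) stop("no comparable pairs", call. = FALSE)
  Si <- matrix(diag(Sti), n, n)          # S_i(t_i) by row i
  Sj <- t(Sti)                           # row i, col j: S_j(t_i)
  conc <- (Si < Sj)[comp]
  ties <- (Si == Sj)[comp]
  (sum(conc) + 0.5 * sum(ties)) / npairs
}

#' Brier score at a time point (IPCW)
#'
#' `BS(t)` is the mean squared difference between the predicted survival
#' probability at `t` and the observed status, inverse-weighted by the
#' censoring survival: subjects with an event by `t` contribute
#' `S(t|x)^2 / G(t_i-)`, subjects still under follow-up contribute
#' `(1 - S(t|x))^2 / G(t)`. Subjects whose weight denominator is zero are
#' dropped from that time point with a warning.
#'
#' @param surv a `surv_curve_matrix` aligned with `test_data`.
#' @param test_data a [surv_dataset()].
#' @param G censoring distribution [step_function()] (reverse KM from the
#'   training split; see [censoring_distribution()]).
#' @param t evaluation time (scalar).
#' @return Scalar in `[0, 1]`.
#' @export
brier_score <- function(surv, test_data, G, t) {
  stopifnot(inherits(surv, "surv_curve_matrix"),
            inherits(test_data, "surv_dataset"), length(t) == 1)
  tt <- test_data$time; ev <- test_data$event
  n <- length(tt)
  St <- drop(eval_surv_matrix(surv, t))
  Gm <- eval_step(G, tt, left_limit = TRUE)
  Gt <- eval_step(G, t)
  had_event <- tt <= t & ev == 1
  at_risk <- tt > t
  contrib <- numeric(n)
  bad <- (had_event & Gm == 0) | (at_risk & Gt == 0)
  if (any(bad)) {
    warning(sum(bad), " subject(s) with zero IPCW weight dropped at t = ", t)
  }
  ok <- !bad
  contrib[ok & had_event] <- (St[ok & had_event]^2) / Gm[ok & had_event]
  contrib[ok & at_risk] <- ((1 - St[ok & at_risk])^2) / Gt
  sum(contrib) / n
}

#' Integrated Brier score
#'
#' Trapezoidal average of [brier_score()] over a time grid, normalized by
#' the grid span. The default grid is the distinct test event times
#' between the 5th and 95th percentile of test follow-up, avoiding the
#' unstable IPCW tails.
#'
#' @inheritParams brier_score
#' @param t_grid increasing evaluation grid (at least 2 points).
#' @return Scalar in `[0, 1]`.
#' @export
integrated_brier_score <- function(surv, test_data, G, t_grid = NULL) {
  if (is.null(t_grid)) {
    qs <- stats::quantile(test_data$time, c(0.05, 0.95), names = FALSE)
    t_grid <- sort(unique(test_data$time[test_data$event == 1 &
                                           test_data$time >= qs[1] &
                                           test_data$time <= qs[2]]))
  }
  if (length(t_grid) < 2) {
    stop("'t_grid' must contain at least two time points", call. = FALSE)
  }
  bs <- vapply(t_grid, function(t) brier_score(surv, test_data, G, t),
               numeric(1))
  span <- diff(range(t_grid))
  sum(diff(t_grid) * (utils::head(bs, -1) + utils::tail(bs, -1)) / 2) / span
}

#' Evaluate a fitted model on a test split
#'
#' Convenience wrapper computing Harrell's, Uno's and Antolini's
#' concordance and the integrated Brier score for a fitted teacher or
#' student model.
#'
#' @param model a `teacher_fit` or `student_model`.
#' @param test_data a [surv_dataset()].
#' @param train_data dataset for the censoring distribution and Uno
#'   weights; defaults to `test_data`.
#' @return Named numeric vector.
#' @export
evaluate_model <- function(model, test_data, train_data = test_data) {
  eta <- predict_linear(model, test_data$X)
  risk <- if (is.list(eta)) eta$eta2 else eta
  surv <- predict_survival(model, test_data$X)
  G <- censoring_distribution(train_data)
  c(harrell_c = harrell_c(risk, test_data$time, test_data$event),
    uno_c = uno_c(train_data, test_data, risk),
    antolini_c = antolini_c(surv, test_data),
    ibs = integrated_brier_score(surv, test_data, G))
}
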