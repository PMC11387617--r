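# Baseline cumulative-hazard and conditional survival-function estimation
# for the Cox, AFT and EH families. Step functions jump AT event times and
# are evaluated right-continuously, matching the risk-set convention of
# surv_dataset.

#' Breslow/Efron baseline cumulative hazard for a Cox model
#'
#' Knots are the distinct event times. Breslow increments are
#' `d_t / sum_{j in R(t)} exp(eta_j)`; Efron increments replace the
#' denominator by the progressively tie-corrected sums used in the Efron
#' partial likelihood. At `eta = 0` and with the Breslow rule this is the
#' Nelson-Aalen estimator.
#'
#' @param data a [surv_dataset()].
#' @param eta linear predictor in canonical row order.
#' @param ties `"breslow"` or `"efron"` (identical on tie-free data).
#' @return A [step_function()] cumulative hazard (`left_value = 0`).
#' @export
breslow_cumulative_hazard <- function(data, eta,
                                      ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  stopifnot(inherits(data, "surv_dataset"))
  q <- cox_group_quantities(eta, data, ties)
  eg <- q$event_groups
  knots <- data$time[q$first][eg]
  inc <- q$a[eg] * exp(-q$m)
  step_function(knots, cumsum(inc), left_value = 0)
}

#' Baseline cumulative hazard on the transformed time scale (AFT/EH)
#'
#' For the EH model the baseline lives on the transformed scale
#' `r_i = t_i * exp(eta1_i)`. The estimator is Breslow-type with risk
#' weights `exp(eta2_j - eta1_j)`:
#' `Lambda0(r) = sum_{r_i <= r, event} 1 / sum_{j: r_j >= r_i} exp(eta2_j - eta1_j)`.
#' With `eta1 = eta2` this serves the AFT model; with `eta1 = 0` it reduces
#' exactly to [breslow_cumulative_hazard()] at `eta = eta2`.
#'
#' @param data a [surv_dataset()].
#' @param eta1,eta2 linear predictors in canonical row order.
#' @return A [step_function()] cumulative hazard on the transformed scale.
#' @export
transformed_scale_cumulative_hazard <- function(data, eta1, eta2) {
  stopifnot(inherits(data, "surv_dataset"))
  n <- data$n
  if (length(eta1) != n || length(eta2) != n) {
    stop("'eta1' and 'eta2' must have length n = ", n, call. = FALSE)
  }
  r <- data$time * exp(eta1)
  v <- eta2 - eta1
  m <- max(v)
  ord <- order(r, -data$event)
  rs <- r[ord]; evs <- data$event[ord]; ws <- exp(v[ord] - m)
  new_grp <- !duplicated(rs)
  grp <- cumsum(new_grp)
  first <- which(new_grp)
  risk <- rev(cumsum(rev(ws)))[first]          # per distinct r value
  d <- as.vector(rowsum(evs, grp))
  eg <- which(d > 0)
  knots <- rs[first][eg]
  inc <- d[eg] / risk[eg] * exp(-m)
  step_function(knots, cumsum(inc), left_value = 0)
}

#' Conditional survival curves from a fitted model
#'
#' Evaluates the model's conditional survival function on a time grid for
#' new subjects. Cox: `S(t|x) = exp(-Lambda0(t) * exp(eta))`. AFT/EH:
#' `S(t|x) = exp(-Lambda0(t * exp(eta1)) * exp(eta2 - eta1))`, with the
#' baseline evaluated right-continuously and equal to 0 before its first
#' knot. Values are clamped to `[0, 1]` after exponentiation.
#'
#' @param model a `teacher_fit` or `student_model` carrying a baseline.
#' @param X_new covariate matrix for the new subjects (raw feature scale).
#' @param times positive, increasing evaluation grid; defaults to the
#'   baseline knots (the distinct event times of the fitting data).
#' @return An object of class `surv_curve_matrix`: list with `times` and
#'   the `n_subjects x n_times` matrix `S`; rows align with `X_new`.
#' @export
predict_survival <- function(model, X_new, times = NULL) {
  if (is.null(model$baseline)) {
    stop("model carries no baseline cumulative hazard; fit or attach one",
         call. = FALSE)
  }
  if (is.null(times)) times <- model$baseline$knots
  times <- as.numeric(times)
  if (length(times) == 0 || any(times <= 0) || any(diff(times) <= 0)) {
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  }
  eta <- predict_linear(model, X_new)
  H0 <- model$baseline
  if (is.list(eta)) {             # EH / AFT pair semantics
    eta1 <- eta$eta1; eta2 <- eta$eta2
  } else if (model$family == "aft") {
    eta1 <- eta2 <- eta
  } else {
    eta1 <- NULL
  }
  if (is.null(eta1)) {            # Cox
    H <- outer(exp(eta), eval_step(H0, times))
  } else {
    res <- vapply(seq_along(eta1),
                  function(i) eval_step(H0, times * exp(eta1[i])),
                  numeric(length(times)))
    M <- if (is.matrix(res)) t(res) else matrix(res, ncol = 1L)
    H <- exp(eta2 - eta1) * M
  }
  S <- pmin(pmax(exp(-H), 0), 1)
  structure(list(times = times, S = S), class = "surv_curve_matrix")
}

#' @export
print.surv_curve_matrix <- function(x, ...) {
  cat("<surv_curve_matrix>", nrow(x$S), "subjects x", length(x$times),
      "times\n")
  invisible(x)
}

# step-function evaluation of stored curves at arbitrary times
eval_surv_matrix <- function(surv, t) {
  idx <- findInterval(t, surv$times)
  cbind(1, surv$S)[, idx + 1L, drop = FALSE]
}

#' Write survival curves to CSV
#'
#' First column `id`, remaining columns the survival probabilities at each
#' grid time (grid written in the header).
#'
#' @param surv a `surv_curve_matrix`.
#' @param path output path.
#' @param ids optional subject identifiers (default row numbers).
#' @return `path`, invisibly.
#' @export
write_survival_csv <- function(surv, path, ids = NULL) {
  stopifnot(inherits(surv, "surv_curve_matrix"))
  if (is.null(ids)) ids <- seq_len(nrow(surv$S))
  df <- data.frame(id = ids, surv$S, check.names = FALSE)
  names(df) <- c("id", paste0("t=", format(surv$times, trim = TRUE)))
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}
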