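# Synthetic right-censored survival data with known ground truth.
#
# A Weibull baseline (shape k, scale s) is used for all three families
# because each then has a closed-form inverse survival function:
#   Cox: S(t|x) = exp(-(t/s)^k e^{x'b})
#   EH:  S(t|x) = exp(-((t e^{x'b1})/s)^k e^{x'b2 - x'b1})
#   AFT: EH with b1 = b2.
# Censoring is exponential, independent of the covariates, with its rate
# calibrated by bisection so that the expected censored fraction matches
# the request.

#' Simulate right-censored survival data
#'
#' @param family `"cox"`, `"aft"` or `"eh"` (for `"cox"` either Cox family
#'   label is also accepted).
#' @param n number of subjects.
#' @param p number of covariates; `beta` is zero-padded to length `p`.
#' @param beta true coefficient vector; for `"eh"` a list
#'   `list(beta1, beta2)`.
#' @param baseline list with Weibull `shape` (k > 0) and `scale` (s > 0).
#' @param censor_rate requested censored fraction in `[0, 1)`.
#' @param covariate_corr exchangeable pairwise correlation of the standard
#'   normal covariates, in `[0, 1)`.
#' @param seed optional integer seed; the same seed reproduces the dataset
#'   exactly.
#' @return List with `data` (a [surv_dataset()]) and `truth` (class
#'   `sim_truth`): the generating family, coefficients, baseline,
#'   requested and achieved censoring rates, calibrated censoring rate
#'   parameter, and seed.
#' @export
simulate_survival <- function(family = c("cox", "aft", "eh",
                                         "cox_breslow", "cox_efron"),
                              n, p, beta,
                              baseline = list(shape = 1.5, scale = 1),
                              censor_rate = 0.3, covariate_corr = 0,
                              seed = NULL) {
  family <- match.arg(family)
  if (family %in% c("cox_breslow", "cox_efron")) family <- "cox"
  k <- baseline$shape; s <- baseline$scale
  stopifnot(k > 0, s > 0, censor_rate >= 0, censor_rate < 1,
            covariate_corr >= 0, covariate_corr < 1)
  if (!is.null(seed)) set.seed(seed)

  pad <- function(b) {
    b <- as.numeric(b)
    if (length(b) > p) stop("'beta' longer than p", call. = FALSE)
    c(b, rep(0, p - length(b)))
  }
  if (family == "eh") {
    if (!is.list(beta) || length(beta) != 2) {
      stop("for family 'eh', 'beta' must be list(beta1, beta2)",
           call. = FALSE)
    }
    beta1 <- pad(beta[[1]]); beta2 <- pad(beta[[2]])
  } else {
    beta1 <- beta2 <- pad(beta)
    if (family == "cox") beta1 <- rep(0, p)
  }

  Z <- matrix(stats::rnorm(n * p), n, p)
  if (covariate_corr > 0) {
    z0 <- stats::rnorm(n)
    Z <- sqrt(1 - covariate_corr) * Z + sqrt(covariate_corr) * z0
  }
  eta1 <- drop(Z %*% beta1)
  eta2 <- drop(Z %*% beta2)
  # inverse-transform from S(t|x); for all families
  # t = e^{-eta1} * s * (-log U * e^{-(eta2 - eta1)})^{1/k}
  U <- stats::runif(n)
  T_event <- exp(-eta1) * s * (-log(U) * exp(-(eta2 - eta1)))^(1 / k)

  if (censor_rate == 0) {
    time <- T_event; event <- rep(1, n); rate <- 0
  } else {
    # P(censored) = E[1 - exp(-c T)] over the drawn event times; monotone
    # increasing in c, so calibrate c by bisection
    f <- function(c) mean(1 - exp(-c * T_event)) - censor_rate
    lo <- 0; hi <- 1 / stats::median(T_event)
    steps <- 0
    while (f(hi) < 0) {
      hi <- hi * 2; steps <- steps + 1
      if (steps > 50) {
        stop("requested censor_rate unreachable", call. = FALSE)
      }
    }
    for (i in 1:50) {
      mid <- (lo + hi) / 2
      if (f(mid) < 0) lo <- mid else hi <- mid
    }
    rate <- (lo + hi) / 2
    C <- stats::rexp(n, rate = rate)
    time <- pmin(T_event, C)
    event <- as.numeric(T_event <= C)
  }
  truth <- structure(
    list(family = family,
         beta = if (family == "eh") list(beta1 = beta1, beta2 = beta2)
                else beta2,
         baseline = list(shape = k, scale = s),
         censor_rate_requested = censor_rate,
         censor_rate_achieved = mean(1 - event),
         censoring_rate_param = rate,
         seed = seed),
    class = "sim_truth"
  )
  list(data = surv_dataset(time, event, Z), truth = truth)
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>", x$family, " censoring",
      sprintf("%.1f%% (requested %.1f%%)\n",
              100 * x$censor_rate_achieved, 100 * x$censor_rate_requested))
  invisible(x)
}
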