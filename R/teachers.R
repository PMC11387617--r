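# Teacher models: Cox PH (Breslow/Efron), and the kernel-smoothed
# profile-likelihood AFT and extended hazards (EH) models.
#
# EH parameterization: hazard lambda(t|x) = lambda0(t e^{x'b1}) e^{x'b2}.
# AFT is the special case b1 = b2; Cox is b1 = 0. These reductions are
# exercised directly by the test suite.

TEACHER_FAMILIES <- c("cox_breslow", "cox_efron", "aft", "eh")

#' Default kernel bandwidth
#'
#' `1.30 * n^(-1/5)`: the standard `n^(-1/5)` rate for kernel smoothing of
#' a density-like object, with a fixed constant. The constant is a package
#' default, overridable everywhere a bandwidth is accepted.
#'
#' @param n number of subjects.
#' @return Positive scalar bandwidth.
#' @export
default_bandwidth <- function(n) 1.30 * n^(-1 / 5)

check_bandwidth <- function(bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1 ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop("'bandwidth' must be a positive number", call. = FALSE)
  }
  bandwidth
}

#' Kernel-smoothed profile log-likelihood of the extended hazards model
#'
#' Smoothed profile log-likelihood in the two EH linear predictors, with a
#' Gaussian kernel of bandwidth `a`. With residuals
#' `e_i = log(t_i) + x_i' beta1`, the value is
#' \deqn{\frac1n \sum_{i:\delta_i=1} \Big[ x_i'(\beta_2-\beta_1)
#'   + \log\frac{1}{na}\sum_{j:\delta_j=1} \phi\big(\tfrac{e_j-e_i}{a}\big)
#'   - \log\frac1n \sum_j e^{x_j'(\beta_2-\beta_1)}
#'       \Phi\big(\tfrac{e_j-e_i}{a}\big) \Big].}
#' The linear term `x'(beta2 - beta1)` is what remains of the EH event
#' contribution `delta [log lambda0(r) + x' beta2]` after the baseline
#' hazard on the transformed scale `r = t exp(x' beta1)` is expressed
#' through the hazard of the log-scale residual and the parameter-free
#' `-log t` is dropped; it also bounds the objective above, since every
#' event's risk sum contains its own weight. The `j = i` self-term is
#' included in the kernel density sum by default, which keeps the
#' likelihood finite for any finite parameters.
#'
#' @param beta1 coefficient vector of the time-scale linear predictor.
#' @param beta2 coefficient vector of the hazard-scale linear predictor.
#' @param data a [surv_dataset()].
#' @param bandwidth positive kernel bandwidth; default [default_bandwidth()].
#' @param include_self include the `j = i` kernel self-term (default `TRUE`).
#' @return The smoothed profile log-likelihood (scalar).
#' @seealso [aft_profile_loglik()] (`beta1 == beta2`), [smoothed_gradient()].
#' @export
eh_profile_loglik <- function(beta1, beta2, data, bandwidth = NULL,
                              include_self = TRUE) {
  stopifnot(inherits(data, "surv_dataset"))
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(data$n)
  check_bandwidth(bandwidth)
  eta1 <- drop(data$X %*% beta1)
  eta2 <- drop(data$X %*% beta2)
  if (data$p == 0) eta1 <- eta2 <- rep(0, data$n)
  eh_loglik_eta(eta1, eta2, data, bandwidth, include_self)
}

#' Smoothed AFT profile log-likelihood
#'
#' The accelerated failure time model as the `beta1 == beta2` special case
#' of [eh_profile_loglik()].
#'
#' @param beta coefficient vector.
#' @inheritParams eh_profile_loglik
#' @return The smoothed profile log-likelihood (scalar).
#' @export
aft_profile_loglik <- function(beta, data, bandwidth = NULL,
                               include_self = TRUE) {
  eh_profile_loglik(beta, beta, data, bandwidth, include_self)
}

#' Smoothed EH/AFT log-likelihood in the linear predictors
#'
#' Low-level entry point taking linear predictors instead of coefficients;
#' used by cross-validation scoring, where student predictions play the
#' role of the linear predictors. AFT corresponds to `eta1 == eta2`.
#'
#' @param eta1,eta2 linear predictors aligned to the canonical row order.
#' @inheritParams eh_profile_loglik
#' @return Scalar log-likelihood.
#' @export
eh_loglik_eta <- function(eta1, eta2, data, bandwidth = NULL,
                          include_self = TRUE) {
  stopifnot(inherits(data, "surv_dataset"))
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(data$n)
  check_bandwidth(bandwidth)
  if (length(eta1) != data$n || length(eta2) != data$n) {
    stop("'eta1' and 'eta2' must have length n = ", data$n, call. = FALSE)
  }
  .eh_loglik_eta_cpp(log(data$time), as.integer(data$event),
                     as.numeric(eta1), as.numeric(eta2),
                     bandwidth, include_self)
}

# gradient of eh_loglik_eta in (eta1, eta2); list of two n-vectors
eh_grad_eta <- function(eta1, eta2, data, bandwidth, include_self = TRUE) {
  .eh_grad_eta_cpp(log(data$time), as.integer(data$event),
                   as.numeric(eta1), as.numeric(eta2),
                   bandwidth, include_self)
}

#' Analytic gradient of the smoothed AFT/EH log-likelihood
#'
#' Exact gradient of [aft_profile_loglik()] (a p-vector) or
#' [eh_profile_loglik()] (a list with components `beta1` and `beta2`),
#' including the kernel chain-rule terms through the residuals in both the
#' density and the risk sums.
#'
#' @param family `"aft"` or `"eh"`.
#' @param params coefficient vector (aft) or list/concatenation of
#'   `beta1` and `beta2` (eh).
#' @inheritParams eh_profile_loglik
#' @return p-vector (aft) or `list(beta1 =, beta2 =)` (eh).
#' @export
smoothed_gradient <- function(family = c("aft", "eh"), params, data,
                              bandwidth = NULL, include_self = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(data, "surv_dataset"))
  if (is.null(bandwidth)) bandwidth <- default_bandwidth(data$n)
  check_bandwidth(bandwidth)
  p <- data$p
  if (family == "aft") {
    beta1 <- beta2 <- as.numeric(params)
  } else {
    if (is.list(params)) {
      beta1 <- as.numeric(params[[1]]); beta2 <- as.numeric(params[[2]])
    } else {
      params <- as.numeric(params)
      beta1 <- params[seq_len(p)]; beta2 <- params[p + seq_len(p)]
    }
  }
  if (p == 0) {
    eta1 <- eta2 <- rep(0, data$n)
  } else {
    eta1 <- drop(data$X %*% beta1); eta2 <- drop(data$X %*% beta2)
  }
  g <- eh_grad_eta(eta1, eta2, data, bandwidth, include_self)
  g1 <- drop(crossprod(data$X, g$g1))
  g2 <- drop(crossprod(data$X, g$g2))
  if (family == "aft") g1 + g2 else list(beta1 = g1, beta2 = g2)
}

#' Standardized principal-component reduction of a covariate matrix
#'
#' Centers and scales each feature, then computes principal-component
#' scores by singular value decomposition. Used to precondition
#' high-dimensional teacher fits; the returned projection composes with
#' reduced-space coefficients so that linear prediction on the raw
#' features remains well-defined.
#'
#' @param X numeric matrix (n x p).
#' @param rank a positive integer number of components (at most
#'   `min(n, p)`), or a fraction in (0, 1): the smallest rank whose
#'   cumulative explained variance reaches that fraction.
#' @param max_rank cap on the rank when `rank` is a fraction
#'   (default `min(n - 1, 64)`).
#' @return An object of class `dr_projection`: `center` and `scale`
#'   p-vectors, orthonormal `loadings` (p x r), the reduced score matrix
#'   `scores` (n x r), and `explained_variance`. Zero-variance features get
#'   scale 1 with a warning.
#' @export
reduce_dimensions <- function(X, rank = 0.9, max_rank = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  if (any(scale == 0)) {
    warning("zero-variance feature(s) at column(s) ",
            paste(utils::head(which(scale == 0), 5), collapse = ", "),
            "; scale set to 1")
    scale[scale == 0] <- 1
  }
  Xs <- sweep(Xc, 2, scale, "/")
  sv <- svd(Xs)
  ev <- sv$d^2 / sum(sv$d^2)
  if (length(rank) != 1 || !is.finite(rank) || rank <= 0) {
    stop("'rank' must be a positive integer or a fraction in (0,1)",
         call. = FALSE)
  }
  if (rank < 1) {
    r <- which(cumsum(ev) >= rank)[1L]
    if (is.na(r)) r <- length(ev)
    cap <- if (is.null(max_rank)) min(n - 1L, 64L) else max_rank
    r <- min(r, cap, sum(sv$d > sv$d[1] * 1e-12))
  } else {
    r <- as.integer(rank)
    if (r > min(n, p)) stop("'rank' exceeds min(n, p)", call. = FALSE)
  }
  r <- max(r, 1L)
  structure(
    list(center = center, scale = scale,
         loadings = sv$v[, seq_len(r), drop = FALSE],
         scores = sv$u[, seq_len(r), drop = FALSE] %*%
           diag(sv$d[seq_len(r)], r),
         explained_variance = ev),
    class = "dr_projection"
  )
}

# apply a dr_projection to new raw features
project_features <- function(projection, X) {
  Xs <- sweep(sweep(as.matrix(X), 2, projection$center), 2,
              projection$scale, "/")
  Xs %*% projection$loadings
}

# compose reduced-space coefficients back to the raw feature scale;
# returns list(beta = p-vector, offset = scalar) with
# eta(x) = x' beta + offset reproducing scores %*% beta_reduced
compose_projection <- function(projection, beta_reduced) {
  beta <- drop(projection$loadings %*% beta_reduced) / projection$scale
  list(beta = beta, offset = -sum(projection$center * beta))
}

# quasi-Newton maximization with analytic gradient; BFGS restarts until
# progress stalls, then Newton polishing with a finite-difference Jacobian
# of the analytic gradient to push the gradient max-norm below tol
bfgs_maximize <- function(fn, gr, init, tol = 1e-7, max_iter = 500) {
  par <- init
  val <- fn(par)
  if (!is.finite(val)) stop("objective not finite at the initial value",
                            call. = FALSE)
  for (round in 1:10) {
    res <- stats::optim(par, fn = function(b) -fn(b),
                        gr = function(b) -gr(b),
                        method = "BFGS",
                        control = list(maxit = max_iter, reltol = 1e-14))
    par <- res$par
    gnorm <- max(abs(gr(par)))
    improved <- (-res$value) - val
    val <- -res$value
    if (gnorm < tol || (round > 1 && improved < 1e-13)) break
  }
  if (gnorm >= tol) {
    pol <- newton_polish(fn, gr, par, tol)
    if (pol$value >= val || pol$grad_norm < gnorm) {
      par <- pol$par; val <- pol$value; gnorm <- pol$grad_norm
    }
  }
  list(par = par, value = val, grad_norm = gnorm,
       converged = gnorm < tol)
}

# Newton refinement near the maximum; the Hessian is the forward-difference
# Jacobian of the analytic gradient, with step halving on the objective
newton_polish <- function(fn, gr, par, tol, max_steps = 10) {
  val <- fn(par)
  g <- gr(par)
  q <- length(par)
  for (s in seq_len(max_steps)) {
    if (max(abs(g)) < tol) break
    H <- matrix(0, q, q)
    h <- 1e-6 * pmax(1, abs(par))
    for (j in seq_len(q)) {
      pj <- par; pj[j] <- pj[j] + h[j]
      H[, j] <- (gr(pj) - g) / h[j]
    }
    H <- (H + t(H)) / 2
    step <- tryCatch(solve(H, g), error = function(e) NULL)
    if (is.null(step) || any(!is.finite(step))) break
    ok <- FALSE
    for (halving in 0:20) {
      cand <- par - step / 2^halving
      vc <- fn(cand)
      if (is.finite(vc) && vc >= val - 1e-12 * max(1, abs(val))) {
        par <- cand; val <- vc; g <- gr(par); ok <- TRUE
        break
      }
    }
    if (!ok) break
  }
  list(par = par, value = val, grad_norm = max(abs(g)))
}

#' Fit a teacher survival model by maximum likelihood
#'
#' Maximizes the family's log-likelihood (Cox partial likelihood with the
#' requested tie correction, or the kernel-smoothed AFT/EH profile
#' likelihood) by quasi-Newton iteration with analytic gradients, and
#' attaches the matching baseline cumulative hazard estimate.
#'
#' @param data a [surv_dataset()].
#' @param family one of `"cox_breslow"`, `"cox_efron"`, `"aft"`, `"eh"`.
#' @param bandwidth kernel bandwidth for aft/eh; default
#'   [default_bandwidth()]. Ignored for the Cox families.
#' @param reduction optional dimension reduction passed to
#'   [reduce_dimensions()] as `rank`: an integer rank or a variance
#'   fraction in (0, 1). Required (or `ridge`) when `p >= n`.
#' @param ridge optional ridge penalty `ridge * ||beta||^2 / 2` added to
#'   the negative log-likelihood; at most one of `reduction`/`ridge` may be
#'   active.
#' @param tol convergence tolerance on the gradient max-norm.
#' @param max_iter maximum quasi-Newton iterations per restart.
#' @param init initial coefficient vector (default all zero).
#' @param include_self include the `j = i` kernel self-term in the aft/eh
#'   density sums (default `TRUE`, which keeps the likelihood finite at
#'   any parameter value; exposed as a switch).
#' @return An object of class `teacher_fit` with elements `family`, `beta`
#'   (raw-feature-scale coefficients; for `"eh"` a list with `beta1` and
#'   `beta2`), `offset` (the constant completing the raw-scale linear
#'   predictor when a projection is used), `projection`, `bandwidth`,
#'   `baseline` (a [step_function()] cumulative hazard), `loglik`,
#'   `converged` and `grad_norm`.
#' @export
fit_teacher <- function(data, family = TEACHER_FAMILIES, bandwidth = NULL,
                        reduction = NULL, ridge = 0, tol = 1e-7,
                        max_iter = 500, init = NULL, include_self = TRUE) {
  family <- match.arg(family)
  stopifnot(inherits(data, "surv_dataset"))
  n <- data$n; p <- data$p
  if (!is.null(reduction) && ridge > 0) {
    stop("use either 'reduction' or 'ridge', not both", call. = FALSE)
  }
  if (p >= n && is.null(reduction) && ridge <= 0) {
    stop("p >= n: enable a PCA 'reduction' or a 'ridge' penalty to fit ",
         "a high-dimensional teacher", call. = FALSE)
  }
  is_cox <- family %in% c("cox_breslow", "cox_efron")
  ties <- if (family == "cox_efron") "efron" else "breslow"
  if (is_cox) {
    bandwidth <- NULL
  } else if (is.null(bandwidth)) {
    bandwidth <- default_bandwidth(n)
  }

  projection <- NULL
  Z <- data$X
  if (!is.null(reduction) && p > 0) {
    projection <- reduce_dimensions(data$X, rank = reduction)
    Z <- projection$scores
  }
  q <- ncol(Z)
  zdata <- data
  zdata$X <- Z
  zdata$p <- q

  npar <- if (family == "eh") 2L * q else q
  if (is.null(init)) init <- rep(0, npar)
  if (length(init) != npar) stop("'init' has the wrong length", call. = FALSE)

  pen <- function(b) ridge * sum(b^2) / 2
  pen_grad <- function(b) ridge * b

  if (q == 0) {
    par <- numeric(0); conv <- TRUE; gnorm <- 0
    val <- if (is_cox) cox_partial_loglik(rep(0, n), data, ties) else
      eh_loglik_eta(rep(0, n), rep(0, n), data, bandwidth)
  } else {
    if (is_cox) {
      fn <- function(b) cox_partial_loglik(drop(Z %*% b), zdata, ties) - pen(b)
      gr <- function(b) drop(crossprod(Z, cox_partial_gradient(
        drop(Z %*% b), zdata, ties))) - pen_grad(b)
    } else if (family == "aft") {
      fn <- function(b) eh_profile_loglik(b, b, zdata, bandwidth,
                                          include_self) - pen(b)
      gr <- function(b) smoothed_gradient("aft", b, zdata, bandwidth,
                                          include_self) - pen_grad(b)
    } else {
      fn <- function(b) eh_profile_loglik(b[seq_len(q)], b[q + seq_len(q)],
                                          zdata, bandwidth, include_self) -
        pen(b)
      gr <- function(b) {
        g <- smoothed_gradient("eh", b, zdata, bandwidth, include_self)
        c(g$beta1, g$beta2) - pen_grad(b)
      }
    }
    opt <- bfgs_maximize(fn, gr, init, tol = tol, max_iter = max_iter)
    par <- opt$par; conv <- opt$converged; gnorm <- opt$grad_norm
    val <- opt$value + pen(par)
    if (!conv) {
      warning("teacher fit did not reach gradient tolerance (final ",
              "max-norm ", format(gnorm, digits = 3), ")")
    }
  }

  to_raw <- function(bz) {
    if (is.null(projection)) {
      list(beta = bz, offset = 0)
    } else {
      compose_projection(projection, bz)
    }
  }
  if (family == "eh") {
    c1 <- to_raw(par[seq_len(q)]); c2 <- to_raw(par[q + seq_len(q)])
    beta <- list(beta1 = c1$beta, beta2 = c2$beta)
    offset <- c(c1$offset, c2$offset)
    eta1 <- if (p > 0) drop(data$X %*% beta$beta1) + offset[1] else rep(0, n)
    eta2 <- if (p > 0) drop(data$X %*% beta$beta2) + offset[2] else rep(0, n)
  } else {
    cc <- to_raw(par)
    beta <- cc$beta; offset <- cc$offset
    eta1 <- eta2 <- if (p > 0) drop(data$X %*% beta) + offset else rep(0, n)
  }
  baseline <- if (is_cox) {
    breslow_cumulative_hazard(data, eta1, ties)
  } else {
    transformed_scale_cumulative_hazard(data, eta1, eta2)
  }
  structure(
    list(family = family, ties = if (is_cox) ties else NULL,
         beta = beta, offset = offset, projection = projection,
         bandwidth = bandwidth, baseline = baseline, loglik = val,
         converged = conv, grad_norm = gnorm, n = n, p = p),
    class = "teacher_fit"
  )
}

#' @export
print.teacher_fit <- function(x, ...) {
  cat("<teacher_fit>", x$family, " n =", x$n, " p =", x$p,
      " loglik =", format(x$loglik, digits = 6),
      if (!x$converged) " (not converged)", "\n")
  invisible(x)
}

#' Linear predictor(s) of a fitted teacher or student model
#'
#' @param model a `teacher_fit` or `student_model`.
#' @param X raw-feature covariate matrix with one row per subject.
#' @return For EH models a list with `eta1` and `eta2`; otherwise a single
#'   numeric vector.
#' @export
predict_linear <- function(model, X) {
  X <- as.matrix(X)
  if (inherits(model, "student_model")) {
    if (model$family == "eh") {
      return(list(eta1 = drop(X %*% model$beta$beta1) + model$intercept[1],
                  eta2 = drop(X %*% model$beta$beta2) + model$intercept[2]))
    }
    return(drop(X %*% model$beta) + model$intercept)
  }
  stopifnot(inherits(model, "teacher_fit"))
  if (model$family == "eh") {
    list(eta1 = drop(X %*% model$beta$beta1) + model$offset[1],
         eta2 = drop(X %*% model$beta$beta2) + model$offset[2])
  } else {
    if (model$p == 0) rep(0, nrow(X)) else
      drop(X %*% model$beta) + model$offset
  }
}

# teacher-family log-likelihood of linear predictors on a dataset;
# the scoring primitive for cross-validation
family_loglik_eta <- function(family, eta, data, ties = NULL,
                              bandwidth = NULL) {
  if (family %in% c("cox_breslow", "cox_efron")) {
    if (is.null(ties)) ties <- if (family == "cox_efron") "efron" else "breslow"
    cox_partial_loglik(eta, data, ties)
  } else if (family == "aft") {
    eh_loglik_eta(eta, eta, data, bandwidth)
  } else {
    eh_loglik_eta(eta$eta1, eta$eta2, data, bandwidth)
  }
}
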