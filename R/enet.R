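# Elastic-net student: lambda grid, coordinate-descent solver, and the
# warm-started regularization path. Features are standardized internally
# (mean 0, population variance 1) and coefficients are mapped back to the
# original scale, as in glmnet.

standardize_design <- function(X) {
  X <- as.matrix(X)
  center <- colMeans(X)
  Xc <- sweep(X, 2, center)
  scale <- sqrt(colMeans(Xc^2))
  scale[scale == 0] <- 1   # zero-variance column: stays all-zero, coef 0
  list(Xs = sweep(Xc, 2, scale, "/"), center = center, scale = scale)
}

#' Regularization path grid
#'
#' Geometric grid of `L` penalty values from `lambda_max` — the smallest
#' penalty whose elastic-net solution is exactly all-zero,
#' `max_j |<x_j, y - mean(y)>| / (n * alpha)` on standardized features —
#' down to `eps * lambda_max`. Index 1 of the path therefore always has
#' zero active coefficients.
#'
#' @param X covariate matrix (standardized internally).
#' @param y response (the teacher's linear predictor; centered internally).
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param L number of grid points (default 100).
#' @param eps ratio of the smallest to the largest penalty; default 0.01
#'   when `n > p`, else 0.05.
#' @return Strictly decreasing numeric vector of length `L`.
#' @export
lambda_path <- function(X, y, alpha = 1, L = 100, eps = NULL) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]", call. = FALSE)
  yc <- y - mean(y)
  if (all(yc == 0)) {
    stop("teacher predictions are constant; nothing to distill",
         call. = FALSE)
  }
  if (is.null(eps)) eps <- if (n > p) 0.01 else 0.05
  sd <- standardize_design(X)
  # the tiny relative nudge keeps the head of the path on the all-zero
  # side of the KKT boundary under floating-point rounding
  lambda_max <- max(abs(crossprod(sd$Xs, yc))) / (n * alpha) * (1 + 1e-9)
  exp(seq(log(lambda_max), log(eps * lambda_max), length.out = L))
}

#' Elastic-net linear regression by cyclic coordinate descent
#'
#' Minimizes
#' `(1/(2n)) ||y - b0 - X b||^2 + lambda (alpha ||b||_1 + (1-alpha) ||b||_2^2 / 2)`
#' by soft-thresholded cyclic coordinate descent on internally standardized
#' features, warm-started from `init`; the returned coefficients and
#' intercept are on the original feature scale.
#'
#' @inheritParams lambda_path
#' @param lambda penalty (non-negative scalar).
#' @param init optional warm-start coefficient vector (original scale).
#' @param tol convergence threshold on the maximum coefficient change per
#'   sweep (standardized scale).
#' @param max_iter maximum coordinate sweeps; exceeding it warns.
#' @return List with `beta`, `intercept`, `sweeps`, `converged`.
#' @export
elastic_net_cd <- function(X, y, lambda, alpha = 1, init = NULL,
                           tol = 1e-7, max_iter = 1e5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, is.finite(lambda), lambda >= 0,
            alpha > 0, alpha <= 1)
  sd <- standardize_design(X)
  yc <- y - mean(y)
  b0 <- if (is.null(init)) rep(0, p) else as.numeric(init) * sd$scale
  fit <- .enet_cd_cpp(sd$Xs, yc, lambda, alpha, b0, tol, as.integer(max_iter))
  if (!fit$converged) {
    warning("coordinate descent hit max_iter before converging")
  }
  beta <- fit$beta / sd$scale
  list(beta = beta, intercept = mean(y) - sum(beta * sd$center),
       sweeps = fit$sweeps, converged = fit$converged)
}

#' Fit the elastic-net regularization path
#'
#' Warm-started sweep from the largest to the smallest penalty;
#' Karush-Kuhn-Tucker optimality is checked at each solution
#' (`|<x_j, r>| / n <= lambda * alpha + 1e-6` for every inactive feature).
#'
#' @inheritParams elastic_net_cd
#' @param lambdas decreasing penalty grid; computed by [lambda_path()] if
#'   omitted.
#' @param L,eps passed to [lambda_path()] when `lambdas` is omitted.
#' @return Object of class `reg_path`: `lambdas`, `alpha`, `coefs`
#'   (`L x p`, original scale), `intercepts`, `n_nonzero`, and
#'   `kkt_violation`, the largest KKT residual excess over the path.
#' @export
fit_path <- function(X, y, lambdas = NULL, alpha = 1, L = 100, eps = NULL,
                     tol = 1e-7, max_iter = 1e5) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  if (is.null(lambdas)) lambdas <- lambda_path(X, y, alpha, L, eps)
  if (any(diff(lambdas) >= 0)) {
    stop("'lambdas' must be strictly decreasing", call. = FALSE)
  }
  L <- length(lambdas)
  sd <- standardize_design(X)
  yc <- y - mean(y)
  coefs_std <- matrix(0, L, p)
  nnz <- integer(L)
  kkt_max <- 0
  b <- rep(0, p)
  for (l in seq_len(L)) {
    fit <- .enet_cd_cpp(sd$Xs, yc, lambdas[l], alpha, b, tol,
                        as.integer(max_iter))
    b <- fit$beta
    coefs_std[l, ] <- b
    nnz[l] <- sum(b != 0)
    r <- yc - drop(sd$Xs %*% b)
    g <- abs(crossprod(sd$Xs, r)) / n
    viol <- max(0, max(g[b == 0] - lambdas[l] * alpha, -Inf))
    kkt_max <- max(kkt_max, viol)
  }
  coefs <- sweep(coefs_std, 2, sd$scale, "/")
  intercepts <- mean(y) - drop(coefs %*% sd$center)
  structure(
    list(lambdas = lambdas, alpha = alpha, coefs = coefs,
         intercepts = intercepts, n_nonzero = nnz, kkt_violation = kkt_max),
    class = "reg_path"
  )
}

#' @export
print.reg_path <- function(x, ...) {
  cat("<reg_path>", length(x$lambdas), "lambdas, alpha =", x$alpha,
      ", active set 0 ->", max(x$n_nonzero), "\n")
  invisible(x)
}
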