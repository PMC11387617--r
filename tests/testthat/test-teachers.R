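# Cox partial likelihood, smoothed AFT/EH likelihoods, gradients,
# dimension reduction, and teacher fitting.

test_that("Cox partial likelihood matches closed forms and the risk-set oracle", {
  d <- surv_dataset(1:3, c(1, 1, 1), matrix(0, 3, 0))
  expect_equal(cox_partial_loglik(rep(0, 3), d, "breslow"), -log(6))
  expect_equal(cox_partial_loglik(rep(0, 3), d, "efron"), -log(6))

  d2 <- surv_dataset(c(1, 1, 2), c(1, 1, 0), matrix(0, 3, 0))
  expect_equal(cox_partial_loglik(rep(0, 3), d2, "breslow"), -2 * log(3))
  expect_equal(cox_partial_loglik(rep(0, 3), d2, "efron"), -log(3) - log(2))

  # spec's 4-subject instance plus random censored/tied instances
  d3 <- surv_dataset(1:4, c(1, 0, 1, 1), matrix(0, 4, 0))
  eta3 <- c(0.5, -0.2, 0.3, 0)
  expect_equal(cox_partial_loglik(eta3, d3, "breslow"),
               oracle_cox_loglik(1:4, c(1, 0, 1, 1), eta3, "breslow"))
  set.seed(42)
  for (rep_i in 1:5) {
    n <- 30
    time <- sample(1:12, n, replace = TRUE) / 2   # many ties
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    eta <- rnorm(n, sd = 1.5)
    d <- surv_dataset(time, event, matrix(0, n, 0))
    eta_s <- eta[d$sort_order]
    for (ties in c("breslow", "efron")) {
      expect_equal(cox_partial_loglik(eta_s, d, ties),
                   oracle_cox_loglik(d$time, d$event, eta_s, ties),
                   tolerance = 1e-12)
    }
  }
})

test_that("Cox likelihood is invariant to storage order and overflow-safe", {
  set.seed(1)
  n <- 40
  time <- rexp(n); event <- rbinom(n, 1, 0.6); event[1] <- 1
  X <- matrix(rnorm(n * 2), n, 2)
  eta <- rnorm(n)
  d <- surv_dataset(time, event, X)
  perm <- sample(n)
  d_p <- surv_dataset(time[perm], event[perm], X[perm, ])
  expect_equal(cox_partial_loglik(eta[d$sort_order], d),
               cox_partial_loglik(eta[perm][d_p$sort_order], d_p))
  # max-shift: huge eta must not overflow; the partial likelihood is
  # exactly invariant to a constant shift of eta
  expect_true(is.finite(cox_partial_loglik(eta + 800, d)))
  expect_equal(cox_partial_loglik(eta + 800, d),
               cox_partial_loglik(eta, d), tolerance = 1e-8)
})

test_that("Cox gradients are exact and sum to zero", {
  d <- surv_dataset(1:3, c(1, 1, 1), matrix(0, 3, 0))
  expect_equal(cox_partial_gradient(rep(0, 3), d),
               c(2 / 3, 1 / 6, -5 / 6))
  set.seed(9)
  for (rep_i in 1:4) {
    n <- 25
    time <- sample(1:10, n, replace = TRUE)
    event <- rbinom(n, 1, 0.7); event[1] <- 1
    d <- surv_dataset(time, event, matrix(0, n, 0))
    eta <- rnorm(n)
    for (ties in c("breslow", "efron")) {
      g <- cox_partial_gradient(eta, d, ties)
      fd <- fd_gradient(function(e) cox_partial_loglik(e, d, ties), eta)
      expect_equal(g, fd, tolerance = 1e-6)
      expect_equal(sum(g), 0, tolerance = 1e-12)
    }
  }
})

test_that("Breslow and Efron coincide exactly on tie-free data", {
  set.seed(3)
  n <- 30
  d <- surv_dataset(rexp(n), rbinom(n, 1, 0.7) | c(1, logical(n - 1)),
                    matrix(rnorm(n), n, 1))
  eta <- rnorm(n)
  expect_identical(cox_partial_loglik(eta, d, "breslow"),
                   cox_partial_loglik(eta, d, "efron"))
  expect_identical(cox_partial_gradient(eta, d, "breslow"),
                   cox_partial_gradient(eta, d, "efron"))
})

test_that("AFT equals EH with equal coefficient vectors, exactly", {
  sim <- tiny_sim(n = 40, seed = 5)
  d <- sim$data
  for (b in list(c(0.5, -0.2, 0.1), c(0, 0, 0), c(2, 1, -1))) {
    expect_identical(aft_profile_loglik(b, d, 0.4),
                     eh_profile_loglik(b, b, d, 0.4))
  }
  g_aft <- smoothed_gradient("aft", c(0.5, -0.2, 0.1), d, 0.4)
  g_eh <- smoothed_gradient("eh", list(c(0.5, -0.2, 0.1), c(0.5, -0.2, 0.1)),
                            d, 0.4)
  expect_equal(g_aft, g_eh$beta1 + g_eh$beta2, tolerance = 1e-12)
})

test_that("smoothed likelihoods match the direct-summation oracle", {
  d <- surv_dataset(c(1, 2, 4), c(1, 1, 1), matrix(c(1, 0, -1), 3, 1))
  expect_equal(aft_profile_loglik(0.5, d, 0.5),
               oracle_eh_loglik(d$time, d$event, d$X, 0.5, 0.5, 0.5),
               tolerance = 1e-12)
  expect_equal(eh_profile_loglik(0.2, -0.1, d, 0.5),
               oracle_eh_loglik(d$time, d$event, d$X, 0.2, -0.1, 0.5),
               tolerance = 1e-12)
  # larger censored instance, both self-term conventions
  sim <- tiny_sim(n = 35, seed = 11, family = "aft")
  dd <- sim$data
  for (self in c(TRUE, FALSE)) {
    expect_equal(
      eh_profile_loglik(c(0.3, 0.1, -0.4), c(-0.2, 0.5, 0), dd, 0.45,
                        include_self = self),
      oracle_eh_loglik(dd$time, dd$event, dd$X, c(0.3, 0.1, -0.4),
                       c(-0.2, 0.5, 0), 0.45, include_self = self),
      tolerance = 1e-12)
  }
})

test_that("smoothed likelihood shifts correctly under an added constant column", {
  sim <- tiny_sim(n = 30, seed = 13)
  d <- sim$data
  b <- c(0.4, -0.3, 0.2)
  c0 <- 0.7
  X2 <- cbind(d$X, 1)
  d2 <- surv_dataset(d$time, d$event, X2)
  expect_equal(eh_profile_loglik(c(b, c0), c(b, c0), d2, 0.5),
               oracle_eh_loglik(d2$time, d2$event, d2$X, c(b, c0),
                                c(b, c0), 0.5),
               tolerance = 1e-12)
})

test_that("smoothed gradients match finite differences across seeds", {
  set.seed(100)
  for (rep_i in 1:4) {
    sim <- tiny_sim(n = 40, p = 4, beta = c(0.5, -0.5, 0.2, 0),
                    seed = 100 + rep_i)
    d <- sim$data
    a <- 0.4
    b1 <- rnorm(4, sd = 0.4); b2 <- rnorm(4, sd = 0.4)
    g <- smoothed_gradient("eh", list(b1, b2), d, a)
    fd <- fd_gradient(function(p) eh_profile_loglik(p[1:4], p[5:8], d, a),
                      c(b1, b2))
    expect_equal(c(g$beta1, g$beta2), fd, tolerance = 1e-5)
    ga <- smoothed_gradient("aft", b1, d, a)
    fda <- fd_gradient(function(p) aft_profile_loglik(p, d, a), b1)
    expect_equal(ga, fda, tolerance = 1e-5)
  }
})

test_that("empty covariate matrix gives empty gradients and finite likelihood", {
  d <- surv_dataset(c(1, 2, 3), c(1, 0, 1), matrix(0, 3, 0))
  expect_length(smoothed_gradient("aft", numeric(0), d, 0.5), 0)
  expect_true(is.finite(eh_profile_loglik(numeric(0), numeric(0), d, 0.5)))
})

test_that("PCA reduction reconstructs, selects rank by variance, composes", {
  set.seed(20)
  X <- matrix(rnorm(60), 20, 3)
  pr <- reduce_dimensions(X, rank = 3)
  # full rank: orthogonal change of basis reconstructs the standardized X
  Xs <- scale(X, scale = apply(X, 2, function(c) sqrt(mean((c - mean(c))^2))))
  expect_equal(pr$scores %*% t(pr$loadings), unclass(Xs),
               ignore_attr = TRUE, tolerance = 1e-10)

  # constructed spread spectrum: smallest r reaching 90% variance of the
  # standardized matrix (reference spectrum recomputed independently)
  U <- qr.Q(qr(matrix(rnorm(320), 40, 8)))
  V <- qr.Q(qr(matrix(rnorm(64), 8, 8)))
  M <- U %*% diag(c(10, 6, 3, 1, 0.5, 0.3, 0.2, 0.1)) %*% t(V)
  Ms <- scale(M, scale = apply(M, 2,
                               function(c) sqrt(mean((c - mean(c))^2))))
  ev <- cumsum(svd(Ms)$d^2) / sum(svd(Ms)$d^2)
  pr2 <- reduce_dimensions(M, rank = 0.9)
  expect_equal(ncol(pr2$loadings), which(ev >= 0.9)[1])

  # rank-1 matrix: scores proportional to the generating direction
  u <- rnorm(20); v <- c(1, -2, 0.5)
  X1 <- outer(u, v)
  pr3 <- reduce_dimensions(X1, rank = 1)
  cors <- abs(cor(pr3$scores[, 1], u))
  expect_gt(cors, 1 - 1e-8)

  expect_warning(reduce_dimensions(cbind(X, 0), rank = 2), "zero-variance")
})

test_that("projection composition reproduces reduced-space predictions", {
  set.seed(21)
  X <- matrix(rnorm(200), 40, 5)
  pr <- reduce_dimensions(X, rank = 3)
  br <- rnorm(3)
  comp <- distillsurv:::compose_projection(pr, br)
  expect_equal(drop(X %*% comp$beta) + comp$offset,
               drop(pr$scores %*% br), tolerance = 1e-10)
})

test_that("teacher fits recover simulated coefficients", {
  sim <- simulate_survival("cox", n = 1500, p = 5, beta = c(1, -1, 0.5, 0, 0),
                           censor_rate = 0.3, seed = 31)
  fit <- fit_teacher(sim$data, "cox_breslow")
  expect_true(fit$converged)
  expect_lt(max(abs(fit$beta - c(1, -1, 0.5, 0, 0))), 0.2)

  sim2 <- simulate_survival("aft", n = 700, p = 3, beta = c(0.8, -0.8, 0),
                            censor_rate = 0.3, seed = 32)
  fit2 <- fit_teacher(sim2$data, "aft")
  expect_true(fit2$converged)
  expect_equal(sign(fit2$beta[1:2]), c(1, -1))
  expect_lt(max(abs(fit2$beta - c(0.8, -0.8, 0))), 0.25)
})

test_that("Cox teacher agrees with an independent partial-likelihood fit", {
  skip_if_not_installed("survival")
  set.seed(33)
  n <- 200
  time <- sample(1:40, n, replace = TRUE)    # heavy ties
  X <- matrix(rnorm(n * 3), n, 3)
  event <- rbinom(n, 1, plogis(X[, 1])); event[1] <- 1
  d <- surv_dataset(time, event, X)
  for (fam in c("cox_breslow", "cox_efron")) {
    ties <- if (fam == "cox_efron") "efron" else "breslow"
    fit <- fit_teacher(d, fam)
    ref <- survival::coxph(survival::Surv(time, event) ~ X, ties = ties)
    expect_equal(unname(fit$beta), unname(coef(ref)), tolerance = 1e-5)
  }
})

test_that("all-zero covariates give a zero fit at the null likelihood", {
  d <- surv_dataset(1:5, c(1, 1, 0, 1, 1), matrix(0, 5, 2))
  fit <- fit_teacher(d, "cox_breslow")
  expect_equal(unname(fit$beta), c(0, 0))
  expect_equal(fit$loglik, cox_partial_loglik(rep(0, 5), d))
})

test_that("fitted Cox likelihood dominates the null and random points", {
  sim <- tiny_sim(n = 120, seed = 35)
  d <- sim$data
  fit <- fit_teacher(d, "cox_breslow")
  ll_hat <- fit$loglik
  expect_gte(ll_hat, cox_partial_loglik(rep(0, d$n), d))
  set.seed(36)
  for (i in 1:20) {
    b <- rnorm(3, sd = 1.5)
    expect_gte(ll_hat, cox_partial_loglik(drop(d$X %*% b), d))
  }
})

test_that("high-dimensional teachers require reduction or ridge", {
  sim <- tiny_sim(n = 20, seed = 37)
  d <- sim$data
  d_wide <- surv_dataset(d$time, d$event,
                         cbind(d$X, matrix(rnorm(20 * 30), 20, 30)))
  expect_error(fit_teacher(d_wide, "cox_breslow"), "reduction|ridge")
  expect_error(fit_teacher(d_wide, "cox_breslow", reduction = 0.9,
                           ridge = 1), "not both")
  fit <- fit_teacher(d_wide, "cox_breslow", reduction = 5)
  expect_length(fit$beta, 33)
  expect_equal(ncol(fit$projection$loadings), 5)
})
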