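# Cross-validated knowledge distillation: CV protocol shape, determinism,
# selection rules, and student-teacher agreement.

make_cv_stub <- function(mu, se, nnz, lambdas = NULL) {
  if (is.null(lambdas)) lambdas <- exp(seq(0, -2, length.out = length(mu)))
  structure(list(mean = mu, se = se, n_nonzero = nnz, lambdas = lambdas),
            class = "kd_cv")
}

test_that("the CV score matrix has the protocol's shape and aligned grid", {
  sim <- tiny_sim(n = 120, p = 5, beta = c(1, -0.8, 0.5, 0, 0), seed = 80)
  cv <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                          k = 5, repeats = 5, L = 30, seed = 81)
  expect_equal(dim(cv$scores), c(25, 30))
  expect_true(all(diff(cv$lambdas) < 0))
  expect_true(all(cv$se >= 0))
  expect_equal(cv$n_nonzero[1], 0L)
  expect_true(all(unlist(cv$selected) %in% seq_len(30)))
})

test_that("cross-validation is deterministic given a seed", {
  sim <- tiny_sim(n = 80, p = 4, beta = c(1, -1, 0, 0), seed = 82)
  cv1 <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                           k = 3, repeats = 2, L = 15, seed = 9)
  cv2 <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                           k = 3, repeats = 2, L = 15, seed = 9)
  cv3 <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                           k = 3, repeats = 2, L = 15, seed = 10)
  expect_identical(cv1$scores, cv2$scores)
  expect_identical(cv1$selected, cv2$selected)
  expect_false(identical(cv1$scores, cv3$scores))
})

test_that("selection rules handle degenerate profiles toward sparsity", {
  # flat mean scores: every rule picks the sparsest index
  cv <- make_cv_stub(mu = rep(1, 10), se = rep(0.1, 10),
                     nnz = c(0, 0, 1, 2, 3, 5, 6, 8, 9, 10))
  expect_equal(select_lambda(cv, "min"), 1L)
  expect_equal(select_lambda(cv, "1se"), 1L)
  expect_equal(select_lambda(cv, "pcvl"), 1L)

  # strictly increasing scores with zero se: min = 1se = last index
  cv2 <- make_cv_stub(mu = seq(0, 1, length.out = 5), se = rep(0, 5),
                      nnz = c(0, 1, 2, 4, 6))
  expect_equal(select_lambda(cv2, "min"), 5L)
  expect_equal(select_lambda(cv2, "1se"), 5L)
  # pcvl on the 5-point toy path, by hand:
  # mu = (0, .25, .5, .75, 1), null index 1, min index 5, N(min) = 6
  # penalty/coef = (1 - 0)/6; profile = mu - N/6
  # = (0, .0833, .1667, .0833, 0) -> argmax at index 3
  expect_equal(select_lambda(cv2, "pcvl"), 3L)

  # N(min) = 0 returns the null index
  cv3 <- make_cv_stub(mu = c(1, 0.5, 0.2), se = rep(0, 3),
                      nnz = c(0, 2, 4))
  expect_equal(select_lambda(cv3, "pcvl"), 1L)
})

test_that("1se and pcvl never select a smaller penalty than min", {
  set.seed(83)
  for (i in 1:20) {
    L <- 12
    cv <- make_cv_stub(mu = cumsum(rnorm(L, 0.05)), se = abs(rnorm(L, 0.2)),
                       nnz = sort(sample(0:20, L, replace = TRUE)))
    cv$n_nonzero[1] <- 0
    i_min <- select_lambda(cv, "min")
    expect_lte(select_lambda(cv, "1se"), i_min)
    expect_lte(select_lambda(cv, "pcvl"), i_min)
    expect_lte(cv$n_nonzero[select_lambda(cv, "1se")], cv$n_nonzero[i_min])
  }
})

test_that("the student reproduces a linear teacher at the path end", {
  sim <- tiny_sim(n = 150, p = 6, beta = c(1, -1, 0.5, 0, 0, 0), seed = 84)
  cv <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                          k = 3, repeats = 1, L = 40, seed = 85)
  pt <- cv$student_path$paths[[1]]
  L <- length(cv$lambdas)
  eta_s <- drop(sim$data$X %*% pt$coefs[L, ]) + pt$intercepts[L]
  eta_t <- predict_linear(cv$teacher, sim$data$X)
  expect_gte(stats::cor(eta_s, eta_t), 0.99)
})

test_that("fit_kd returns a usable sparse model with matching support size", {
  sim <- tiny_sim(n = 150, p = 10,
                  beta = c(1, -1, 0.8, 0, 0, 0, 0, 0, 0, 0), seed = 86)
  m <- fit_kd(sim$data, list(family = "cox_breslow"), rule = "min",
              k = 3, repeats = 2, L = 30, seed = 87)
  expect_s3_class(m, "student_model")
  expect_equal(m$n_nonzero, sum(m$beta != 0))
  expect_false(is.null(m$baseline))
  s <- predict_survival(m, sim$data$X[1:5, ])
  expect_true(all(s$S >= 0 & s$S <= 1))
  eta <- predict_linear(m, sim$data$X)
  expect_gt(harrell_c(eta, sim$data$time, sim$data$event), 0.5)
})

test_that("pcvl models are at most as dense as min models", {
  set.seed(88)
  denser <- 0
  for (i in 1:6) {
    sim <- simulate_survival("cox", n = 100, p = 8,
                             beta = c(1, -1, 0.5, rep(0, 5)),
                             censor_rate = 0.25, seed = 880 + i)
    cv <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                            k = 3, repeats = 2, L = 25, seed = 880 + i)
    n_min <- cv$n_nonzero[cv$selected$min]
    n_pcvl <- cv$n_nonzero[cv$selected$pcvl]
    if (n_pcvl > n_min) denser <- denser + 1
  }
  expect_lte(denser, 0)
})

test_that("EH teachers distill into a pair of students with union support", {
  sim <- simulate_survival("eh", n = 120, p = 4,
                           beta = list(c(0.5, -0.3, 0, 0), c(0.6, 0.2, 0, 0)),
                           censor_rate = 0.2, seed = 89)
  m <- suppressWarnings(
    fit_kd(sim$data, list(family = "eh"), rule = "min", k = 3,
           repeats = 1, L = 15, seed = 90))
  expect_type(m$beta, "list")
  expect_equal(m$n_nonzero, sum(m$beta$beta1 != 0 | m$beta$beta2 != 0))
  eta <- predict_linear(m, sim$data$X)
  expect_named(eta, c("eta1", "eta2"))
  s <- predict_survival(m, sim$data$X[1:3, ])
  expect_true(all(apply(s$S, 1, function(r) all(diff(r) <= 1e-12))))
})

test_that("alternative scoring methods produce the documented shapes", {
  sim <- tiny_sim(n = 90, p = 4, beta = c(1, -0.5, 0, 0), seed = 91)
  cv_b <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                            k = 3, repeats = 2, L = 10, seed = 92,
                            scoring = "basic")
  expect_equal(nrow(cv_b$scores), 6)
  cv_lp <- kd_cross_validate(sim$data, list(family = "cox_breslow"),
                             k = 3, repeats = 2, L = 10, seed = 92,
                             scoring = "linear_predictor")
  expect_equal(nrow(cv_lp$scores), 2)
})
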