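# Independent brute-force oracles used to freeze expected values.
# These deliberately share no code with the package internals: explicit
# loops over risk sets and pairs, no max-shifting, no grouping tricks.

# Cox log partial likelihood by explicit risk-set enumeration
oracle_cox_loglik <- function(time, event, eta, ties = "breslow") {
  ll <- 0
  for (t in sort(unique(time[event == 1]))) {
    D <- which(time == t & event == 1)
    R <- which(time >= t)
    d <- length(D)
    ll <- ll + sum(eta[D])
    if (ties == "breslow") {
      ll <- ll - d * log(sum(exp(eta[R])))
    } else {
      for (l in seq_len(d)) {
        ll <- ll - log(sum(exp(eta[R])) - (l - 1) / d * sum(exp(eta[D])))
      }
    }
  }
  ll
}

# smoothed EH profile log-likelihood by direct summation
oracle_eh_loglik <- function(time, event, X, b1, b2, a,
                             include_self = TRUE) {
  n <- length(time)
  eta1 <- drop(X %*% b1); eta2 <- drop(X %*% b2)
  e <- log(time) + eta1
  v <- eta2 - eta1
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] == 0) next
    dens <- 0
    for (j in seq_len(n)) {
      if (event[j] == 1 && (include_self || j != i)) {
        dens <- dens + dnorm((e[j] - e[i]) / a)
      }
    }
    risk <- 0
    for (j in seq_len(n)) {
      risk <- risk + exp(v[j]) * pnorm((e[j] - e[i]) / a)
    }
    total <- total + v[i] + log(dens / (n * a)) - log(risk / n)
  }
  total / n
}

# EH transformed-scale baseline by direct summation
oracle_eh_baseline <- function(time, event, eta1, eta2, r_eval) {
  r <- time * exp(eta1)
  w <- exp(eta2 - eta1)
  sapply(r_eval, function(rr) {
    tot <- 0
    for (i in seq_along(time)) {
      if (event[i] == 1 && r[i] <= rr) {
        tot <- tot + 1 / sum(w[r >= r[i]])
      }
    }
    tot
  })
}

# central finite differences of a scalar function
fd_gradient <- function(f, x, h = 1e-6) {
  vapply(seq_along(x), function(j) {
    x1 <- x; x2 <- x
    x1[j] <- x1[j] + h; x2[j] <- x2[j] - h
    (f(x1) - f(x2)) / (2 * h)
  }, numeric(1))
}

# elastic-net objective on given (already standardized) design
enet_objective <- function(Xs, yc, b, lambda, alpha) {
  n <- nrow(Xs)
  sum((yc - Xs %*% b)^2) / (2 * n) +
    lambda * (alpha * sum(abs(b)) + (1 - alpha) * sum(b^2) / 2)
}

# proximal-gradient (ISTA) elastic-net solver on a standardized design
oracle_enet_prox <- function(Xs, yc, lambda, alpha, iters = 20000,
                             tol = 1e-12) {
  n <- nrow(Xs); p <- ncol(Xs)
  Lf <- max(eigen(crossprod(Xs) / n, symmetric = TRUE,
                  only.values = TRUE)$values) + lambda * (1 - alpha)
  b <- rep(0, p)
  soft <- function(z, g) sign(z) * pmax(abs(z) - g, 0)
  obj_old <- Inf
  for (it in seq_len(iters)) {
    grad <- -drop(crossprod(Xs, yc - Xs %*% b)) / n + lambda * (1 - alpha) * b
    b <- soft(b - grad / Lf, lambda * alpha / Lf)
    if (it %% 50 == 0) {
      obj <- enet_objective(Xs, yc, b, lambda, alpha)
      if (obj_old - obj < tol) break
      obj_old <- obj
    }
  }
  b
}

# pairwise concordance by explicit double loop
oracle_harrell <- function(eta, time, event) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    comparable <- (time[i] < time[j] && event[i] == 1) ||
      (time[i] == time[j] && event[i] == 1 && event[j] == 0)
    if (!comparable) next
    den <- den + 1
    if (eta[i] > eta[j]) num <- num + 1
    else if (eta[i] == eta[j]) num <- num + 0.5
  }
  num / den
}

# Uno IPCW concordance by explicit double loop; G_left is a function
# giving G(t-) for the training censoring distribution
oracle_uno <- function(time, event, eta, G_left, tau) {
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(event[i] == 1 && time[i] < time[j] && time[i] < tau)) next
    g <- G_left(time[i])
    if (g == 0) next
    w <- 1 / g^2
    den <- den + w
    if (eta[i] > eta[j]) num <- num + w
    else if (eta[i] == eta[j]) num <- num + w / 2
  }
  num / den
}

# Antolini time-dependent concordance from a step-evaluated curve matrix
oracle_antolini <- function(time, event, S_at) {
  # S_at(k, t): survival of subject k at time t
  num <- 0; den <- 0
  n <- length(time)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (!(event[i] == 1 && time[i] < time[j])) next
    den <- den + 1
    si <- S_at(i, time[i]); sj <- S_at(j, time[i])
    if (si < sj) num <- num + 1
    else if (si == sj) num <- num + 0.5
  }
  num / den
}

# Brier score by explicit loop
oracle_brier <- function(time, event, S_t, G_left, G_at, t) {
  n <- length(time)
  tot <- 0
  for (i in seq_len(n)) {
    if (time[i] <= t && event[i] == 1) {
      g <- G_left(time[i])
      if (g > 0) tot <- tot + S_t[i]^2 / g
    } else if (time[i] > t) {
      g <- G_at(t)
      if (g > 0) tot <- tot + (1 - S_t[i])^2 / g
    }
  }
  tot / n
}

# reverse Kaplan-Meier as a plain function of t
oracle_reverse_km <- function(time, event) {
  ut <- sort(unique(time))
  surv <- 1
  kn <- c(); vals <- c()
  for (t in ut) {
    dc <- sum(time == t & event == 0)
    nr <- sum(time >= t)
    if (dc > 0) {
      surv <- surv * (1 - dc / nr)
      kn <- c(kn, t); vals <- c(vals, surv)
    }
  }
  function(t, left = FALSE) {
    if (length(kn) == 0) return(1)
    idx <- if (left) sum(kn < t) else sum(kn <= t)
    if (idx == 0) 1 else vals[idx]
  }
}

# small simulated dataset helper
tiny_sim <- function(n = 60, p = 3, beta = c(0.8, -0.5, 0), seed = 1,
                     censor = 0.25, family = "cox") {
  simulate_survival(family, n = n, p = p, beta = beta,
                    censor_rate = censor, seed = seed)
}
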