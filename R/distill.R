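# Knowledge distillation: the teacher's training-set linear predictors are
# the regression targets for an elastic-net student along a shared
# regularization path, with k-fold cross-validated selection of the
# penalty by the min / 1se / pcvl rules.
#
# The lambda grid is computed ONCE on the full data so that path indices
# align across folds; teacher targets are always the teacher's own
# TRAINING-row predictions, never held-out predictions. EH teachers emit
# two linear predictors, distilled by two independent students sharing the
# grid; the reported active-set size is the union of the two supports.

# teacher_spec: list(family = ..., plus optional fit_teacher arguments
# bandwidth / reduction / ridge / tol / max_iter)
fit_teacher_spec <- function(data, spec) {
  do.call(fit_teacher, c(list(data = data), spec))
}

# teacher targets on its own training rows (vector, or list for EH)
teacher_targets <- function(teacher, data) {
  predict_linear(teacher, data$X)
}

# stratified fold assignment: events and censored rows are shuffled and
# dealt round-robin so every fold gets events whenever #events >= k
make_folds <- function(event, k) {
  fold <- integer(length(event))
  for (cls in unique(event)) {
    idx <- sample(which(event == cls))
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

# student path(s) for one training split; returns function(idx_rows, l)
# giving the linear predictor(s) at path index l for given rows
student_paths <- function(X, y, lambdas, alpha) {
  if (is.list(y)) {
    p1 <- fit_path(X, y$eta1, lambdas = lambdas, alpha = alpha)
    p2 <- fit_path(X, y$eta2, lambdas = lambdas, alpha = alpha)
    list(paths = list(p1, p2), eh = TRUE)
  } else {
    list(paths = list(fit_path(X, y, lambdas = lambdas, alpha = alpha)),
         eh = FALSE)
  }
}

path_eta <- function(sp, X, l) {
  lp <- lapply(sp$paths, function(pt) {
    drop(X %*% pt$coefs[l, ]) + pt$intercepts[l]
  })
  if (sp$eh) list(eta1 = lp[[1]], eta2 = lp[[2]]) else lp[[1]]
}

path_nnz <- function(sp) {
  if (sp$eh) {
    colSums(sp$paths[[1]]$coefs != 0 | sp$paths[[2]]$coefs != 0)
  } else {
    sp$paths[[1]]$n_nonzero
  }
}

subset_eta <- function(eta, idx) {
  if (is.list(eta)) list(eta1 = eta$eta1[idx], eta2 = eta$eta2[idx])
  else eta[idx]
}

#' Cross-validate the knowledge-distillation pipeline
#'
#' For each repeat, rows are shuffled (seeded) and split into `k` folds
#' stratified by the event indicator. For each fold, the teacher is
#' refitted on the k-1 training folds, its training-row predictions become
#' the student targets, the student path is fitted on the training folds,
#' and every penalty on the shared grid is scored against the held-out
#' fold. Scores are teacher-family log-likelihoods (higher is better).
#'
#' @param data a [surv_dataset()].
#' @param teacher_spec list with `family` and optional [fit_teacher()]
#'   arguments (`bandwidth`, `reduction`, `ridge`, ...).
#' @param alpha elastic-net mixing parameter in (0, 1].
#' @param k number of folds (>= 2).
#' @param repeats number of CV repetitions.
#' @param scoring `"vvh"` (default; Verweij-van Houwelingen:
#'   `loglik(eta, all data) - loglik(eta, training folds)`), `"basic"`
#'   (log-likelihood of the held-out fold alone), or
#'   `"linear_predictor"` (held-out predictions pooled across folds and
#'   scored once per repeat).
#' @param seed integer seed controlling the fold shuffles.
#' @param L,eps regularization grid size and ratio, see [lambda_path()].
#' @return An object of class `kd_cv`: the per-fold `scores` matrix
#'   (rows = folds x repeats, or repeats for pooled scoring), per-lambda
#'   `mean` and `se`, the shared `lambdas` grid, `n_nonzero` along the
#'   full-data path, the indices `selected` by the min / 1se / pcvl rules,
#'   the full-data `teacher` fit and student `path`(s).
#' @export
kd_cross_validate <- function(data, teacher_spec, alpha = 1, k = 5,
                              repeats = 5,
                              scoring = c("vvh", "basic",
                                          "linear_predictor"),
                              seed = NULL, L = 100, eps = NULL) {
  scoring <- match.arg(scoring)
  stopifnot(inherits(data, "surv_dataset"), k >= 2)
  if (!is.null(seed)) set.seed(seed)
  family <- teacher_spec$family
  n <- data$n

  teacher_full <- fit_teacher_spec(data, teacher_spec)
  y_full <- teacher_targets(teacher_full, data)
  bw <- teacher_full$bandwidth
  if (is.list(y_full)) {
    lambdas <- pmax(lambda_path(data$X, y_full$eta1, alpha, L, eps),
                    lambda_path(data$X, y_full$eta2, alpha, L, eps))
  } else {
    lambdas <- lambda_path(data$X, y_full, alpha, L, eps)
  }
  sp_full <- student_paths(data$X, y_full, lambdas, alpha)

  score_eta <- function(eta, d) {
    family_loglik_eta(family, eta, d, bandwidth = bw)
  }

  nrows <- if (scoring == "linear_predictor") repeats else k * repeats
  scores <- matrix(NA_real_, nrows, L)
  row <- 0
  for (rep_i in seq_len(repeats)) {
    fold <- NULL
    for (attempt in 1:20) {
      fold <- make_folds(data$event, k)
      ok <- all(vapply(seq_len(k),
                       function(f) sum(data$event[fold == f]) > 0,
                       logical(1)))
      if (ok) break
      if (attempt == 20) stop("could not build folds with events in every ",
                              "fold", call. = FALSE)
    }
    pooled_mat <- NULL
    for (f in seq_len(k)) {
      train <- which(fold != f); test <- which(fold == f)
      d_train <- surv_dataset(data$time[train], data$event[train],
                              data$X[train, , drop = FALSE])
      teacher_f <- fit_teacher_spec(d_train, teacher_spec)
      y_train <- teacher_targets(teacher_f, d_train)
      sp <- student_paths(d_train$X, y_train, lambdas, alpha)
      if (scoring == "vvh") {
        row <- row + 1
        for (l in seq_len(L)) {
          eta_all <- path_eta(sp, data$X, l)
          eta_tr <- path_eta(sp, d_train$X, l)
          scores[row, l] <- score_eta(eta_all, data) -
            score_eta(eta_tr, d_train)
        }
      } else if (scoring == "basic") {
        d_test <- surv_dataset(data$time[test], data$event[test],
                               data$X[test, , drop = FALSE])
        row <- row + 1
        for (l in seq_len(L)) {
          eta_te <- path_eta(sp, d_test$X, l)
          scores[row, l] <- score_eta(eta_te, d_test)
        }
      } else {
        if (is.null(pooled_mat)) {
          pooled_mat <- if (family == "eh") {
            list(eta1 = matrix(NA_real_, n, L),
                 eta2 = matrix(NA_real_, n, L))
          } else matrix(NA_real_, n, L)
        }
        for (l in seq_len(L)) {
          eta_te <- path_eta(sp, data$X[test, , drop = FALSE], l)
          if (family == "eh") {
            pooled_mat$eta1[test, l] <- eta_te$eta1
            pooled_mat$eta2[test, l] <- eta_te$eta2
          } else {
            pooled_mat[test, l] <- eta_te
          }
        }
      }
    }
    if (scoring == "linear_predictor") {
      row <- row + 1
      for (l in seq_len(L)) {
        eta_l <- if (family == "eh") {
          list(eta1 = pooled_mat$eta1[, l], eta2 = pooled_mat$eta2[, l])
        } else pooled_mat[, l]
        scores[row, l] <- score_eta(eta_l, data)
      }
    }
  }

  mu <- colMeans(scores)
  se <- apply(scores, 2, stats::sd) / sqrt(nrow(scores))
  nnz <- path_nnz(sp_full)
  cv <- structure(
    list(scores = scores, mean = mu, se = se, lambdas = lambdas,
         alpha = alpha, n_nonzero = nnz, scoring = scoring,
         teacher = teacher_full, student_path = sp_full,
         k = k, repeats = repeats, seed = seed),
    class = "kd_cv"
  )
  cv$selected <- list(min = select_lambda(cv, "min"),
                      `1se` = select_lambda(cv, "1se"),
                      pcvl = select_lambda(cv, "pcvl"))
  cv
}

#' @export
print.kd_cv <- function(x, ...) {
  cat("<kd_cv>", x$k, "folds x", x$repeats, "repeats,",
      length(x$lambdas), "lambdas (scoring:", x$scoring, ")\n")
  cat("  selected indices: min =", x$selected$min,
      " 1se =", x$selected$`1se`, " pcvl =", x$selected$pcvl, "\n")
  invisible(x)
}

#' Select a regularization-path index from cross-validation scores
#'
#' Rules (ties always break toward the sparser model, i.e. the larger
#' penalty): `min` — maximizer of the mean score; `1se` — largest penalty
#' whose mean score is within one standard error of the best;
#' `pcvl` — maximizer of the penalized profile
#' `mean(l) - N(l) * (mean(l_min) - mean(l_null)) / N(l_min)`, where
#' `N` is the active-set size along the path and `l_null` is the largest
#' penalty with an empty active set. When `N(l_min) = 0`, `l_null` is
#' returned.
#'
#' @param cv a `kd_cv` object.
#' @param rule `"min"`, `"1se"` or `"pcvl"`.
#' @param n_nonzero optional active-set sizes overriding `cv$n_nonzero`.
#' @return A path index (1-based, aligned with `cv$lambdas`).
#' @export
select_lambda <- function(cv, rule = c("min", "1se", "pcvl"),
                          n_nonzero = NULL) {
  rule <- match.arg(rule)
  mu <- cv$mean; se <- cv$se
  if (is.null(n_nonzero)) n_nonzero <- cv$n_nonzero
  i_min <- which.max(mu)                   # first max = largest lambda
  if (rule == "min") return(i_min)
  if (rule == "1se") {
    thr <- mu[i_min] - se[i_min]
    return(min(which(mu >= thr)))
  }
  # pcvl
  null_idx <- which(n_nonzero == 0)
  i_null <- if (length(null_idx)) min(null_idx) else 1L
  if (n_nonzero[i_min] == 0) return(i_null)
  pen <- mu - n_nonzero * (mu[i_min] - mu[i_null]) / n_nonzero[i_min]
  which.max(pen)
}

#' Fit a sparse survival model by knowledge distillation
#'
#' Runs [kd_cross_validate()], selects the penalty by `rule`, refits the
#' teacher and the student at the selected penalty on all training rows,
#' and re-estimates the baseline cumulative hazard from the student's
#' linear predictors (with the survival-function semantics of the teacher
#' family). The result supports [predict_linear()], [predict_survival()]
#' and the metrics module.
#'
#' @inheritParams kd_cross_validate
#' @param rule `"min"`, `"1se"` or `"pcvl"` (see [select_lambda()]).
#' @return An object of class `student_model`: sparse `beta` (for EH a
#'   list of two), `intercept`, the selected `lambda`/`lambda_index` and
#'   `rule`, `n_nonzero`, the full-data `teacher`, the re-estimated
#'   `baseline`, and the `cv` object.
#' @export
fit_kd <- function(data, teacher_spec, alpha = 1,
                   rule = c("min", "1se", "pcvl"), k = 5, repeats = 5,
                   scoring = c("vvh", "basic", "linear_predictor"),
                   seed = NULL, L = 100, eps = NULL) {
  rule <- match.arg(rule)
  scoring <- match.arg(scoring)
  cv <- kd_cross_validate(data, teacher_spec, alpha = alpha, k = k,
                          repeats = repeats, scoring = scoring,
                          seed = seed, L = L, eps = eps)
  model <- refit_baseline(build_student(cv, rule), data)
  model$cv <- cv
  model
}

#' Extract the student model at a selection rule from a fitted CV
#'
#' @param cv a `kd_cv` object.
#' @param rule `"min"`, `"1se"` or `"pcvl"`.
#' @return A `student_model` (see [fit_kd()]).
#' @export
build_student <- function(cv, rule = c("min", "1se", "pcvl")) {
  rule <- match.arg(rule)
  idx <- cv$selected[[if (rule == "1se") "1se" else rule]]
  sp <- cv$student_path
  teacher <- cv$teacher
  family <- teacher$family
  if (sp$eh) {
    beta <- list(beta1 = sp$paths[[1]]$coefs[idx, ],
                 beta2 = sp$paths[[2]]$coefs[idx, ])
    intercept <- c(sp$paths[[1]]$intercepts[idx],
                   sp$paths[[2]]$intercepts[idx])
    nnz <- sum(beta$beta1 != 0 | beta$beta2 != 0)
  } else {
    beta <- sp$paths[[1]]$coefs[idx, ]
    intercept <- sp$paths[[1]]$intercepts[idx]
    nnz <- sum(beta != 0)
  }
  model <- structure(
    list(family = family, beta = beta, intercept = intercept,
         lambda = cv$lambdas[idx], lambda_index = idx, rule = rule,
         alpha = cv$alpha, n_nonzero = nnz, teacher = teacher,
         bandwidth = teacher$bandwidth, ties = teacher$ties,
         baseline = NULL),
    class = "student_model"
  )
  model
}

#' Attach a baseline cumulative hazard estimated from student predictions
#'
#' @param model a `student_model`.
#' @param data the training [surv_dataset()].
#' @return The model with its `baseline` re-estimated from the student's
#'   own linear predictors under the teacher family's semantics.
#' @export
refit_baseline <- function(model, data) {
  stopifnot(inherits(model, "student_model"),
            inherits(data, "surv_dataset"))
  eta <- predict_linear(model, data$X)
  model$baseline <- if (model$family %in% c("cox_breslow", "cox_efron")) {
    breslow_cumulative_hazard(data, eta, model$ties)
  } else if (model$family == "aft") {
    transformed_scale_cumulative_hazard(data, eta, eta)
  } else {
    transformed_scale_cumulative_hazard(data, eta$eta1, eta$eta2)
  }
  model
}

#' @export
print.student_model <- function(x, ...) {
  cat("<student_model>", x$family, " rule =", x$rule,
      " lambda index =", x$lambda_index,
      " active =", x$n_nonzero, "\n")
  invisible(x)
}
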