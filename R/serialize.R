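# JSON serialization of fitted models. Coefficients of student models are
# stored sparsely as index/value pairs; doubles are written at full
# precision so that a serialize -> deserialize round trip reproduces
# predictions exactly.

step_to_list <- function(f) {
  if (is.null(f)) return(NULL)
  list(knots = f$knots, values = f$values, left_value = f$left_value)
}

step_from_list <- function(x) {
  if (is.null(x)) return(NULL)
  step_function(unlist(x$knots), unlist(x$values),
                left_value = x$left_value)
}

sparse_to_list <- function(beta) {
  idx <- which(beta != 0)
  list(p = length(beta), index = idx, value = beta[idx])
}

sparse_from_list <- function(x) {
  beta <- rep(0, x$p)
  if (length(x$index)) beta[unlist(x$index)] <- unlist(x$value)
  beta
}

teacher_to_list <- function(fit) {
  proj <- NULL
  if (!is.null(fit$projection)) {
    proj <- list(center = fit$projection$center,
                 scale = fit$projection$scale,
                 loadings = fit$projection$loadings)
  }
  list(type = "teacher_fit", family = fit$family, ties = fit$ties,
       beta = fit$beta, offset = fit$offset, bandwidth = fit$bandwidth,
       projection = proj, baseline = step_to_list(fit$baseline),
       loglik = fit$loglik, converged = fit$converged,
       grad_norm = fit$grad_norm, n = fit$n, p = fit$p)
}

teacher_from_list <- function(x) {
  beta <- if (x$family == "eh") {
    list(beta1 = unlist(x$beta$beta1), beta2 = unlist(x$beta$beta2))
  } else unlist(x$beta)
  proj <- NULL
  if (!is.null(x$projection)) {
    proj <- structure(
      list(center = unlist(x$projection$center),
           scale = unlist(x$projection$scale),
           loadings = do.call(rbind, lapply(x$projection$loadings, unlist))),
      class = "dr_projection")
  }
  structure(
    list(family = x$family, ties = x$ties, beta = beta,
         offset = unlist(x$offset), projection = proj,
         bandwidth = x$bandwidth, baseline = step_from_list(x$baseline),
         loglik = x$loglik, converged = x$converged,
         grad_norm = x$grad_norm, n = x$n, p = x$p),
    class = "teacher_fit"
  )
}

#' Serialize a fitted model to JSON
#'
#' Supports `teacher_fit` and `student_model` objects. Student
#' coefficients are written sparsely (index/value pairs); baselines as
#' knot/value arrays. Doubles keep full precision, so reloading the file
#' with [model_from_json()] reproduces predictions exactly.
#'
#' @param model a `teacher_fit` or `student_model`.
#' @param path output path; when `NULL` the JSON string is returned.
#' @return `path` (or the JSON string), invisibly.
#' @export
model_to_json <- function(model, path = NULL) {
  x <- if (inherits(model, "teacher_fit")) {
    teacher_to_list(model)
  } else if (inherits(model, "student_model")) {
    beta <- if (model$family == "eh") {
      list(beta1 = sparse_to_list(model$beta$beta1),
           beta2 = sparse_to_list(model$beta$beta2))
    } else sparse_to_list(model$beta)
    list(type = "student_model", family = model$family, beta = beta,
         intercept = model$intercept, lambda = model$lambda,
         lambda_index = model$lambda_index, rule = model$rule,
         alpha = model$alpha, n_nonzero = model$n_nonzero,
         ties = model$ties, bandwidth = model$bandwidth,
         baseline = step_to_list(model$baseline),
         teacher = teacher_to_list(model$teacher))
  } else {
    stop("unsupported model class", call. = FALSE)
  }
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(js)))
  writeLines(js, path)
  invisible(path)
}

#' Load a fitted model from JSON
#'
#' @param path path to a file written by [model_to_json()] (or a JSON
#'   string).
#' @return A `teacher_fit` or `student_model`.
#' @export
model_from_json <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(x$type)) stop("not a serialized model", call. = FALSE)
  if (x$type == "teacher_fit") return(teacher_from_list(x))
  if (x$type != "student_model") stop("unknown model type: ", x$type,
                                      call. = FALSE)
  beta <- if (x$family == "eh") {
    list(beta1 = sparse_from_list(x$beta$beta1),
         beta2 = sparse_from_list(x$beta$beta2))
  } else sparse_from_list(x$beta)
  structure(
    list(family = x$family, beta = beta, intercept = unlist(x$intercept),
         lambda = x$lambda, lambda_index = x$lambda_index, rule = x$rule,
         alpha = x$alpha, n_nonzero = x$n_nonzero, ties = x$ties,
         bandwidth = x$bandwidth, baseline = step_from_list(x$baseline),
         teacher = teacher_from_list(x$teacher)),
    class = "student_model"
  )
}
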