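#' Right-continuous step function
#'
#' Piecewise-constant, right-continuous function used for cumulative
#' baseline hazards and survival curves: `f(t) = values[max k: knots[k] <= t]`
#' and `f(t) = left_value` for `t < knots[1]`. For a cumulative hazard use
#' `left_value = 0` and non-decreasing values; for a survival curve
#' `left_value = 1` and non-increasing values in `[0, 1]`.
#'
#' @param knots strictly increasing numeric vector.
#' @param values numeric vector, same length as `knots`.
#' @param left_value value returned strictly before the first knot.
#' @return An object of class `surv_stepfun`.
#' @export
step_function <- function(knots, values, left_value = 0) {
  knots <- as.numeric(knots)
  values <- as.numeric(values)
  if (length(knots) != length(values)) {
    stop("'knots' and 'values' must have equal length", call. = FALSE)
  }
  if (length(knots) && any(diff(knots) <= 0)) {
    stop("'knots' must be strictly increasing", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("'values' must be finite", call. = FALSE)
  structure(list(knots = knots, values = values,
                 left_value = as.numeric(left_value)),
            class = "surv_stepfun")
}

#' Evaluate a step function
#'
#' @param f a [step_function()].
#' @param t numeric evaluation points.
#' @param left_limit if `TRUE`, evaluate the left limit `f(t-)` (the value
#'   just before `t`) instead of the right-continuous value `f(t)`. Used for
#'   inverse-probability-of-censoring weights at observed event times.
#' @return Numeric vector of the same length as `t`.
#' @export
eval_step <- function(f, t, left_limit = FALSE) {
  stopifnot(inherits(f, "surv_stepfun"))
  if (!length(f$knots)) return(rep(f$left_value, length(t)))
  idx <- findInterval(t, f$knots, left.open = left_limit)
  c(f$left_value, f$values)[idx + 1L]
}

#' @export
print.surv_stepfun <- function(x, ...) {
  cat("<surv_stepfun>", length(x$knots), "knots, left value",
      x$left_value, "\n")
  invisible(x)
}
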