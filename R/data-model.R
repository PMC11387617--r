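#' Build a canonical right-censored survival dataset
#'
#' Validates and canonically orders right-censored survival data. Rows are
#' stored in ascending follow-up time; among tied times, event rows precede
#' censored rows, so that risk sets include subjects censored exactly at an
#' event time. All likelihood, baseline and distillation functions in the
#' package consume objects of this class and assume this ordering.
#'
#' @param time positive, finite follow-up times (one per subject).
#' @param event event indicators: 1 = event observed, 0 = right-censored.
#'   Logical vectors are accepted and coerced.
#' @param X numeric covariate matrix with one row per subject. A data frame
#'   of numeric columns or a bare vector (treated as a single column) is
#'   accepted. May have zero columns.
#'
#' @return An object of class `surv_dataset`: a list with components
#'   `time`, `event`, `X` (all in canonical order), `n`, `p`, and
#'   `sort_order`, the permutation such that `time == original_time[sort_order]`.
#'   Un-permuting with `order(sort_order)` restores the input row order.
#'
#' @details At least one event is required: every likelihood in the package
#'   is undefined on all-censored data. Left truncation, interval censoring
#'   and time-varying covariates are not supported.
#'
#' @examples
#' d <- surv_dataset(c(3, 1, 2), c(1, 0, 1), diag(3))
#' d$time   # 1 2 3
#' d$event  # 0 1 1
#' @export
surv_dataset <- function(time, event, X = NULL) {
  time <- as.numeric(time)
  if (is.logical(event)) event <- as.numeric(event)
  event <- as.numeric(event)
  n <- length(time)
  if (length(event) != n) {
    stop("'time' and 'event' must have the same length (", n, " vs ",
         length(event), ")", call. = FALSE)
  }
  if (is.null(X)) X <- matrix(numeric(0), nrow = n, ncol = 0)
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X)) X <- matrix(as.numeric(X), ncol = 1L)
  storage.mode(X) <- "double"
  if (nrow(X) != n) {
    stop("'X' must have one row per subject (", nrow(X), " rows for ", n,
         " subjects)", call. = FALSE)
  }
  bad <- which(!is.finite(time) | time <= 0)
  if (length(bad)) {
    stop("non-positive or non-finite follow-up time in row ", bad[1L],
         call. = FALSE)
  }
  bad <- which(!(event %in% c(0, 1)))
  if (length(bad)) {
    stop("non-binary event indicator in row ", bad[1L], call. = FALSE)
  }
  if (ncol(X) > 0 && any(!is.finite(X))) {
    stop("non-finite covariate value in row ",
         which(rowSums(!is.finite(X)) > 0)[1L], call. = FALSE)
  }
  if (sum(event) < 1) {
    stop("no events: at least one observed event is required", call. = FALSE)
  }
  # ascending time; events (event = 1) before censored at tied times
  ord <- order(time, -event)
  structure(
    list(
      time = time[ord],
      event = event[ord],
      X = X[ord, , drop = FALSE],
      n = n,
      p = ncol(X),
      sort_order = ord
    ),
    class = "surv_dataset"
  )
}

#' @export
print.surv_dataset <- function(x, ...) {
  cat("<surv_dataset> n =", x$n, " p =", x$p,
      " events =", sum(x$event),
      sprintf(" (%.1f%% censored)\n", 100 * mean(1 - x$event)))
  invisible(x)
}

#' Restore the original row order of a canonical dataset
#'
#' @param data a [surv_dataset()].
#' @return A list with `time`, `event`, `X` in the order the rows were
#'   originally supplied.
#' @export
unsort_dataset <- function(data) {
  stopifnot(inherits(data, "surv_dataset"))
  inv <- order(data$sort_order)
  list(time = data$time[inv], event = data$event[inv],
       X = data$X[inv, , drop = FALSE])
}

#' Read right-censored survival data from a delimited text file
#'
#' Expects a header row with columns `time` and `event`; every remaining
#' column is taken as a numeric covariate. The delimiter is inferred from
#' the file extension (`.tsv`/`.tab` = tab, otherwise comma) unless
#' overridden.
#'
#' @param path path to the CSV/TSV file.
#' @param delim optional delimiter override (e.g. `","` or `"\t"`).
#' @return A [surv_dataset()].
#' @export
read_survival_data <- function(path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  df <- utils::read.table(path, header = TRUE, sep = delim,
                          check.names = FALSE, stringsAsFactors = FALSE)
  need <- c("time", "event")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("input file is missing required column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  covars <- setdiff(names(df), need)
  X <- if (length(covars)) as.matrix(df[covars]) else NULL
  if (!is.null(X) && !is.numeric(X)) {
    stop("covariate columns must be numeric", call. = FALSE)
  }
  surv_dataset(df$time, df$event, X)
}

#' Write a survival dataset to a delimited text file
#'
#' Inverse of [read_survival_data()]; rows are written in the original
#' (pre-canonicalization) order.
#'
#' @param data a [surv_dataset()].
#' @param path output path; extension selects the delimiter as in
#'   [read_survival_data()].
#' @param delim optional delimiter override.
#' @return `path`, invisibly.
#' @export
write_survival_data <- function(data, path, delim = NULL) {
  if (is.null(delim)) {
    delim <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  }
  orig <- unsort_dataset(data)
  X <- orig$X
  if (is.null(colnames(X)) && ncol(X) > 0) {
    colnames(X) <- paste0("x", seq_len(ncol(X)))
  }
  df <- data.frame(time = orig$time, event = orig$event, check.names = FALSE)
  if (ncol(X) > 0) df <- cbind(df, as.data.frame(X))
  utils::write.table(df, path, sep = delim, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
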