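# Surrogate-model comparison criteria and parity-plot data.

#' Prediction-quality metrics
#'
#' Computes the four comparison criteria used to judge surrogate models of
#' the conversion response:
#' R-squared `1 - sum((a-p)^2) / sum((a-mean(a))^2)`,
#' `rmse = sqrt(mean((a-p)^2))` (divisor n, not n - p),
#' `mae = mean(|a-p|)`, and
#' `mape = mean(|a-p| / |a|)` reported as a fraction (0.0465, not 4.65%).
#'
#' @param actual,predicted Numeric vectors of equal length >= 2 (%).
#' @return A list of class `metrics_report`: `r2`, `rmse`, `mae`, `mape`
#'   (`NA` with a warning if any `actual` is zero), `n`.
#' @examples
#' score_metrics(c(10, 20, 30), c(11, 19, 31))
#' @export
score_metrics <- function(actual, predicted) {
  stopifnot(is.numeric(actual), is.numeric(predicted))
  if (length(actual) != length(predicted)) {
    stop("actual and predicted must have equal length", call. = FALSE)
  }
  if (length(actual) < 2L) stop("need at least 2 observations", call. = FALSE)
  e <- actual - predicted
  sst <- sum((actual - mean(actual))^2)
  if (sst == 0) stop("zero variance in actual values: R2 undefined", call. = FALSE)
  mape <- if (any(actual == 0)) {
    warning("zero value in actual: MAPE not reported")
    NA_real_
  } else {
    mean(abs(e) / abs(actual))
  }
  structure(list(r2 = 1 - sum(e^2) / sst,
                 rmse = sqrt(mean(e^2)),
                 mae = mean(abs(e)),
                 mape = mape,
                 n = length(actual)),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("<metrics_report> n=%d  R2=%.4f  RMSE=%.4g  MAE=%.4g  MAPE=%.4g\n",
              x$n, x$r2, x$rmse, x$mae, x$mape))
  invisible(x)
}

#' Side-by-side comparison of two metric reports
#'
#' @param report_a,report_b `metrics_report`s computed against the same
#'   actual vector (same `n`).
#' @param labels Character(2) row labels (default `c("A", "B")`).
#' @return A list of class `comparison_table`: `table` (a `data.frame` with
#'   one row per model and the four criteria), `mae_ratio` (a/b) and
#'   `mae_ratio_rounded` (nearest integer).
#' @examples
#' # MAE 2.6847 vs 0.045 gives a ratio that rounds to 60
#' @export
compare_metrics <- function(report_a, report_b, labels = c("A", "B")) {
  stopifnot(inherits(report_a, "metrics_report"),
            inherits(report_b, "metrics_report"))
  if (report_a$n != report_b$n) {
    stop("reports computed on different numbers of observations", call. = FALSE)
  }
  tab <- data.frame(
    model = labels,
    r2 = c(report_a$r2, report_b$r2),
    rmse = c(report_a$rmse, report_b$rmse),
    mae = c(report_a$mae, report_b$mae),
    mape = c(report_a$mape, report_b$mape)
  )
  ratio <- report_a$mae / report_b$mae
  structure(list(table = tab, mae_ratio = ratio,
                 mae_ratio_rounded = round(ratio)),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table>\n")
  print(x$table, row.names = FALSE)
  cat(sprintf("  MAE ratio (%s/%s): %.4g (~%d x)\n",
              x$table$model[1], x$table$model[2], x$mae_ratio,
              x$mae_ratio_rounded))
  invisible(x)
}

#' Parity-plot data with the 45-degree reference line
#'
#' @param actual,predicted Numeric vectors of equal length.
#' @return A list: `points` (`data.frame` with `actual`, `predicted`,
#'   `residual = predicted - actual`) and `line` (`data.frame` of the two
#'   endpoints of the 45-degree perfect-prediction line, spanning the pooled
#'   data range).
#' @export
parity_data <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted))
  pooled <- range(c(actual, predicted))
  list(
    points = data.frame(actual = actual, predicted = predicted,
                        residual = predicted - actual),
    line = data.frame(actual = pooled, predicted = pooled)
  )
}
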