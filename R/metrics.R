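#' Regression error metrics
#'
#' The four standard indices used to judge a chlorophyll prediction run:
#' \describe{
#'   \item{RMSE}{root mean square error, `sqrt(mean((T' - T)^2))`.}
#'   \item{MAE}{mean absolute error.}
#'   \item{MAPE}{mean absolute percentage error, `100 * mean(|T' - T| / |T|)`,
#'     computed over samples with nonzero actual value; the number of
#'     excluded zero-actual samples is reported.}
#'   \item{R2}{`1 - sum((T' - T)^2) / sum((mean(T) - T)^2)`; at most 1 and
#'     negative when the predictor is worse than the constant mean.}
#' }
#'
#' @param actual numeric vector of measured values `T`.
#' @param predicted numeric vector of model predictions `T'`, same length.
#' @return An object of class `metric_report`: `rmse`, `mae`, `mape`,
#'   `mape_excluded` (zero-actual count), `r2`, `n_evaluated`.
#' @export
compute_metrics <- function(actual, predicted) {
  actual <- as.numeric(actual)
  predicted <- as.numeric(predicted)
  k <- length(actual)
  if (k < 1L || length(predicted) != k) {
    stop("actual and predicted must have equal positive length")
  }
  if (anyNA(actual) || anyNA(predicted)) stop("missing values in metric input")
  err <- predicted - actual
  rmse <- sqrt(mean(err^2))
  mae <- mean(abs(err))
  nz <- actual != 0
  if (!any(nz)) stop("MAPE undefined: all actual values are zero")
  mape <- 100 * mean(abs(err[nz] / actual[nz]))
  ss_tot <- sum((mean(actual) - actual)^2)
  if (ss_tot == 0) stop("R-squared undefined: actual values have zero variance")
  r2 <- 1 - sum(err^2) / ss_tot
  structure(list(rmse = rmse, mae = mae, mape = mape,
                 mape_excluded = sum(!nz), r2 = r2, n_evaluated = k),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, digits = 4, ...) {
  cat(sprintf("metric_report (n=%d): RMSE %.*g | MAE %.*g | MAPE %.*g%%%s | R2 %.*g\n",
              x$n_evaluated, digits, x$rmse, digits, x$mae, digits, x$mape,
              if (x$mape_excluded > 0)
                sprintf(" (%d zero-actual excluded)", x$mape_excluded) else "",
              digits, x$r2))
  invisible(x)
}
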