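#' Mean absolute error
#'
#' The absolute regression loss and headline metric for age prediction,
#' \eqn{\mathrm{MAE}(y,\hat y) = \frac{1}{N}\sum_i |y_i - \hat y_i|}, in the
#' units of the target (years).
#'
#' @param y numeric vector of true values.
#' @param y_hat numeric vector of predicted values, same length as `y`.
#' @return A single number.
#' @seealso [male()] for the relative (log-ratio) counterpart.
#' @export
#' @examples
#' mae(c(10, 20), c(12, 16)) # 3
mae <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  mean(abs(y - y_hat))
}

#' Mean absolute logarithmic error (relative loss)
#'
#' A scale-insensitive regression loss,
#' \eqn{\mathrm{MALE}(y,\hat y) = \frac{1}{N}\sum_i |\ln(y_i+1) - \ln(\hat y_i+1)|}.
#' Because it penalises the log-ratio of (shifted) true and predicted values,
#' an error of 2 years at age 8 weighs as much as one of 10 years at age 50,
#' which favours accurate prediction of young subjects.
#'
#' Predictions are shifted by one and clamped to a small positive floor before
#' the logarithm so that non-positive model outputs remain finite.
#'
#' @inheritParams mae
#' @param eps positive floor applied to `y_hat + 1` before the logarithm.
#' @return A single number.
#' @export
#' @examples
#' male(1, 0) # log(2)
male <- function(y, y_hat, eps = 1e-6) {
  check_metric_args(y, y_hat)
  if (any(y < 0)) stopf("'y' must be non-negative for the logarithmic loss")
  mean(abs(log(y + 1) - log(pmax(y_hat + 1, eps))))
}

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum_i (y_i-\hat y_i)^2 / \sum_i (y_i-\bar y)^2}: the
#' proportion of target variance explained by the predictions. Can be negative
#' for predictions worse than the mean.
#'
#' @inheritParams mae
#' @return A single number.
#' @export
r_squared <- function(y, y_hat) {
  check_metric_args(y, y_hat)
  if (length(y) < 2L) stopf("r_squared needs at least 2 observations")
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stopf("r_squared is undefined for constant 'y'")
  1 - sum((y - y_hat)^2) / ss_tot
}

#' Upper bound of the 95\% confidence interval across folds
#'
#' Aggregates a per-fold metric into a single conservative score,
#' \eqn{\bar x + 1.96\,\mathrm{sd}(x)/\sqrt{N_{cv}}}, with the sample (N-1)
#' standard deviation. Used to pick the segment length and to report
#' cross-validated errors.
#'
#' @param metric_per_fold numeric vector, one metric value per fold.
#' @param n_cv number of folds; must equal `length(metric_per_fold)`.
#' @return A single number.
#' @export
ci95_upper <- function(metric_per_fold, n_cv = length(metric_per_fold)) {
  if (length(metric_per_fold) != n_cv) {
    stopf("length(metric_per_fold) (%d) != n_cv (%d)",
          length(metric_per_fold), n_cv)
  }
  if (n_cv < 2L) stopf("ci95_upper needs at least 2 folds")
  mean(metric_per_fold) + 1.96 * stats::sd(metric_per_fold) / sqrt(n_cv)
}

check_metric_args <- function(y, y_hat) {
  if (length(y) == 0L) stopf("empty metric input")
  if (length(y) != length(y_hat)) {
    stopf("length mismatch: length(y) = %d, length(y_hat) = %d",
          length(y), length(y_hat))
  }
  if (!is.numeric(y) || !is.numeric(y_hat)) stopf("metric inputs must be numeric")
  if (anyNA(y) || anyNA(y_hat)) stopf("metric inputs contain NA")
  invisible(TRUE)
}
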