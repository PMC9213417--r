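check_paired <- function(y, y_hat) {
  if (length(y) == 0L) stop("empty series")
  if (length(y) != length(y_hat)) stop("length mismatch between y and y_hat")
  if (any(!is.finite(y)) || any(!is.finite(y_hat)))
    stop("non-finite values in paired series")
  invisible(NULL)
}

#' Mean absolute error
#'
#' \deqn{\mathrm{MAE} = \frac{1}{n}\sum_{i=1}^n |y_i - \hat y_i|}
#'
#' @param y real values.
#' @param y_hat predicted values, same length.
#' @return Nonnegative scalar; 0 iff the forecast is perfect.
#' @export
#' @examples
#' mae(c(0, 2), c(1, 1))  # 1
mae <- function(y, y_hat) {
  check_paired(y, y_hat)
  mean(abs(y - y_hat))
}

#' Mean squared error
#'
#' \deqn{\mathrm{MSE} = \frac{1}{n}\sum_{i=1}^n (y_i - \hat y_i)^2}
#'
#' @inheritParams mae
#' @return Nonnegative scalar; always >= mae(y, y_hat)^2.
#' @export
mse <- function(y, y_hat) {
  check_paired(y, y_hat)
  mean((y - y_hat)^2)
}

#' Mean absolute scaled error
#'
#' Forecast MAE divided by the in-sample mean absolute error of the one-step
#' naive forecast on \code{reference}:
#' \deqn{\mathrm{MASE} = \frac{\frac{1}{n}\sum_j |y_j - \hat y_j|}
#'   {\frac{1}{m-1}\sum_{i=2}^m |r_i - r_{i-1}|}}
#' The reference defaults to \code{y} itself; for hold-out evaluation pass the
#' full time-ordered series of real values.
#'
#' @inheritParams mae
#' @param reference time-ordered series whose one-step naive error scales the
#'   numerator; length >= 2 and not constant.
#' @return Nonnegative scalar, unitless; 1 means the forecast errs as much as
#'   the naive one-step-behind forecast.
#' @export
#' @examples
#' mase(1:4, 2:5)  # 1
mase <- function(y, y_hat, reference = y) {
  check_paired(y, y_hat)
  if (length(reference) < 2L) stop("reference must have length >= 2")
  if (any(!is.finite(reference))) stop("non-finite reference values")
  denom <- mean(abs(diff(reference)))
  if (denom == 0) stop("zero naive error: constant reference series")
  mean(abs(y - y_hat)) / denom
}
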