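as_series_matrix <- function(series) {
  x <- as.matrix(series)
  if (!is.numeric(x)) stop("series must be numeric")
  if (any(!is.finite(x))) stop("non-finite values in series")
  x
}

#' Moving-average forecast
#'
#' One-step forecast = mean of the last \code{window} observations, per
#' column; multi-step forecasts roll forward, appending each forecast to the
#' history before the next step.
#'
#' @param series numeric vector or time-by-variable matrix, ordered in time.
#' @param window number of trailing observations averaged (>= 1).
#' @param horizon number of steps to forecast (>= 1).
#' @return horizon-by-variable matrix of forecasts.
#' @export
#' @examples
#' ma_forecast(c(1, 3, 5), window = 2, horizon = 2)  # 4, 4.5
ma_forecast <- function(series, window = 3, horizon = 1) {
  x <- as_series_matrix(series)
  stopifnot(window >= 1, horizon >= 1)
  if (nrow(x) < window) stop("window larger than series length")
  out <- matrix(NA_real_, horizon, ncol(x), dimnames = list(NULL, colnames(x)))
  for (h in seq_len(horizon)) {
    out[h, ] <- colMeans(x[nrow(x) - window + seq_len(window), , drop = FALSE])
    x <- rbind(x, out[h, ])
  }
  out
}

#' Fit a vector autoregression by least squares
#'
#' Equation-by-equation OLS of \eqn{y_t = c + A_1 y_{t-1} + \dots +
#' A_p y_{t-p} + e_t} over the rows of \code{series}.
#'
#' @param series numeric vector or time-by-variable matrix, ordered in time,
#'   with at least \code{order + 5} rows.
#' @param order lag order p (>= 1).
#' @return A \code{fry_var} model: list with \code{order}, \code{intercept}
#'   (length-k vector) and \code{coef} (list of p k-by-k lag matrices, the
#'   entry [i, j] weighting variable j at that lag in the equation for
#'   variable i).
#' @export
var_fit <- function(series, order = 1) {
  x <- as_series_matrix(series)
  stopifnot(order >= 1)
  n <- nrow(x); k <- ncol(x)
  if (n < order + 5) stop("series too short for the requested order")
  Y <- x[(order + 1):n, , drop = FALSE]
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(l)
    x[(order + 1 - l):(n - l), , drop = FALSE])))
  qx <- qr(X)
  if (qx$rank < ncol(X)) stop("singular design")
  B <- qr.coef(qx, Y)  # (1 + k*order) x k
  coefs <- lapply(seq_len(order), function(l)
    t(B[1 + (l - 1) * k + seq_len(k), , drop = FALSE]))
  structure(list(order = order, intercept = as.numeric(B[1, ]), coef = coefs,
                 k = k),
            class = "fry_var")
}

#' Forecast from a fitted VAR
#'
#' Applies the recursion \eqn{\hat y_{t+1} = c + \sum_l A_l y_{t+1-l}},
#' appending each forecast to the history for multi-step horizons.
#'
#' @param model a \code{fry_var} from \code{\link{var_fit}}.
#' @param history time-by-variable matrix ending at the forecast origin, with
#'   at least \code{model$order} rows.
#' @param horizon number of steps ahead.
#' @return horizon-by-variable matrix of forecasts.
#' @export
var_forecast <- function(model, history, horizon = 1) {
  stopifnot(inherits(model, "fry_var"), horizon >= 1)
  x <- as_series_matrix(history)
  if (ncol(x) != model$k) stop("history has wrong number of variables")
  if (nrow(x) < model$order) stop("history shorter than model order")
  out <- matrix(NA_real_, horizon, ncol(x), dimnames = list(NULL, colnames(x)))
  for (h in seq_len(horizon)) {
    f <- model$intercept
    for (l in seq_len(model$order))
      f <- f + as.numeric(model$coef[[l]] %*% x[nrow(x) + 1 - l, ])
    out[h, ] <- f
    x <- rbind(x, f)
  }
  out
}
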