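#' Default simulation parameters
#'
#' Per-indicator coefficients of the deterministic trend
#' \deqn{\mu_k(t, T) = a_k (t/36)^{p_k} \exp\{b_k (T - 140)/40\}}
#' plus the additive-noise standard deviation \code{sigma}. The defaults were
#' obtained by log-linear least squares against the seven published real-value
#' measurements (see \code{\link{table1_fixture}}) and reproduce each of those
#' cells to within 26\% relative error. \code{sigma} defaults to 5\% of the
#' trend value at the most severe condition (36 h, 180 degrees C).
#'
#' @param sigma_scale multiplier applied to the default noise level; 0 gives a
#'   noiseless dataset.
#' @return A list with one element per indicator (\code{av}, \code{tpc},
#'   \code{tgp}, \code{tfa}), each holding \code{a} (amplitude, indicator
#'   units), \code{p} (time exponent, dimensionless), \code{b} (temperature
#'   sensitivity per 40 degrees C, dimensionless) and \code{sigma} (noise SD,
#'   indicator units).
#' @export
#' @examples
#' default_sim_params()$av
default_sim_params <- function(sigma_scale = 1) {
  stopifnot(is.numeric(sigma_scale), length(sigma_scale) == 1L, sigma_scale >= 0)
  base <- list(
    av  = list(a = 2.31034,  p = 0.78400, b = 0.70572),
    tpc = list(a = 16.91537, p = 0.53253, b = 0.63595),
    tgp = list(a = 10.96025, p = 0.90213, b = 0.21613),
    tfa = list(a = 0.12343,  p = 0.31492, b = 0.71808)
  )
  lapply(base, function(ind) {
    ind$sigma <- sigma_scale * 0.05 * ind$a * exp(ind$b)
    ind
  })
}

validate_sim_params <- function(params) {
  if (!is.list(params) || !all(INDICATORS %in% names(params)))
    stop("params must be a list with elements av, tpc, tgp, tfa")
  for (k in INDICATORS) {
    ind <- params[[k]]
    if (!all(c("a", "p", "b", "sigma") %in% names(ind)))
      stop("params$", k, " must have fields a, p, b, sigma")
    if (!isTRUE(ind$a > 0)) stop("params$", k, "$a must be > 0")
    if (!isTRUE(ind$p > 0)) stop("params$", k, "$p must be > 0")
    if (!isTRUE(ind$b >= 0)) stop("params$", k, "$b must be >= 0")
    if (!isTRUE(ind$sigma >= 0)) stop("negative sigma for indicator ", k)
  }
  invisible(params)
}

#' The default experimental condition grid
#'
#' Five frying temperatures (140, 150, ..., 180 degrees C) crossed with
#' sampling every 4 h from the raw oil (t = 0) up to 36 h: 50 conditions,
#' i.e. 200 indicator values over the four indices.
#'
#' @return A data frame with columns \code{time_h} and \code{temp_C}, ordered
#'   by temperature then time.
#' @export
#' @examples
#' nrow(default_grid())  # 50
default_grid <- function() {
  g <- expand.grid(time_h = seq(0, 36, by = 4),
                   temp_C = seq(140, 180, by = 10),
                   KEEP.OUT.ATTRS = FALSE)
  g <- g[order(g$temp_C, g$time_h), c("time_h", "temp_C")]
  rownames(g) <- NULL
  g
}

trend_value <- function(time_h, temp_C, ind) {
  ind$a * (time_h / 36)^ind$p * exp(ind$b * (temp_C - 140) / 40)
}

#' Simulate a frying-oil deterioration dataset
#'
#' Draws, for every (time, temperature) condition on \code{grid}, the four
#' deterioration indices as deterministic monotone trend + truncated Gaussian
#' noise:
#' \deqn{y_k = \max\{0,\; \mu_k(t, T) + \epsilon_k\},\quad
#'       \epsilon_k \sim N(0, \sigma_k^2).}
#' With \code{sigma = 0} the values are exactly the trend, nondecreasing in
#' both time and temperature.
#'
#' @param grid data frame of conditions with columns \code{time_h},
#'   \code{temp_C} (e.g. \code{\link{default_grid}}).
#' @param params simulation parameters, see \code{\link{default_sim_params}}.
#' @param seed integer seed; the same (grid, params, seed) always yields the
#'   identical dataset.
#' @return A \code{fry_dataset}: data frame with columns \code{time_h},
#'   \code{temp_C}, \code{av}, \code{tpc}, \code{tgp}, \code{tfa} and a
#'   \code{split} column initialised to \code{"train"}.
#' @export
#' @examples
#' ds <- simulate_dataset(default_grid(), default_sim_params(0), seed = 1)
#' head(ds)
simulate_dataset <- function(grid, params = default_sim_params(), seed = 1) {
  if (!is.data.frame(grid) || nrow(grid) == 0L) stop("empty condition grid")
  if (!all(c("time_h", "temp_C") %in% names(grid)))
    stop("grid must have columns time_h and temp_C")
  if (any(!is.finite(grid$time_h)) || any(grid$time_h < 0))
    stop("time_h must be finite and >= 0")
  if (any(grid$temp_C < 140) || any(grid$temp_C > 180))
    warning("temperatures outside the calibrated 140-180 C range")
  validate_sim_params(params)

  ds <- data.frame(time_h = grid$time_h, temp_C = grid$temp_C)
  n <- nrow(ds)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  for (k in INDICATORS) {
    ind <- params[[k]]
    mu <- trend_value(ds$time_h, ds$temp_C, ind)
    eps <- if (ind$sigma > 0) stats::rnorm(n, 0, ind$sigma) else numeric(n)
    ds[[k]] <- pmax(0, mu + eps)
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ds$split <- "train"
  class(ds) <- c("fry_dataset", "data.frame")
  ds
}

#' Published test-condition fixture
#'
#' The seven held-out conditions with their measured ("real") indicator values,
#' as published, plus the model predictions printed alongside them. Note one
#' predicted acid value is negative (-0.0706): the regressor's output layer is
#' linear and predictions are not clipped.
#'
#' @return A list with elements \code{real} (a \code{fry_dataset} of 7 records,
#'   split label \code{"test"}) and \code{predicted} (a data frame of the
#'   corresponding reference predictions, same column order).
#' @export
#' @examples
#' table1_fixture()$real[1, ]
table1_fixture <- function() {
  real <- data.frame(
    time_h = c(4, 8, 8, 16, 20, 28, 28),
    temp_C = c(150, 180, 140, 140, 170, 140, 150),
    av  = c(0.4653, 1.4942, 0.7041, 1.4387, 2.3514, 1.6464, 2.3987),
    tpc = c(6.50, 12.40, 7.80, 10.70, 23.60, 13.40, 17.70),
    tgp = c(1.71, 3.50, 2.84, 4.21, 7.19, 9.75, 10.12),
    tfa = c(0.0796, 0.1292, 0.0811, 0.0892, 0.2210, 0.1009, 0.1412),
    split = "test"
  )
  class(real) <- c("fry_dataset", "data.frame")
  predicted <- data.frame(
    time_h = real$time_h,
    temp_C = real$temp_C,
    av  = c(0.0019, 2.0568, -0.0706, 0.8481, 2.9030, 2.2261, 2.7580),
    tpc = c(6.6604, 16.2901, 6.2470, 10.4405, 20.0702, 16.7313, 19.2421),
    tgp = c(1.0424, 4.2830, 1.8503, 4.6824, 7.9230, 8.9303, 9.5388),
    tfa = c(0.2914, 0.1701, 0.2956, 0.2419, 0.1206, 0.1611, 0.1297)
  )
  list(real = real, predicted = predicted)
}

#' Assign train/validation/test split labels
#'
#' Two protocols. \code{"time_holdout"} mirrors the benchmark protocol of
#' holding out the latest sampled frying times: every record whose
#' \code{time_h} is in \code{holdout_times} (default: the two largest times
#' present) goes to \code{test}, and the remainder is split train/validation
#' at random. \code{"random"} assigns all three labels at random with the
#' given fractions.
#'
#' @param ds a \code{fry_dataset}.
#' @param mode \code{"random"} or \code{"time_holdout"}.
#' @param fractions named or positional numeric vector (train, val, test)
#'   summing to 1; in \code{time_holdout} mode only the train:val ratio is
#'   used.
#' @param holdout_times times routed to the test set (time_holdout mode).
#' @param seed integer seed for the random assignments.
#' @return The dataset with its \code{split} column filled in.
#' @export
split_dataset <- function(ds, mode = c("time_holdout", "random"),
                          fractions = c(train = 0.7, val = 0.15, test = 0.15),
                          holdout_times = NULL, seed = 1) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(ds), nrow(ds) >= 3L)
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  n <- nrow(ds)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  if (mode == "random") {
    if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
    n_train <- round(fractions[[1]] * n)
    n_val <- round(fractions[[2]] * n)
    lab <- rep("test", n)
    idx <- sample.int(n)
    lab[idx[seq_len(n_train)]] <- "train"
    lab[idx[n_train + seq_len(n_val)]] <- "val"
    ds$split <- lab
  } else {
    if (is.null(holdout_times)) {
      times <- sort(unique(ds$time_h), decreasing = TRUE)
      holdout_times <- times[seq_len(min(2L, length(times)))]
    }
    if (!all(holdout_times %in% ds$time_h))
      stop("holdout times absent from dataset: ",
           paste(setdiff(holdout_times, ds$time_h), collapse = ", "))
    test <- ds$time_h %in% holdout_times
    rest <- which(!test)
    p_val <- fractions[[2]] / (fractions[[1]] + fractions[[2]])
    n_val <- max(1L, round(p_val * length(rest)))
    val_idx <- sample(rest, n_val)
    ds$split <- "train"
    ds$split[val_idx] <- "val"
    ds$split[test] <- "test"
  }
  if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  ds
}
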