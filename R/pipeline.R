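# Benchmark protocol: hold out the latest frying times, train the adversarial
# regressor on the remainder, and forecast the held-out times per temperature
# with the moving-average and VAR baselines for comparison.

#' Forecast the held-out times with all three models
#'
#' The dataset must carry a time-holdout split (see
#' \code{\link{split_dataset}}): the test records are the latest sampled
#' times of every temperature series. The GAN regressor predicts them from
#' (time, temperature); the moving-average and VAR baselines are fitted per
#' temperature series on the earlier (train + val) time points and rolled
#' forward over the held-out horizon.
#'
#' @param ds a split \code{fry_dataset}.
#' @param config training configuration for the regressor.
#' @param ma_window moving-average window (observations).
#' @param var_order VAR lag order.
#' @return List with \code{truth} (the test records), \code{pred} (named list
#'   of prediction data frames for \code{gan}, \code{ma}, \code{var}, each
#'   aligned row-by-row with \code{truth}), and \code{model} (the trained
#'   \code{fry_gan}).
#' @export
benchmark_forecasts <- function(ds, config = fry_train_config(),
                                ma_window = 3, var_order = 1) {
  stopifnot(is.data.frame(ds), all(c("train", "val", "test") %in% ds$split))
  truth <- ds[ds$split == "test", , drop = FALSE]
  truth <- truth[order(truth$temp_C, truth$time_h), , drop = FALSE]

  model <- train_gan(ds, config)
  gan_pred <- generator_forward(model, truth)

  ma_pred <- truth; var_pred <- truth
  for (temp in unique(truth$temp_C)) {
    hist_rows <- ds[ds$split != "test" & ds$temp_C == temp, , drop = FALSE]
    hist_rows <- hist_rows[order(hist_rows$time_h), , drop = FALSE]
    test_rows <- which(truth$temp_C == temp)
    horizon <- length(test_rows)
    H <- as.matrix(hist_rows[, INDICATORS])
    ma_pred[test_rows, INDICATORS] <- ma_forecast(H, ma_window, horizon)
    vm <- var_fit(H, var_order)
    var_pred[test_rows, INDICATORS] <- var_forecast(vm, H, horizon)
  }
  list(truth = truth,
       pred = list(gan = gan_pred, ma = ma_pred, var = var_pred),
       model = model)
}

pooled_naive_error <- function(ds) {
  diffs <- unlist(lapply(split(as.data.frame(ds), ds$temp_C), function(s) {
    s <- s[order(s$time_h), , drop = FALSE]
    lapply(INDICATORS, function(k) abs(diff(s[[k]])))
  }))
  mean(diffs)
}

#' Score forecasts against held-out truth
#'
#' Computes pooled MAE, MSE and MASE over all (condition, indicator) pairs in
#' the test set, in raw indicator units; per-indicator values are attached as
#' the \code{"per_indicator"} attribute. The MASE denominator is the mean
#' one-step absolute difference pooled over every per-temperature,
#' per-indicator real series of the full dataset (the naive-forecast error of
#' the data the forecasters saw), identical for every model so the scaled
#' errors are directly comparable.
#'
#' @param truth test records (real values).
#' @param preds named list of aligned prediction data frames.
#' @param full_ds the complete dataset providing the MASE reference series.
#' @return Data frame with columns \code{model}, \code{mase}, \code{mse},
#'   \code{mae}, one row per model, ordered as given.
#' @export
score_forecasts <- function(truth, preds, full_ds) {
  denom <- pooled_naive_error(full_ds)
  if (denom == 0) stop("zero naive error: constant reference series")
  per_ind <- list()
  rows <- lapply(names(preds), function(nm) {
    p <- preds[[nm]]
    y <- unlist(truth[, INDICATORS]); yh <- unlist(p[, INDICATORS])
    per_ind[[nm]] <<- vapply(INDICATORS, function(k)
      c(mae = mae(truth[[k]], p[[k]]), mse = mse(truth[[k]], p[[k]])),
      numeric(2))
    data.frame(model = nm, mase = mae(y, yh) / denom, mse = mse(y, yh),
               mae = mae(y, yh))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_indicator") <- per_ind
  out
}

#' Run the full workflow: simulate, train, predict, classify, benchmark
#'
#' Simulates a dataset on the default condition grid, holds out the two
#' latest frying times, trains the adversarial regressor, forecasts the
#' held-out conditions with the regressor and both baselines, scores all
#' three, and classifies every regressor prediction against the regulatory
#' thresholds. With \code{out_dir} set, writes \code{data.csv},
#' \code{model.json}, \code{trace.csv}, \code{predictions.csv},
#' \code{verdicts.json} and \code{metrics.csv}. Fully reproducible from
#' \code{seed}.
#'
#' @param seed master seed; the simulation, split and training seeds are
#'   derived from it.
#' @param config run configuration, see \code{\link{default_run_config}}.
#' @param out_dir optional artifact directory (created if missing).
#' @return List with \code{dataset}, \code{model}, \code{metrics} (the
#'   3 model x 3 metric table), \code{predictions}, \code{verdicts} and
#'   \code{truth}.
#' @export
run_pipeline <- function(seed = 0, config = default_run_config(),
                         out_dir = NULL) {
  params <- default_sim_params(config$sigma_scale)
  ds <- simulate_dataset(default_grid(), params, seed = seed)
  ds <- split_dataset(ds, "time_holdout", seed = seed + 1L)

  tc <- config$train
  tcfg <- fry_train_config(max_iterations = tc$max_iterations,
                           lr_g = tc$lr_g, lr_d = tc$lr_d,
                           lambda = tc$lambda, d_steps = tc$d_steps,
                           hidden = tc$hidden, eval_every = tc$eval_every,
                           seed = seed)
  bench <- benchmark_forecasts(ds, tcfg, config$ma_window, config$var_order)
  metrics <- score_forecasts(bench$truth, bench$pred, ds)
  metrics$model <- c(gan = "GAN-R", ma = "MA", var = "VAR")[metrics$model]
  per_ind <- attr(metrics, "per_indicator")
  metrics <- metrics[match(c("MA", "VAR", "GAN-R"), metrics$model), ]
  rownames(metrics) <- NULL
  attr(metrics, "per_indicator") <- per_ind

  th <- do.call(default_thresholds, config$thresholds)
  verdicts <- lapply(seq_len(nrow(bench$pred$gan)), function(i) {
    v <- classify_deterioration(bench$pred$gan[i, ], th)
    c(list(time_h = bench$pred$gan$time_h[i],
           temp_C = bench$pred$gan$temp_C[i]),
      v[c("deteriorated", "triggered")])
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_dataset_csv(ds, file.path(out_dir, "data.csv"))
    write_model_json(bench$model, file.path(out_dir, "model.json"))
    write_trace_csv(bench$model, file.path(out_dir, "trace.csv"))
    pred <- bench$pred$gan
    pred$split <- "test"
    write_dataset_csv(pred, file.path(out_dir, "predictions.csv"))
    jsonlite::write_json(verdicts, file.path(out_dir, "verdicts.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(metrics, file.path(out_dir, "metrics.csv"),
                     row.names = FALSE)
  }

  list(dataset = ds, model = bench$model, metrics = metrics,
       predictions = bench$pred, verdicts = verdicts, truth = bench$truth)
}
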