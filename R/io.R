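DATASET_COLS <- c("time_h", "temp_C", INDICATORS)

#' Read a dataset from the interchange CSV format
#'
#' Expects the header \code{time_h,temp_C,av,tpc,tgp,tfa} with an optional
#' trailing \code{split} column; any other column set is rejected. Values use
#' '.' as the decimal separator.
#'
#' @param path CSV file path.
#' @return A \code{fry_dataset} data frame.
#' @export
read_dataset_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  missing <- setdiff(DATASET_COLS, names(raw))
  if (length(missing))
    stop("missing column(s): ", paste(missing, collapse = ", "))
  extra <- setdiff(names(raw), c(DATASET_COLS, "split"))
  if (length(extra))
    stop("unknown column(s): ", paste(extra, collapse = ", "))
  ds <- data.frame(row.names = seq_len(nrow(raw)))
  for (col in DATASET_COLS) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !is.na(raw[[col]]) | is.na(raw[[col]]))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at row ", bad[1])
    ds[[col]] <- v
  }
  ds$split <- if ("split" %in% names(raw)) raw$split else "train"
  if (!all(ds$split %in% c("train", "val", "test")))
    stop("split labels must be train, val or test")
  if (any(ds$time_h < 0)) stop("negative frying time")
  if (any(ds$temp_C < 140 | ds$temp_C > 180))
    warning("temperatures outside the calibrated 140-180 C range")
  class(ds) <- c("fry_dataset", "data.frame")
  ds
}

#' Write a dataset to the interchange CSV format
#'
#' Indicator values are written with 6 decimals (enough to round-trip the
#' 4-decimal published precision); byte output is deterministic for a fixed
#' dataset.
#'
#' @param ds a \code{fry_dataset}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_dataset_csv <- function(ds, path) {
  stopifnot(is.data.frame(ds), all(DATASET_COLS %in% names(ds)))
  lines <- c(paste(c(DATASET_COLS, "split"), collapse = ","),
             vapply(seq_len(nrow(ds)), function(i) {
               paste(c(sprintf("%g", ds$time_h[i]), sprintf("%g", ds$temp_C[i]),
                       sprintf("%.6f", unlist(ds[i, INDICATORS])),
                       if ("split" %in% names(ds)) ds$split[i] else "train"),
                     collapse = ",")
             }, character(1)))
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(path)
}

#' Serialize / load a trained model as JSON
#'
#' The JSON carries the generator and discriminator weights (best-validation
#' generator snapshot), normalisation statistics, and an echo of the training
#' configuration; the training trace is not included (write it separately with
#' \code{\link{write_trace_csv}}).
#'
#' @param model a \code{fry_gan}.
#' @param path JSON file path.
#' @return \code{path} invisibly (write) or the reconstructed \code{fry_gan}
#'   (read).
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "fry_gan"))
  ser_net <- function(net) list(sizes = net$sizes, W = net$W, b = net$b)
  obj <- list(schema = "frygan-model-1",
              generator = ser_net(model$gen),
              discriminator = ser_net(model$disc),
              norm = model$norm,
              config = unclass(model$config),
              best_val_mse = model$best_val_mse)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model_json
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$schema, "frygan-model-1")) stop("not a frygan model file")
  de_net <- function(x) list(
    W = lapply(x$W, function(w) if (is.matrix(w)) w else as.matrix(w)),
    b = lapply(x$b, as.numeric), sizes = as.integer(x$sizes))
  cfg <- obj$config
  config <- fry_train_config(cfg$max_iterations, cfg$lr_g, cfg$lr_d,
                             cfg$lambda, cfg$d_steps, cfg$hidden,
                             cfg$batch_size, cfg$latent_dim,
                             cfg$conditional_discriminator, cfg$eval_every,
                             cfg$seed)
  gen <- de_net(obj$generator)
  structure(list(gen = gen, final_gen = gen, disc = de_net(obj$discriminator),
                 norm = list(mean = unlist(obj$norm$mean),
                             sd = unlist(obj$norm$sd)),
                 config = config, best_val_mse = obj$best_val_mse,
                 trace = NULL),
            class = "fry_gan")
}

#' Write the training trace as CSV
#'
#' Columns \code{iteration,g_loss,d_loss,train_mse,val_mse}, one row per
#' logged evaluation.
#'
#' @param model a \code{fry_gan} with a trace, or the trace data frame itself.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_trace_csv <- function(model, path) {
  trace <- if (inherits(model, "fry_gan")) model$trace else model
  stopifnot(is.data.frame(trace))
  utils::write.csv(trace, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a run configuration (YAML)
#'
#' A run configuration bundles training hyperparameters, simulation settings
#' and threshold overrides; it round-trips losslessly through YAML.
#'
#' @param path YAML file path.
#' @param config list as produced by \code{\link{default_run_config}}.
#' @return The configuration list (read) or \code{path} invisibly (write).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$schema)) cfg$schema <- "frygan-run-1"
  utils::modifyList(default_run_config(), cfg)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' @rdname read_run_config
#' @export
default_run_config <- function() {
  list(schema = "frygan-run-1",
       sigma_scale = 1,
       train = list(max_iterations = 6000, lr_g = 1e-3, lr_d = 1e-3,
                    lambda = 1, d_steps = 1, hidden = c(32L, 32L),
                    eval_every = 50),
       ma_window = 3, var_order = 1,
       thresholds = as.list(default_thresholds()))
}
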