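# Shared fixtures, built in code.

IND <- c("av", "tpc", "tgp", "tfa")

# Noiseless dataset on the default grid with the time-holdout split.
noiseless_split_ds <- function(seed = 1) {
  ds <- simulate_dataset(default_grid(), default_sim_params(0), seed = seed)
  split_dataset(ds, "time_holdout", seed = seed)
}

# A short training run for structural tests (not for convergence claims).
quick_config <- function(seed = 0, iters = 300) {
  fry_train_config(max_iterations = iters, eval_every = 50, seed = seed)
}

# Cache one quick model per session to keep unit tests fast.
.quick_model_env <- new.env()
quick_model <- function() {
  if (is.null(.quick_model_env$m))
    .quick_model_env$m <- train_gan(noiseless_split_ds(), quick_config())
  .quick_model_env$m
}

# Zero out every weight and bias of a network.
zero_net <- function(net) {
  net$W <- lapply(net$W, function(w) w * 0)
  net$b <- lapply(net$b, function(b) b * 0)
  net
}
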