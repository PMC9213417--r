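# Small dense networks in plain matrix algebra. The generator maps a
# (time, temperature) condition to the 4 indices; the discriminator maps an
# indicator vector to a real/fake probability. Everything runs in standardized
# units internally; only generator_forward/predict denormalize.

mlp_init <- function(sizes) {
  L <- length(sizes) - 1L
  W <- vector("list", L); b <- vector("list", L)
  for (i in seq_len(L)) {
    lim <- sqrt(6 / (sizes[i] + sizes[i + 1]))  # Glorot uniform
    W[[i]] <- matrix(stats::runif(sizes[i] * sizes[i + 1], -lim, lim),
                     sizes[i], sizes[i + 1])
    b[[i]] <- numeric(sizes[i + 1])
  }
  list(W = W, b = b, sizes = sizes)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

mlp_forward <- function(net, X, out = c("linear", "sigmoid")) {
  out <- match.arg(out)
  L <- length(net$W)
  A <- vector("list", L + 1L); Z <- vector("list", L)
  A[[1]] <- X
  for (i in seq_len(L)) {
    Z[[i]] <- sweep(A[[i]] %*% net$W[[i]], 2, net$b[[i]], "+")
    A[[i + 1]] <- if (i < L) pmax(Z[[i]], 0) else
      switch(out, linear = Z[[i]],
             sigmoid = pmin(pmax(sigmoid(Z[[i]]), 1e-7), 1 - 1e-7))
  }
  list(A = A, Z = Z, out = A[[L + 1]])
}

# dZL: gradient w.r.t. the final pre-activation. Returns parameter gradients
# and the gradient w.r.t. the network input.
mlp_backward <- function(net, cache, dZL) {
  L <- length(net$W)
  dW <- vector("list", L); db <- vector("list", L)
  dZ <- dZL
  for (i in rev(seq_len(L))) {
    dW[[i]] <- crossprod(cache$A[[i]], dZ)
    db[[i]] <- colSums(dZ)
    dA <- dZ %*% t(net$W[[i]])
    if (i > 1L) dZ <- dA * (cache$Z[[i - 1L]] > 0)
  }
  list(dW = dW, db = db, dX = dA)
}

adam_init <- function(net) {
  zero <- function(p) lapply(p, function(x) x * 0)
  list(mW = zero(net$W), vW = zero(net$W), mb = zero(net$b), vb = zero(net$b),
       t = 0L)
}

adam_step <- function(net, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  c1 <- 1 - beta1^state$t; c2 <- 1 - beta2^state$t
  for (i in seq_along(net$W)) {
    state$mW[[i]] <- beta1 * state$mW[[i]] + (1 - beta1) * grads$dW[[i]]
    state$vW[[i]] <- beta2 * state$vW[[i]] + (1 - beta2) * grads$dW[[i]]^2
    net$W[[i]] <- net$W[[i]] -
      lr * (state$mW[[i]] / c1) / (sqrt(state$vW[[i]] / c2) + eps)
    state$mb[[i]] <- beta1 * state$mb[[i]] + (1 - beta1) * grads$db[[i]]
    state$vb[[i]] <- beta2 * state$vb[[i]] + (1 - beta2) * grads$db[[i]]^2
    net$b[[i]] <- net$b[[i]] -
      lr * (state$mb[[i]] / c1) / (sqrt(state$vb[[i]] / c2) + eps)
  }
  list(net = net, state = state)
}

#' Training configuration for the adversarial regressor
#'
#' @param max_iterations adversarial iterations (one iteration = \code{d_steps}
#'   discriminator updates followed by one generator update).
#' @param lr_g,lr_d Adam learning rates for generator and discriminator.
#' @param lambda weight of the mean-squared-error term in the generator
#'   objective, in standardized units.
#' @param d_steps discriminator updates per generator update.
#' @param hidden hidden-layer widths shared by both networks.
#' @param batch_size rows per update; \code{NULL} (default) uses the full
#'   training split, appropriate at this dataset scale.
#' @param latent_dim optional latent-noise inputs appended to the generator's
#'   condition input; 0 (default) makes the generator a deterministic
#'   regressor.
#' @param conditional_discriminator if \code{TRUE} the discriminator also sees
#'   the normalized condition alongside the 4 indicator values; off by
#'   default.
#' @param eval_every iterations between trace/validation evaluations.
#' @param seed integer seed governing initialisation and any sampling.
#' @return A \code{fry_train_config} list.
#' @export
fry_train_config <- function(max_iterations = 6000, lr_g = 1e-3, lr_d = 1e-3,
                             lambda = 1, d_steps = 1, hidden = c(32, 32),
                             batch_size = NULL, latent_dim = 0,
                             conditional_discriminator = FALSE,
                             eval_every = 50, seed = 0) {
  stopifnot(max_iterations >= 1, lr_g > 0, lr_d > 0, lambda >= 0,
            d_steps >= 1, all(hidden >= 1), latent_dim >= 0, eval_every >= 1)
  structure(list(max_iterations = as.integer(max_iterations), lr_g = lr_g,
                 lr_d = lr_d, lambda = lambda, d_steps = as.integer(d_steps),
                 hidden = as.integer(hidden),
                 batch_size = if (!is.null(batch_size)) as.integer(batch_size),
                 latent_dim = as.integer(latent_dim),
                 conditional_discriminator = isTRUE(conditional_discriminator),
                 eval_every = as.integer(eval_every), seed = as.integer(seed)),
            class = "fry_train_config")
}

normalize_conditions <- function(conditions) {
  x <- as.data.frame(conditions)
  if (!all(c("time_h", "temp_C") %in% names(x)))
    stop("conditions need columns time_h and temp_C")
  if (any(!is.finite(x$time_h)) || any(!is.finite(x$temp_C)))
    stop("non-finite condition")
  cbind(x$time_h / 36, (x$temp_C - 140) / 40)
}

standardize <- function(Y, norm) sweep(sweep(Y, 2, norm$mean), 2, norm$sd, "/")
destandardize <- function(Ys, norm) sweep(sweep(Ys, 2, norm$sd, "*"), 2,
                                          norm$mean, "+")

#' Discriminator cross-entropy loss
#'
#' \code{-mean(log real_probs) - mean(log(1 - fake_probs))}: minimised when
#' real samples score near 1 and generated samples near 0. Equals
#' \code{2 log 2} when every probability is 0.5.
#'
#' @param real_probs,fake_probs probabilities strictly inside (0, 1).
#' @return Nonnegative scalar.
#' @export
discriminator_loss <- function(real_probs, fake_probs) {
  p <- c(real_probs, fake_probs)
  if (any(!is.finite(p)) || any(p <= 0) || any(p >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  -mean(log(real_probs)) - mean(log(1 - fake_probs))
}

#' Generator loss: non-saturating adversarial term plus weighted MSE
#'
#' \code{-mean(log fake_probs) + lambda * mean((predicted - real)^2)}, the MSE
#' taken elementwise over all indicator components (standardized units during
#' training). \code{lambda = 0} recovers the pure adversarial objective.
#'
#' @param fake_probs discriminator scores of the generated vectors, in (0, 1).
#' @param predicted,real matrices of identical shape.
#' @param lambda nonnegative MSE weight.
#' @return Finite scalar.
#' @export
generator_loss <- function(fake_probs, predicted, real, lambda = 1) {
  if (any(!is.finite(fake_probs)) || any(fake_probs <= 0) ||
      any(fake_probs >= 1))
    stop("probabilities must lie strictly in (0, 1)")
  if (lambda < 0) stop("lambda must be >= 0")
  predicted <- as.matrix(predicted); real <- as.matrix(real)
  if (!identical(dim(predicted), dim(real))) stop("shape mismatch")
  -mean(log(fake_probs)) + lambda * mean((predicted - real)^2)
}

gen_input <- function(Xc, latent_dim) {
  if (latent_dim > 0)
    Xc <- cbind(Xc, matrix(stats::rnorm(nrow(Xc) * latent_dim), nrow(Xc)))
  Xc
}

disc_input <- function(Ys, Xc, config) {
  if (config$conditional_discriminator) cbind(Xc, Ys) else Ys
}

#' Train the adversarial regressor
#'
#' Alternates \code{d_steps} discriminator updates (real indicator vectors vs
#' generated ones) with one generator update per iteration, the generator
#' minimising the non-saturating adversarial loss plus \code{lambda} times the
#' regression MSE, all in standardized units. Indicator normalisation
#' statistics are frozen from the training split. The returned model is the
#' parameter snapshot with the best validation MSE seen at any evaluation
#' point.
#'
#' @param ds a \code{fry_dataset} with non-empty \code{train} and \code{val}
#'   splits.
#' @param config a \code{\link{fry_train_config}}.
#' @return A \code{fry_gan} model carrying generator and discriminator
#'   weights, the normalisation statistics, the config, and \code{$trace}: a
#'   data frame of (iteration, g_loss, d_loss, train_mse, val_mse) logged
#'   every \code{eval_every} iterations (MSEs in standardized units).
#' @export
train_gan <- function(ds, config = fry_train_config()) {
  stopifnot(is.data.frame(ds), inherits(config, "fry_train_config"))
  tr <- ds[ds$split == "train", , drop = FALSE]
  va <- ds[ds$split == "val", , drop = FALSE]
  if (nrow(tr) == 0L) stop("no training records")
  if (nrow(va) == 0L) stop("no validation records")

  Y_tr <- as.matrix(tr[, INDICATORS])
  norm <- list(mean = colMeans(Y_tr), sd = apply(Y_tr, 2, stats::sd))
  norm$sd[norm$sd == 0 | !is.finite(norm$sd)] <- 1
  Ys_tr <- standardize(Y_tr, norm)
  Ys_va <- standardize(as.matrix(va[, INDICATORS]), norm)
  Xc_tr <- normalize_conditions(tr)
  Xc_va <- normalize_conditions(va)

  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(config$seed)

  d_in <- 4L + if (config$conditional_discriminator) 2L else 0L
  gen <- mlp_init(c(2L + config$latent_dim, config$hidden, 4L))
  disc <- mlp_init(c(d_in, config$hidden, 1L))
  opt_g <- adam_init(gen); opt_d <- adam_init(disc)

  n <- nrow(tr)
  bs <- if (is.null(config$batch_size)) n else min(config$batch_size, n)
  lambda <- config$lambda
  trace <- NULL
  best <- list(val_mse = Inf, gen = gen)

  for (it in seq_len(config$max_iterations)) {
    for (s in seq_len(config$d_steps)) {
      idx <- if (bs < n) sample.int(n, bs) else seq_len(n)
      Xb <- Xc_tr[idx, , drop = FALSE]; Yb <- Ys_tr[idx, , drop = FALSE]
      fake <- mlp_forward(gen, gen_input(Xb, config$latent_dim))$out
      fr <- mlp_forward(disc, disc_input(Yb, Xb, config), "sigmoid")
      ff <- mlp_forward(disc, disc_input(fake, Xb, config), "sigmoid")
      m <- nrow(Xb)
      gr <- mlp_backward(disc, fr, (fr$out - 1) / m)
      gf <- mlp_backward(disc, ff, ff$out / m)
      grads <- list(dW = Map(`+`, gr$dW, gf$dW), db = Map(`+`, gr$db, gf$db))
      up <- adam_step(disc, grads, opt_d, config$lr_d)
      disc <- up$net; opt_d <- up$state
    }

    idx <- if (bs < n) sample.int(n, bs) else seq_len(n)
    Xb <- Xc_tr[idx, , drop = FALSE]; Yb <- Ys_tr[idx, , drop = FALSE]
    gcache <- mlp_forward(gen, gen_input(Xb, config$latent_dim))
    fake <- gcache$out
    dcache <- mlp_forward(disc, disc_input(fake, Xb, config), "sigmoid")
    m <- nrow(Xb)
    dback <- mlp_backward(disc, dcache, -(1 - dcache$out) / m)
    d_fake <- dback$dX
    if (config$conditional_discriminator)
      d_fake <- d_fake[, -(1:2), drop = FALSE]
    d_fake <- d_fake + lambda * 2 * (fake - Yb) / (m * 4)
    ggrads <- mlp_backward(gen, gcache, d_fake)
    up <- adam_step(gen, ggrads, opt_g, config$lr_g)
    gen <- up$net; opt_g <- up$state

    if (it %% config$eval_every == 0L || it == config$max_iterations) {
      fake_tr <- mlp_forward(gen, gen_input(Xc_tr, config$latent_dim))$out
      p_fake <- mlp_forward(disc, disc_input(fake_tr, Xc_tr, config),
                            "sigmoid")$out
      p_real <- mlp_forward(disc, disc_input(Ys_tr, Xc_tr, config),
                            "sigmoid")$out
      g_loss <- generator_loss(p_fake, fake_tr, Ys_tr, lambda)
      d_loss <- discriminator_loss(p_real, p_fake)
      train_mse <- mean((fake_tr - Ys_tr)^2)
      fake_va <- mlp_forward(gen, gen_input(Xc_va, config$latent_dim))$out
      val_mse <- mean((fake_va - Ys_va)^2)
      if (!all(is.finite(c(g_loss, d_loss, train_mse, val_mse))))
        stop("non-finite loss at iteration ", it)
      trace <- rbind(trace, data.frame(iteration = it, g_loss = g_loss,
                                       d_loss = d_loss, train_mse = train_mse,
                                       val_mse = val_mse))
      if (val_mse < best$val_mse) best <- list(val_mse = val_mse, gen = gen)
    }
  }

  structure(list(gen = best$gen, final_gen = gen, disc = disc, norm = norm,
                 config = config, best_val_mse = best$val_mse, trace = trace),
            class = "fry_gan")
}

#' Generator forward pass (predictions in original units)
#'
#' Runs the conditions through the generator and denormalizes the output.
#' The output layer is linear, so predictions can be negative; they are not
#' clipped.
#'
#' @param model a \code{fry_gan}.
#' @param conditions data frame with \code{time_h}, \code{temp_C}.
#' @param use_best use the best-validation snapshot (default) rather than the
#'   final iterate.
#' @return Data frame of the conditions plus predicted \code{av}, \code{tpc},
#'   \code{tgp}, \code{tfa}.
#' @export
generator_forward <- function(model, conditions, use_best = TRUE) {
  stopifnot(inherits(model, "fry_gan"))
  Xc <- normalize_conditions(conditions)
  net <- if (use_best) model$gen else model$final_gen
  if (model$config$latent_dim > 0)
    Xc <- cbind(Xc, matrix(0, nrow(Xc), model$config$latent_dim))
  Ys <- mlp_forward(net, Xc)$out
  Y <- destandardize(Ys, model$norm)
  colnames(Y) <- INDICATORS
  cbind(as.data.frame(conditions)[c("time_h", "temp_C")], as.data.frame(Y))
}

#' Discriminator forward pass
#'
#' Scores indicator vectors (given in original units; standardized internally
#' with the model's training statistics) as probabilities of being real.
#'
#' @param model a \code{fry_gan}.
#' @param indicators matrix or data frame with columns av, tpc, tgp, tfa.
#' @param conditions required only for a conditional discriminator.
#' @return Numeric vector of probabilities strictly inside (0, 1).
#' @export
discriminator_forward <- function(model, indicators, conditions = NULL) {
  stopifnot(inherits(model, "fry_gan"))
  Y <- as.matrix(as.data.frame(indicators)[INDICATORS])
  if (any(!is.finite(Y))) stop("non-finite indicator values")
  Ys <- standardize(Y, model$norm)
  Xc <- if (model$config$conditional_discriminator) {
    if (is.null(conditions)) stop("conditional discriminator needs conditions")
    normalize_conditions(conditions)
  }
  as.numeric(mlp_forward(model$disc, disc_input(Ys, Xc, model$config),
                         "sigmoid")$out)
}

#' @rdname generator_forward
#' @param object a \code{fry_gan} model.
#' @param newdata conditions to predict at.
#' @param ... unused.
#' @export
predict.fry_gan <- function(object, newdata, ...) {
  generator_forward(object, newdata)
}
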