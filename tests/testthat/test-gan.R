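test_that("loss functions match their closed forms", {
  expect_equal(discriminator_loss(0.5, 0.5), 2 * log(2), tolerance = 1e-9)
  expect_equal(discriminator_loss(c(0.8), c(0.3)),
               -log(0.8) - log(0.7), tolerance = 1e-9)
  # perfect discriminator limit
  expect_lt(discriminator_loss(1 - 1e-9, 1e-9), 1e-6)
  expect_equal(generator_loss(0.5, matrix(1, 1, 4), matrix(1, 1, 4),
                              lambda = 0), log(2), tolerance = 1e-9)
  expect_equal(generator_loss(0.5, matrix(2, 1, 4), matrix(2, 1, 4),
                              lambda = 5), log(2), tolerance = 1e-9)
  expect_equal(generator_loss(0.5, matrix(c(2, 0, 0, 0), 1, 4),
                              matrix(c(1, 0, 0, 0), 1, 4), lambda = 1),
               log(2) + 0.25, tolerance = 1e-9)
})

test_that("loss functions reject invalid input", {
  expect_error(discriminator_loss(1, 0.5), "strictly in")
  expect_error(discriminator_loss(0.5, 0), "strictly in")
  expect_error(generator_loss(1.2, matrix(1), matrix(1)), "strictly in")
  expect_error(generator_loss(0.5, matrix(1, 1, 4), matrix(1, 2, 4)),
               "shape mismatch")
  expect_error(generator_loss(0.5, matrix(1), matrix(1), lambda = -1),
               ">= 0")
})

test_that("zero-weight networks give the analytic forward passes", {
  m <- quick_model()
  mz <- m
  mz$gen <- zero_net(mz$gen)
  mz$disc <- zero_net(mz$disc)
  pred <- generator_forward(mz, data.frame(time_h = c(4, 28),
                                           temp_C = c(150, 170)))
  tr_means <- mz$norm$mean
  for (k in IND) expect_equal(pred[[k]], rep(tr_means[[k]], 2))
  probs <- discriminator_forward(mz, pred)
  expect_equal(probs, c(0.5, 0.5))
})

test_that("discriminator outputs stay strictly inside (0, 1)", {
  m <- quick_model()
  set.seed(3)
  batch <- data.frame(av = runif(1000, -50, 50), tpc = runif(1000, -50, 50),
                      tgp = runif(1000, -50, 50), tfa = runif(1000, -50, 50))
  p <- discriminator_forward(m, batch)
  expect_true(all(p > 0 & p < 1))
})

test_that("forward passes are deterministic", {
  m <- quick_model()
  cond <- data.frame(time_h = c(8, 16, 32), temp_C = c(140, 160, 180))
  expect_identical(generator_forward(m, cond), generator_forward(m, cond))
  expect_identical(predict(m, cond), generator_forward(m, cond))
  ind <- table1_fixture()$real
  expect_identical(discriminator_forward(m, ind),
                   discriminator_forward(m, ind))
  expect_error(generator_forward(m, data.frame(time_h = NA, temp_C = 150)),
               "non-finite")
})

test_that("indicator normalization round-trips", {
  m <- quick_model()
  Y <- as.matrix(simulate_dataset(default_grid(), default_sim_params(),
                                  seed = 2)[, IND])
  back <- frygan:::destandardize(frygan:::standardize(Y, m$norm), m$norm)
  expect_equal(back, Y, tolerance = 1e-12)
})

test_that("training is seed-reproducible and validates its inputs", {
  ds <- noiseless_split_ds()
  m1 <- train_gan(ds, quick_config(seed = 4, iters = 200))
  m2 <- train_gan(ds, quick_config(seed = 4, iters = 200))
  expect_identical(m1$trace, m2$trace)
  expect_identical(m1$best_val_mse, m2$best_val_mse)
  expect_identical(generator_forward(m1, ds), generator_forward(m2, ds))
  m3 <- train_gan(ds, quick_config(seed = 5, iters = 200))
  expect_false(identical(m1$best_val_mse, m3$best_val_mse))
  expect_true(all(is.finite(as.matrix(m1$trace))))

  no_train <- ds; no_train$split[no_train$split == "train"] <- "test"
  expect_error(train_gan(no_train), "no training records")
  no_val <- ds; no_val$split[no_val$split == "val"] <- "train"
  expect_error(train_gan(no_val), "no validation records")
})

test_that("short training already reduces the regression error", {
  m <- quick_model()
  expect_lt(m$best_val_mse, m$trace$val_mse[1])
})
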