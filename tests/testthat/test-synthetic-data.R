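test_that("default grid covers the experimental design", {
  g <- default_grid()
  expect_equal(nrow(g), 50)
  expect_setequal(unique(g$temp_C), seq(140, 180, by = 10))
  expect_equal(range(g$time_h), c(0, 36))
  expect_true(nrow(merge(g, data.frame(time_h = c(4, 28), temp_C = 150))) == 2)
  expect_false(anyDuplicated(g) > 0)
})

test_that("simulation is reproducible, nonnegative, and zero at t = 0", {
  g <- default_grid()
  ds1 <- simulate_dataset(g, default_sim_params(), seed = 7)
  ds2 <- simulate_dataset(g, default_sim_params(), seed = 7)
  expect_identical(ds1, ds2)
  expect_false(identical(ds1, simulate_dataset(g, default_sim_params(),
                                               seed = 8)))
  for (k in IND) expect_true(all(ds1[[k]] >= 0))
  # At t = 0 the trend is zero: noiseless values vanish exactly.
  ds0 <- simulate_dataset(g, default_sim_params(0), seed = 1)
  at0 <- ds0[ds0$time_h == 0, IND]
  expect_true(all(unlist(at0) == 0))
})

test_that("noiseless indicators are nondecreasing in time and temperature", {
  ds <- simulate_dataset(default_grid(), default_sim_params(0), seed = 1)
  for (k in IND) {
    for (temp in unique(ds$temp_C)) {
      s <- ds[ds$temp_C == temp, ]
      expect_true(all(diff(s[[k]][order(s$time_h)]) >= 0))
    }
    for (t in unique(ds$time_h)) {
      s <- ds[ds$time_h == t, ]
      expect_true(all(diff(s[[k]][order(s$temp_C)]) >= 0))
    }
  }
})

test_that("noiseless simulation matches the published measurements", {
  fx <- table1_fixture()$real
  sim <- simulate_dataset(fx[c("time_h", "temp_C")], default_sim_params(0),
                          seed = 1)
  for (i in seq_len(nrow(fx))) {
    for (k in IND) {
      real <- fx[[k]][i]; pred <- sim[[k]][i]
      if (real > 0.5) {
        expect_lt(abs(pred - real) / real, 0.30)
      } else {
        expect_lt(abs(pred - real), 0.3)
      }
    }
  }
})

test_that("fixture carries the seven published test conditions", {
  fx <- table1_fixture()
  expect_equal(nrow(fx$real), 7)
  expect_equal(nrow(fx$predicted), 7)
  r1 <- fx$real[fx$real$time_h == 4 & fx$real$temp_C == 150, ]
  expect_equal(unlist(r1[IND], use.names = FALSE),
               c(0.4653, 6.50, 1.71, 0.0796))
  r2 <- fx$real[fx$real$time_h == 20 & fx$real$temp_C == 170, ]
  expect_equal(unlist(r2[IND], use.names = FALSE),
               c(2.3514, 23.60, 7.19, 0.2210))
  # predictions may be negative (linear output layer, not clipped)
  expect_lt(min(fx$predicted$av), 0)
})

test_that("split_dataset implements both protocols", {
  ds <- simulate_dataset(default_grid(), default_sim_params(), seed = 1)
  th <- split_dataset(ds, "time_holdout", seed = 1)
  expect_equal(sum(th$split == "test"), 10)  # 2 times x 5 temperatures
  expect_setequal(unique(th$time_h[th$split == "test"]), c(32, 36))
  expect_true(all(th$split[th$time_h %in% c(32, 36)] == "test"))
  expect_gt(sum(th$split == "val"), 0)

  r1 <- split_dataset(ds, "random", seed = 3)
  r2 <- split_dataset(ds, "random", seed = 3)
  expect_identical(r1$split, r2$split)
  expect_equal(sum(table(r1$split)), 50)
  expect_setequal(unique(r1$split), c("train", "val", "test"))
})

test_that("invalid inputs are rejected", {
  expect_error(simulate_dataset(default_grid()[0, ], default_sim_params()),
               "empty condition grid")
  bad <- default_sim_params(); bad$av$sigma <- -1
  expect_error(simulate_dataset(default_grid(), bad), "negative sigma")
  ds <- simulate_dataset(default_grid(), default_sim_params(), seed = 1)
  expect_error(split_dataset(ds, "time_holdout", holdout_times = c(13, 36)),
               "holdout times absent")
  expect_error(split_dataset(ds, "random",
                             fractions = c(0.5, 0.3, 0.3)), "sum to 1")
})
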