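# Closed-form normal-equations OLS, independent of the qr-based fit path.
ols_oracle <- function(x, order) {
  n <- nrow(x); k <- ncol(x)
  Y <- x[(order + 1):n, , drop = FALSE]
  X <- cbind(1, do.call(cbind, lapply(seq_len(order), function(l)
    x[(order + 1 - l):(n - l), , drop = FALSE])))
  solve(t(X) %*% X, t(X) %*% Y)
}

test_that("moving average: fixed point, hand means, roll-forward", {
  expect_true(all(ma_forecast(rep(3.5, 8), window = 3, horizon = 5) == 3.5))
  expect_equal(as.numeric(ma_forecast(c(1, 3, 5), 2, 1)), 4)
  expect_equal(as.numeric(ma_forecast(c(1, 3, 5), 2, 2)), c(4, 4.5))
  m <- ma_forecast(cbind(a = rep(2, 5), b = rep(-1, 5)), 3, 4)
  expect_true(all(m[, "a"] == 2) && all(m[, "b"] == -1))
  expect_error(ma_forecast(1:2, window = 5, horizon = 1), "window")
})

test_that("VAR OLS recovers a noiseless AR(0.5) process", {
  y <- 0.5^(0:11)                       # y_t = 0.5 y_{t-1}, y_0 = 1
  m <- var_fit(matrix(y, ncol = 1), order = 1)
  expect_equal(m$coef[[1]][1, 1], 0.5, tolerance = 1e-8)
  expect_equal(m$intercept, 0, tolerance = 1e-8)
  # forecast continues the geometric decay
  f <- var_forecast(m, matrix(y, ncol = 1), horizon = 1)
  expect_equal(as.numeric(f), 0.5^12, tolerance = 1e-8)
})

test_that("VAR OLS recovers known stable coefficient matrices exactly", {
  simulate_var1 <- function(A, c0, y0, n) {
    k <- length(y0)
    out <- matrix(NA_real_, n, k)
    out[1, ] <- y0
    for (t in 2:n) out[t, ] <- c0 + as.numeric(A %*% out[t - 1, ])
    out
  }
  A2 <- matrix(c(0.5, 0.2, -0.3, 0.4), 2, 2)
  x2 <- simulate_var1(A2, c(0.1, -0.2), c(1, -1), 15)
  m2 <- var_fit(x2, 1)
  expect_lt(max(abs(m2$coef[[1]] - A2)), 1e-6)
  expect_lt(max(abs(m2$intercept - c(0.1, -0.2))), 1e-6)

  # 4-dim: damped rotation mixes all coordinates, keeping the design regular
  set.seed(5)
  Q <- qr.Q(qr(matrix(rnorm(16), 4)))
  A4 <- 0.9 * Q
  x4 <- simulate_var1(A4, rep(0, 4), rnorm(4), 20)
  m4 <- var_fit(x4, 1)
  expect_lt(max(abs(m4$coef[[1]] - A4)), 1e-6)
  expect_lt(max(abs(m4$intercept)), 1e-6)
})

test_that("VAR forecasts match a step-by-step recursion oracle", {
  set.seed(9)
  for (rep in 1:20) {
    k <- sample(2:4, 1)
    A <- matrix(rnorm(k * k, sd = 0.3), k)
    c0 <- rnorm(k)
    model <- structure(list(order = 1L, intercept = c0, coef = list(A), k = k),
                       class = "fry_var")
    hist <- matrix(rnorm(5 * k), 5, k)
    f <- var_forecast(model, hist, horizon = 3)
    h <- hist
    for (s in 1:3) {
      nxt <- c0 + as.numeric(A %*% h[nrow(h), ])
      expect_equal(as.numeric(f[s, ]), nxt, tolerance = 1e-12)
      h <- rbind(h, nxt)
    }
  }
  # zero coefficients: every forecast equals the intercept
  m0 <- structure(list(order = 1L, intercept = c(2, -3),
                       coef = list(matrix(0, 2, 2)), k = 2L),
                  class = "fry_var")
  f0 <- var_forecast(m0, matrix(rnorm(6), 3, 2), horizon = 4)
  expect_true(all(f0[, 1] == 2) && all(f0[, 2] == -3))
})

test_that("fit matches the normal-equations oracle and rejects degeneracy", {
  set.seed(21)
  x <- matrix(rnorm(48), 12, 4)
  m <- var_fit(x, 1)
  B <- ols_oracle(x, 1)
  expect_equal(m$intercept, as.numeric(B[1, ]), tolerance = 1e-9)
  expect_equal(m$coef[[1]], t(B[-1, , drop = FALSE]), tolerance = 1e-9,
               ignore_attr = TRUE)
  # exact linear dependence between columns
  dep <- cbind(x[, 1], 2 * x[, 1], x[, 3], x[, 4])
  expect_error(var_fit(dep, 1), "singular design")
  expect_error(var_fit(matrix(rnorm(8), 4, 2), order = 1), "too short")
  expect_error(var_forecast(m, x[0, , drop = FALSE], 1), "history")
})
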