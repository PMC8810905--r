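test_that("predict_consumed takes analytic limits for degenerate parameters", {
  expect_identical(predict_consumed(a = 0, h = 0.1, N0 = 32), 0)
  expect_identical(predict_consumed(a = 2, h = 0.1, N0 = 0), 0)
  # no handling: pure exponential depletion
  expect_equal(predict_consumed(a = 2, h = 0, N0 = 10), 10 * (1 - exp(-2)),
               tolerance = 1e-12)
})

test_that("closed form matches the fixed-point oracle value", {
  # frozen from the bracketing oracle solved before the Lambert-W path
  expect_equal(predict_consumed(a = 0.5, h = 0.1, N0 = 32, T = 1),
               5.913579655955, tolerance = 1e-8)
})

test_that("closed form agrees with the fixed-point oracle on a grid", {
  grid <- expand.grid(
    a = c(0.05, 0.2, 0.5, 1, 2, 4.72, 8, 14, 34, 41),
    h = c(0.01, 0.03, 0.045, 0.063, 0.085, 0.1, 0.2, 0.5, 1, 2),
    N0 = c(1, 2, 4, 8, 16, 32)
  )
  ours <- predict_consumed(grid$a, grid$h, grid$N0)
  oracle <- mapply(rogers_oracle, grid$a, grid$h, grid$N0)
  expect_equal(ours, oracle, tolerance = 1e-8)
})

test_that("solutions satisfy the implicit equation and its bounds", {
  set.seed(21)
  n <- 400
  a <- 10^runif(n, -2, 2)
  h <- 10^runif(n, -3, 1)
  N0 <- sample(1:64, n, replace = TRUE)
  T <- runif(n, 0.25, 4)
  ne <- predict_consumed(a, h, N0, T)
  resid <- abs(N0 * (1 - exp(a * (ne * h - T))) - ne)
  expect_lt(max(resid / (1e-9 * N0)), 1)
  expect_true(all(ne >= 0))
  expect_true(all(ne <= pmin(N0, T / h) + 1e-9))
})

test_that("expected consumption is monotone in each argument", {
  set.seed(22)
  for (i in 1:25) {
    a <- 10^runif(1, -1.5, 1.5)
    h <- 10^runif(1, -2, 0)
    N0 <- sample(2:40, 1)
    T <- runif(1, 0.5, 2)
    a_grid <- sort(10^runif(8, -2, 2))
    expect_true(all(diff(predict_consumed(a_grid, h, N0, T)) >= -1e-10))
    h_grid <- sort(10^runif(8, -3, 1))
    expect_true(all(diff(predict_consumed(a, h_grid, N0, T)) <= 1e-10))
    n_grid <- 1:40
    expect_true(all(diff(predict_consumed(a, h, n_grid, T)) >= -1e-10))
    t_grid <- sort(runif(8, 0.1, 4))
    expect_true(all(diff(predict_consumed(a, h, N0, t_grid)) >= -1e-10))
  }
})

test_that("extreme saturation is handled without overflow", {
  # a*h*N0 large enough that the Lambert argument overflows exp()
  ne <- predict_consumed(a = 500, h = 0.1, N0 = 32, T = 1)
  expect_true(is.finite(ne))
  # saturated trials approach the handling-limited ceiling T/h
  expect_equal(ne, 10, tolerance = 1e-3)
})

test_that("fr_params validates and derives the maximum feeding rate", {
  p <- fr_params(attack_rate = 4.72, handling_time = 0.063)
  expect_s3_class(p, "fr_params")
  expect_equal(p$max_feeding_rate * p$handling_time, 1, tolerance = 1e-15)
  expect_identical(fr_params(1, 0)$max_feeding_rate, Inf)
  expect_error(fr_params(0, 0.1), "attack_rate")
  expect_error(fr_params(1, -0.1), "handling_time")
})

test_that("max_feeding_rate is the reciprocal handling time", {
  expect_identical(max_feeding_rate(1), 1)
  expect_equal(max_feeding_rate(0.063), 15.873, tolerance = 5e-4)
  expect_equal(max_feeding_rate(0.045), 22.222, tolerance = 5e-4)
  expect_error(max_feeding_rate(0), "> 0")
  expect_error(max_feeding_rate(-1), "> 0")
})
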