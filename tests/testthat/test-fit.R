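# Coarse grid-search oracle for the maximum-likelihood surface: the best
# (a, h) on a wide log grid, independent of the optimiser under test.
grid_search_oracle <- function(trials, n = 61) {
  a_grid <- 10^seq(-2, 3, length.out = n)
  h_grid <- 10^seq(-4, 1, length.out = n)
  best <- c(NA, NA, Inf)
  for (a in a_grid) {
    ne <- predict_consumed(a, rep(h_grid, each = nrow(trials)),
                           rep(trials$initial_density, times = length(h_grid)),
                           1)
    p <- pmin(pmax(ne / rep(trials$initial_density, times = length(h_grid)),
                   1e-12), 1 - 1e-12)
    ll <- colSums(matrix(dbinom(trials$eaten, trials$initial_density, p,
                                log = TRUE),
                         nrow = nrow(trials)))
    j <- which.max(ll)
    if (-ll[j] < best[3]) best <- c(a, h_grid[j], -ll[j])
  }
  best
}

test_that("fitted parameters agree with a coarse grid-search oracle", {
  densities <- c(1, 2, 4, 8, 16, 32)
  n0 <- rep(densities, each = 3)
  # eaten counts are the rounded Rogers expectations for a = 2, h = 0.08
  tr <- data.frame(initial_density = n0,
                   eaten = round(predict_consumed(2, 0.08, n0, 1)),
                   duration = 1)
  fit <- fit_rogers(tr)
  oracle <- grid_search_oracle(tr)
  # within one log-grid cell of the oracle optimum
  grid_step <- 10^(5 / 60)
  expect_lt(abs(log(fit$params$attack_rate) - log(oracle[1])),
            log(grid_step) * 1.01)
  expect_lt(abs(log(fit$params$handling_time) - log(oracle[2])),
            log(grid_step) * 1.01)
  expect_lte(-fit$loglik, oracle[3] + 1e-9)
  expect_true(fit$converged)
  expect_true(is.finite(fit$loglik))
})

test_that("the optimum dominates a surrounding 21x21 log-scale grid", {
  tr <- make_group_trials(a = 4.72, h = 0.063, seed = 201)
  fit <- fit_rogers(tr)
  lik <- rogersfr:::prep_lik_data(tr$initial_density, tr$eaten, tr$duration)
  la <- log(fit$params$attack_rate) + seq(-1, 1, length.out = 21)
  lh <- log(fit$params$handling_time) + seq(-1, 1, length.out = 21)
  grid_nll <- outer(la, lh, Vectorize(function(x, y)
    rogersfr:::rogers_nll(c(x, y), lik)))
  expect_lte(-fit$loglik, min(grid_nll) + 1e-6)
})

test_that("fitting is deterministic and invariant to row order", {
  tr <- make_group_trials(a = 5.87, h = 0.045, seed = 202)
  f1 <- fit_rogers(tr)
  f2 <- fit_rogers(tr)
  expect_identical(f1, f2)
  set.seed(3)
  f3 <- fit_rogers(tr[sample(nrow(tr)), ])
  expect_equal(coef(f1), coef(f3), tolerance = 1e-12)
  expect_equal(f1$loglik, f3$loglik, tolerance = 1e-12)
})

test_that("unidentifiable and malformed inputs raise errors", {
  zero <- data.frame(initial_density = rep(c(2, 8, 32), each = 3), eaten = 0)
  expect_error(fit_rogers(zero), "unidentifiable")
  one_density <- data.frame(initial_density = rep(8, 9), eaten = 2)
  expect_error(fit_rogers(one_density), "distinct prey densities")
  expect_error(fit_rogers(data.frame(x = 1)), "missing required columns")
})

test_that("well-identified parameters are recovered from simulated trials", {
  rel_h <- rel_a <- numeric(30)
  for (s in 1:30) {
    tr <- make_group_trials(a = 4.72, h = 0.063, seed = 300 + s)
    f <- fit_rogers(tr)
    rel_a[s] <- abs(f$params$attack_rate - 4.72) / 4.72
    rel_h[s] <- abs(f$params$handling_time - 0.063) / 0.063
  }
  expect_lt(median(rel_h), 0.25)
  expect_lt(median(rel_a), 0.5)
})

test_that("standard errors and p-values are produced for stable fits", {
  tr <- make_group_trials(a = 4.72, h = 0.063, reps = 10, seed = 204)
  f <- fit_rogers(tr)
  expect_true(is.finite(f$se_a) && f$se_a > 0)
  expect_true(is.finite(f$se_h) && f$se_h > 0)
  expect_true(f$p_a >= 0 && f$p_a <= 1)
  expect_true(f$p_h < 0.05)  # handling time is strongly identified here
  expect_equal(f$params$max_feeding_rate * f$params$handling_time, 1,
               tolerance = 1e-12)
})
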