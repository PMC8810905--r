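test_that("the trout-fry preset matches the factorial design", {
  d <- trout_fry_design(seed = 1)
  tr <- simulate_trials(d)
  expect_identical(sum(!tr$is_control), 108L)  # 3 types x 2 novelty x 6 x 3
  expect_identical(sum(tr$is_control), 18L)    # 6 densities x 3 controls
  expect_identical(d$duration, 1)
  cell <- d$groups[d$groups$fish_type == "brown_diploid" &
                     d$groups$novelty == "not_novel", ]
  expect_identical(cell$handling_time, 0.045)
  expect_identical(cell$attack_rate, 5.873)
  expect_true(all(tr$eaten >= 0 & tr$eaten <= tr$initial_density))
})

test_that("simulated datasets are reproducible from the design seed", {
  t1 <- simulate_trials(trout_fry_design(seed = 42))
  t2 <- simulate_trials(trout_fry_design(seed = 42))
  expect_identical(t1, t2)
  t3 <- simulate_trials(trout_fry_design(seed = 43))
  expect_false(identical(t1, t3))
  # the global RNG stream is left untouched
  set.seed(5); before <- runif(1)
  set.seed(5); invisible(simulate_trials(trout_fry_design(seed = 1)))
  expect_identical(runif(1), before)
})

test_that("predator-free controls have full prey survival by default", {
  tr <- simulate_trials(trout_fry_design(seed = 9))
  ctrl <- tr[tr$is_control, ]
  expect_identical(sum(ctrl$eaten), 0L)
  expect_true(all(is.na(ctrl$fish_type)))
})

test_that("a zero attack rate eats nothing under either mechanism", {
  for (mech in c("binomial", "event_driven")) {
    d <- sim_design(groups = data.frame(fish_type = "x", novelty = "y",
                                        attack_rate = 0, handling_time = 0.1),
                    mechanism = mech, control_reps = 0, seed = 2)
    expect_identical(sum(simulate_trials(d)$eaten), 0L)
  }
})

test_that("binomial mechanism means match the Rogers expectation", {
  d <- sim_design(densities = 16, reps_per_density = 10000,
                  groups = data.frame(fish_type = "x", novelty = "y",
                                      attack_rate = 4.72,
                                      handling_time = 0.063),
                  control_reps = 0, seed = 31)
  tr <- simulate_trials(d)
  ne <- predict_consumed(4.72, 0.063, 16, 1)
  p <- ne / 16
  se <- sqrt(16 * p * (1 - p) / nrow(tr))
  expect_lt(abs(mean(tr$eaten) - ne), 3 * se)
})

test_that("event-driven and binomial mechanisms agree when handling is negligible", {
  gr <- data.frame(fish_type = "x", novelty = "y",
                   attack_rate = 1.5, handling_time = 0)
  means <- ses <- numeric(2)
  for (i in 1:2) {
    d <- sim_design(densities = 16, reps_per_density = 4000, groups = gr,
                    mechanism = c("binomial", "event_driven")[i],
                    control_reps = 0, seed = 60 + i)
    e <- simulate_trials(d)$eaten
    means[i] <- mean(e)
    ses[i] <- sd(e) / sqrt(length(e))
  }
  expect_lt(abs(means[1] - means[2]), 3 * sqrt(sum(ses^2)))
})

test_that("event-driven trials respect the handling-time ceiling", {
  d <- sim_design(densities = c(16, 32), reps_per_density = 400,
                  groups = data.frame(fish_type = "x", novelty = "y",
                                      attack_rate = 50, handling_time = 0.11),
                  mechanism = "event_driven", control_reps = 0, seed = 71)
  tr <- simulate_trials(d)
  expect_lte(max(tr$eaten), ceiling(1 / 0.11))  # at most ceil(T/h)
  expect_true(all(tr$eaten <= tr$initial_density))
})

test_that("background mortality reaches the control arm when enabled", {
  d <- sim_design(densities = c(16, 32), reps_per_density = 1,
                  control_reps = 50, background_mortality = 0.2, seed = 81)
  ctrl <- simulate_trials(d)
  ctrl <- ctrl[ctrl$is_control, ]
  expect_gt(sum(ctrl$eaten), 0)
})

test_that("invalid designs are rejected", {
  expect_error(sim_design(seed = 1, densities = c(0, 2)), "positive integers")
  expect_error(sim_design(seed = 1, reps_per_density = 0), "reps_per_density")
  expect_error(sim_design(seed = 1,
                          groups = data.frame(fish_type = "x", novelty = "y",
                                              attack_rate = -1,
                                              handling_time = 0.1)),
               ">= 0")
  expect_error(sim_design(densities = c(1, 2)), "seed")
  expect_error(simulate_trials(list()), "sim_design")
})
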