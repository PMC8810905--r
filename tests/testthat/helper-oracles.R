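# Independent numerical oracles used to check the closed-form / ML paths.

# Fixed-point / bracketing oracle for Rogers' equation: solves
# Ne = N0 (1 - exp(a (Ne h - T))) on [0, N0] without Lambert W.
rogers_oracle <- function(a, h, N0, T = 1) {
  if (a == 0 || N0 == 0) return(0)
  # the root lies below the handling ceiling T/h; bracketing there keeps
  # the exponential finite
  upper <- if (h > 0) min(N0, T / h) else N0
  f <- function(ne) N0 * (1 - exp(a * (ne * h - T))) - ne
  stats::uniroot(f, c(0, upper), tol = 1e-13)$root
}

# Independently coded IRLS for a grouped-binomial logistic regression of
# (eaten, surviving) on a design matrix X; returns coefficients.
irls_logistic <- function(X, eaten, n) {
  beta <- rep(0, ncol(X))
  for (i in 1:100) {
    eta <- as.numeric(X %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- n * mu * (1 - mu)
    z <- eta + (eaten - n * mu) / pmax(w, 1e-10)
    beta_new <- solve(crossprod(X, w * X), crossprod(X, w * z))
    if (max(abs(beta_new - beta)) < 1e-12) {
      beta <- beta_new
      break
    }
    beta <- beta_new
  }
  as.numeric(beta)
}

# Simulate one group's trials directly (independent of simulate_trials):
# binomial draws around the Rogers expectation.
make_group_trials <- function(a, h, densities = c(1, 2, 4, 8, 16, 32),
                              reps = 3, T = 1, seed = 1) {
  set.seed(seed)
  n0 <- rep(densities, each = reps)
  p <- predict_consumed(a, h, n0, T) / n0
  data.frame(
    fish_type = "x", novelty = "y",
    initial_density = n0,
    eaten = rbinom(length(n0), n0, p),
    duration = T,
    is_control = FALSE,
    replicate_id = rep(seq_len(reps), times = length(densities))
  )
}
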