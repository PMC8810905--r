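# Precompute the parts of the likelihood that do not change between
# optimizer iterations: the success probability depends only on the
# unique (N0, T) pairs, not on every trial row. Internal.
prep_lik_data <- function(N0, eaten, T) {
  key <- paste(N0, T)
  u <- which(!duplicated(key))
  list(N0 = N0, eaten = eaten,
       N0u = N0[u], Tu = T[u],
       map = match(key, key[u]))
}

# Negative binomial log-likelihood of (log a, log h). Each trial's eaten
# count is Binomial(N0, p) with p the depletion-corrected expected
# proportion consumed from Rogers' equation. Internal.
rogers_nll <- function(theta, lik) {
  a <- exp(theta[1L])
  h <- exp(theta[2L])
  if (!is.finite(a) || !is.finite(h)) return(1e10)
  ne <- rogers_ne_core(a, h, lik$N0u, lik$Tu)
  p <- pmin(pmax(ne / lik$N0u, 1e-12), 1 - 1e-12)[lik$map]
  ll <- sum(stats::dbinom(lik$eaten, size = lik$N0, prob = p, log = TRUE))
  if (!is.finite(ll)) return(1e10)
  -ll
}

# Heuristic starting values: h0 from the high-density consumption plateau
# (max mean eaten approximates T/h), a0 from the proportion consumed at the
# lowest density (Ne/N0 ~ 1 - exp(-aT) when depletion is mild). Internal.
rogers_starts <- function(N0, eaten, T) {
  mean_T <- mean(T)
  by_dens <- tapply(eaten, N0, mean)
  plateau <- max(by_dens, 0.5)
  h0 <- mean_T / plateau
  low <- N0 == min(N0)
  p_low <- sum(eaten[low]) / sum(N0[low])
  p_low <- min(max(p_low, 0.05), 0.95)
  a0 <- -log(1 - p_low) / mean_T
  mults <- c(0.3, 1, 3)
  expand.grid(log_a = log(a0 * mults), log_h = log(h0 * mults))
}

#' Fit Rogers' random predator equation by maximum likelihood
#'
#' Estimates the attack rate `a` and handling time `h` of a Type II
#' functional response from prey-depletion feeding trials for one
#' predator group. Each trial's eaten count is modelled as
#' `Binomial(N0, p)` with success probability
#' `p = predict_consumed(a, h, N0, T) / N0`, the depletion-corrected
#' expected proportion consumed. The likelihood is maximised over
#' `(log a, log h)` (enforcing positivity) by Nelder-Mead from a fixed
#' 3 x 3 grid of data-driven starts; the best optimum is polished and its
#' observed information inverted for asymptotic standard errors.
#' Wald p-values (`z = estimate / SE` with delta-method SEs on the natural
#' scale) are approximate.
#'
#' @param trials Data frame with columns `initial_density`, `eaten` and
#'   optionally `duration` (default 1 trial period) for a single predator
#'   group; control rows are dropped.
#' @return An object of class `fr_fit`: list with `params` (an
#'   [fr_params] object), `se_a`, `se_h`, `p_a`, `p_h`, `loglik`,
#'   `converged`, `n_trials`, `group` (attribute columns `fish_type` /
#'   `novelty` if constant in the input) and the data used (`data`).
#' @examples
#' d <- trout_fry_design(seed = 42)
#' tr <- simulate_trials(d)
#' g <- tr[tr$fish_type == "brown_diploid" & tr$novelty == "novel" &
#'           !tr$is_control, ]
#' fit_rogers(g)
#' @export
fit_rogers <- function(trials) {
  trials <- drop_controls(trials)
  need <- c("initial_density", "eaten")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  N0 <- as.numeric(trials$initial_density)
  eaten <- as.numeric(trials$eaten)
  T <- if ("duration" %in% names(trials)) as.numeric(trials$duration) else rep(1, length(N0))
  if (length(unique(N0)) < 2L) {
    stop("insufficient data: need trials at >= 2 distinct prey densities",
         call. = FALSE)
  }
  if (sum(eaten) == 0) {
    stop("unidentifiable data: zero consumption in every trial ",
         "(likelihood is maximised on the a -> 0 boundary)", call. = FALSE)
  }

  lik <- prep_lik_data(N0, eaten, T)
  starts <- rogers_starts(N0, eaten, T)
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    op <- try(stats::optim(as.numeric(starts[i, ]), rogers_nll, lik = lik,
                           method = "Nelder-Mead",
                           control = list(maxit = 1000, reltol = 1e-12)),
              silent = TRUE)
    if (inherits(op, "try-error")) next
    if (is.null(best) || op$value < best$value) best <- op
  }
  if (is.null(best)) {
    stop("fit_rogers: optimisation failed from every start", call. = FALSE)
  }
  # polish from the best optimum
  op2 <- stats::optim(best$par, rogers_nll, lik = lik,
                      method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-12))
  if (op2$value <= best$value) best <- op2
  if (best$convergence != 0) {
    stop(sprintf(paste0("fit_rogers did not converge (code %d); best point ",
                        "found: a = %.6g, h = %.6g, nll = %.6g"),
                 best$convergence, exp(best$par[1]), exp(best$par[2]),
                 best$value), call. = FALSE)
  }

  a <- exp(best$par[1L])
  h <- exp(best$par[2L])
  H <- try(stats::optimHess(best$par, rogers_nll, lik = lik), silent = TRUE)
  se_log <- c(NA_real_, NA_real_)
  if (!inherits(H, "try-error")) {
    V <- try(solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(diag(V) > 0)) se_log <- sqrt(diag(V))
  }
  if (anyNA(se_log)) {
    warning("observed information not invertible; standard errors are NA",
            call. = FALSE)
  }
  # delta method: se(theta) = theta * se(log theta)
  se_a <- a * se_log[1L]
  se_h <- h * se_log[2L]
  p_a <- 2 * stats::pnorm(-abs(a / se_a))
  p_h <- 2 * stats::pnorm(-abs(h / se_h))

  group <- c(
    fish_type = single_value(trials, "fish_type"),
    novelty = single_value(trials, "novelty")
  )

  structure(
    list(
      params = fr_params(a, h),
      se_a = unname(se_a), se_h = unname(se_h),
      p_a = unname(p_a), p_h = unname(p_h),
      loglik = -best$value,
      converged = TRUE,
      n_trials = length(N0),
      group = group,
      data = data.frame(initial_density = N0, eaten = eaten, duration = T)
    ),
    class = "fr_fit"
  )
}

# The single value of a grouping column, or NA if absent / not constant.
# Internal.
single_value <- function(df, col) {
  if (!col %in% names(df)) return(NA_character_)
  u <- unique(as.character(df[[col]]))
  if (length(u) == 1L) u else NA_character_
}

#' @export
print.fr_fit <- function(x, ...) {
  cat("Rogers random predator equation fit (maximum likelihood)\n")
  if (!all(is.na(x$group))) {
    cat(sprintf("  group: %s / %s\n", x$group[["fish_type"]],
                x$group[["novelty"]]))
  }
  cat(sprintf("  attack rate (a)      : %.4g (SE %.3g, p = %.3g)%s\n",
              x$params$attack_rate, x$se_a, x$p_a, signif_stars(x$p_a)))
  cat(sprintf("  handling time (h)    : %.4g (SE %.3g, p = %.3g)%s\n",
              x$params$handling_time, x$se_h, x$p_h, signif_stars(x$p_h)))
  cat(sprintf("  max feeding rate 1/h : %.4g prey per trial period\n",
              x$params$max_feeding_rate))
  cat(sprintf("  log-likelihood: %.4f on %d trials\n", x$loglik, x$n_trials))
  invisible(x)
}

#' @export
coef.fr_fit <- function(object, ...) {
  c(attack_rate = object$params$attack_rate,
    handling_time = object$params$handling_time)
}

#' @export
logLik.fr_fit <- function(object, ...) {
  structure(object$loglik, df = 2L, class = "logLik")
}
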