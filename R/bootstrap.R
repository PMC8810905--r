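#' Non-parametric bootstrap for a Rogers functional-response fit
#'
#' Resamples feeding trials (rows) with replacement to the original sample
#' size, refits Rogers' random predator equation to each resample, and
#' summarises the replicate `(a, h)` draws as 95% percentile confidence
#' intervals plus per-density prediction quantiles (the confidence "cloud"
#' drawn around a functional-response curve).
#'
#' Resamples without at least two distinct densities, or with zero total
#' consumption, leave the model unidentifiable and are redrawn (counted in
#' `n_redrawn`). Replicates whose refit fails to converge are discarded
#' and counted; if more than 20% fail the data are considered too unstable
#' and an error is raised.
#'
#' @param fit An `fr_fit` object from [fit_rogers()].
#' @param n_boot Number of bootstrap replicates (default 2000).
#' @param seed Integer seed; required, so every summary is reproducible.
#' @param density_grid Densities at which the prediction band is
#'   evaluated; defaults to the sorted unique trial densities.
#' @param stratified Resample within density strata instead of across all
#'   rows (default FALSE, plain row resampling).
#' @param bca Use bias-corrected and accelerated (BCa) intervals instead
#'   of plain percentile intervals (default FALSE).
#' @param conf Confidence level (default 0.95).
#' @return An object of class `fr_boot`: list with `draws` (data frame of
#'   replicate `attack_rate`, `handling_time`), `ci_a`, `ci_h`, `band`
#'   (data frame `density`, `lower`, `point`, `upper`), `n_boot`, `seed`,
#'   `n_failed`, `n_redrawn`, `conf`, `method`.
#' @examples
#' d <- trout_fry_design(seed = 42)
#' tr <- simulate_trials(d)
#' g <- tr[tr$fish_type == "brown_diploid" & tr$novelty == "novel" &
#'           !tr$is_control, ]
#' bootstrap_fr(fit_rogers(g), n_boot = 50, seed = 1)
#' @export
bootstrap_fr <- function(fit, n_boot = 2000, seed, density_grid = NULL,
                         stratified = FALSE, bca = FALSE, conf = 0.95) {
  if (!inherits(fit, "fr_fit")) stop("`fit` must be an fr_fit", call. = FALSE)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is required (single integer) for reproducibility",
         call. = FALSE)
  }
  if (!is.numeric(n_boot) || n_boot < 1) stop("`n_boot` must be >= 1", call. = FALSE)
  n_boot <- as.integer(n_boot)
  dat <- fit$data
  # canonical row order: seed-fixed resampling is then invariant to the
  # order trials arrived in
  dat <- dat[order(dat$initial_density, dat$eaten, dat$duration), ,
             drop = FALSE]
  n <- nrow(dat)
  if (is.null(density_grid)) density_grid <- sort(unique(dat$initial_density))
  strata <- if (stratified) split(seq_len(n), dat$initial_density) else NULL

  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(as.integer(seed))

  start <- log(c(fit$params$attack_rate, fit$params$handling_time))
  draws <- matrix(NA_real_, n_boot, 2L)
  n_redrawn <- 0L
  n_failed <- 0L
  for (b in seq_len(n_boot)) {
    for (try_i in seq_len(1000L)) {
      idx <- if (stratified) {
        unlist(lapply(strata, function(s) s[sample.int(length(s),
                                                       replace = TRUE)]),
               use.names = FALSE)
      } else {
        sample.int(n, replace = TRUE)
      }
      ok <- length(unique(dat$initial_density[idx])) >= 2L &&
        sum(dat$eaten[idx]) > 0
      if (ok) break
      n_redrawn <- n_redrawn + 1L
    }
    if (!ok) stop("bootstrap_fr: could not draw an identifiable resample",
                  call. = FALSE)
    est <- refit_once(start, dat[idx, , drop = FALSE])
    if (anyNA(est)) n_failed <- n_failed + 1L else draws[b, ] <- est
  }
  if (n_failed > 0.2 * n_boot) {
    stop(sprintf(paste0("bootstrap_fr: %d of %d replicates failed to ",
                        "converge (> 20%%); data too unstable for a ",
                        "bootstrap summary"), n_failed, n_boot),
         call. = FALSE)
  }

  draws_df <- data.frame(attack_rate = draws[, 1L], handling_time = draws[, 2L])
  probs <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  if (bca) {
    ci_a <- bca_interval(draws_df$attack_rate, fit$params$attack_rate,
                         dat, conf, which = "a")
    ci_h <- bca_interval(draws_df$handling_time, fit$params$handling_time,
                         dat, conf, which = "h")
    method <- "bca"
  } else {
    ci_a <- stats::quantile(draws_df$attack_rate, probs, na.rm = TRUE,
                            names = FALSE)
    ci_h <- stats::quantile(draws_df$handling_time, probs, na.rm = TRUE,
                            names = FALSE)
    method <- "percentile"
  }

  keep <- !is.na(draws[, 1L])
  Tband <- stats::median(dat$duration)
  preds <- vapply(
    density_grid,
    function(d) {
      per_rep <- predict_consumed(draws[keep, 1L], draws[keep, 2L], d, Tband)
      stats::quantile(per_rep, probs, names = FALSE)
    },
    numeric(2L)
  )
  band <- data.frame(
    density = density_grid,
    lower = preds[1L, ],
    point = predict_consumed(fit$params$attack_rate,
                             fit$params$handling_time, density_grid, Tband),
    upper = preds[2L, ]
  )

  structure(
    list(
      draws = draws_df,
      ci_a = ci_a, ci_h = ci_h,
      band = band,
      n_boot = n_boot,
      seed = as.integer(seed),
      n_failed = n_failed,
      n_redrawn = n_redrawn,
      conf = conf,
      method = method,
      point = c(attack_rate = fit$params$attack_rate,
                handling_time = fit$params$handling_time)
    ),
    class = "fr_boot"
  )
}

# Single-start refit used for bootstrap replicates: Nelder-Mead from the
# original fit's optimum. Returns c(a, h) or NA on failure. Internal.
refit_once <- function(start, dat) {
  lik <- prep_lik_data(dat$initial_density, dat$eaten, dat$duration)
  op <- try(stats::optim(start, rogers_nll, lik = lik,
                         method = "Nelder-Mead",
                         control = list(maxit = 500, reltol = 1e-9)),
            silent = TRUE)
  if (inherits(op, "try-error") || op$convergence != 0) {
    return(c(NA_real_, NA_real_))
  }
  exp(op$par)
}

# BCa interval: bias correction z0 from the fraction of draws below the
# point estimate, acceleration from a leave-one-out jackknife. Internal.
bca_interval <- function(draws, point, dat, conf, which = c("a", "h")) {
  which <- match.arg(which)
  draws <- draws[!is.na(draws)]
  if (length(draws) < 2L) return(rep(draws[1L], 2L))
  z0 <- stats::qnorm(mean(draws < point))
  if (!is.finite(z0)) z0 <- 0
  n <- nrow(dat)
  jack <- vapply(seq_len(n), function(i) {
    d <- dat[-i, , drop = FALSE]
    if (length(unique(d$initial_density)) < 2L || sum(d$eaten) == 0) {
      return(NA_real_)
    }
    est <- refit_once(log(pmax(c(point, point), 1e-8)), d)
    if (which == "a") est[1L] else est[2L]
  }, numeric(1L))
  jack <- jack[!is.na(jack)]
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * (sum((jm - jack)^2))^1.5
  acc <- if (den > 0) num / den else 0
  alpha2 <- c((1 - conf) / 2, 1 - (1 - conf) / 2)
  zq <- stats::qnorm(alpha2)
  adj <- stats::pnorm(z0 + (z0 + zq) / (1 - acc * (z0 + zq)))
  stats::quantile(draws, adj, names = FALSE)
}

#' @export
print.fr_boot <- function(x, ...) {
  cat(sprintf("Bootstrap summary (%s, %d replicates, seed %d)\n",
              x$method, x$n_boot, x$seed))
  cat(sprintf("  attack rate   : %.4g  [%0.4g, %0.4g] %g%% CI\n",
              x$point[["attack_rate"]], x$ci_a[1L], x$ci_a[2L],
              100 * x$conf))
  cat(sprintf("  handling time : %.4g  [%0.4g, %0.4g] %g%% CI\n",
              x$point[["handling_time"]], x$ci_h[1L], x$ci_h[2L],
              100 * x$conf))
  if (x$n_failed > 0 || x$n_redrawn > 0) {
    cat(sprintf("  replicates failed: %d; unidentifiable resamples redrawn: %d\n",
                x$n_failed, x$n_redrawn))
  }
  invisible(x)
}

#' Plot a functional-response curve with its bootstrap band
#'
#' Draws the fitted expected-consumption curve over the band's density
#' grid with the bootstrap confidence cloud as a shaded polygon.
#'
#' @param x An `fr_boot` object.
#' @param ... Further arguments passed to [plot()].
#' @return The object, invisibly.
#' @export
plot.fr_boot <- function(x, ...) {
  b <- x$band
  graphics::plot(b$density, b$point, type = "n",
                 xlab = "Initial prey density",
                 ylab = "Prey eaten per trial period",
                 ylim = range(0, b$upper), ...)
  graphics::polygon(c(b$density, rev(b$density)), c(b$lower, rev(b$upper)),
                    col = grDevices::adjustcolor("steelblue", 0.3),
                    border = NA)
  graphics::lines(b$density, b$point, lwd = 2, col = "steelblue4")
  invisible(x)
}
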