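#' Functional-response parameter set
#'
#' Bundles an attack rate and handling time with the derived maximum
#' feeding rate, validating the parameter constraints used throughout
#' the package.
#'
#' Time is trial-normalised: one unit equals one trial period, so the
#' handling time `h` is in trial periods per prey item and `1/h` is the
#' maximum number of prey that can be handled per trial period.
#'
#' @param attack_rate Attack rate `a` (> 0), per unit prey density per
#'   trial period.
#' @param handling_time Handling time `h` (>= 0), trial periods per prey.
#' @return An object of class `fr_params`: a list with elements
#'   `attack_rate`, `handling_time` and `max_feeding_rate` (`1/h`, `Inf`
#'   when `h = 0`).
#' @examples
#' fr_params(attack_rate = 4.72, handling_time = 0.063)
#' @export
fr_params <- function(attack_rate, handling_time) {
  if (!is.numeric(attack_rate) || length(attack_rate) != 1L ||
      !is.finite(attack_rate) || attack_rate <= 0) {
    stop("`attack_rate` must be a single finite value > 0", call. = FALSE)
  }
  if (!is.numeric(handling_time) || length(handling_time) != 1L ||
      !is.finite(handling_time) || handling_time < 0) {
    stop("`handling_time` must be a single finite value >= 0", call. = FALSE)
  }
  structure(
    list(
      attack_rate = as.numeric(attack_rate),
      handling_time = as.numeric(handling_time),
      max_feeding_rate = if (handling_time > 0) 1 / handling_time else Inf
    ),
    class = "fr_params"
  )
}

#' @export
print.fr_params <- function(x, ...) {
  cat("Functional-response parameters (time in trial periods)\n")
  cat(sprintf("  attack rate (a)      : %.4g\n", x$attack_rate))
  cat(sprintf("  handling time (h)    : %.4g\n", x$handling_time))
  cat(sprintf("  max feeding rate 1/h : %.4g prey per trial period\n",
              x$max_feeding_rate))
  invisible(x)
}

#' Expected consumption under Rogers' random predator equation
#'
#' Solves the implicit random predator equation
#' \deqn{N_e = N_0 (1 - \exp(a (N_e h - T)))}
#' for the expected number of prey eaten `N_e` when consumed prey are not
#' replaced. The unique root in `[0, N_0]` is obtained in closed form via
#' the principal Lambert W branch:
#' \deqn{N_e = N_0 - W_0(a h N_0 e^{-a (T - h N_0)}) / (a h).}
#'
#' Degenerate parameters take their analytic limits rather than being
#' pushed through the Lambert form (which divides by `a h`): `a = 0`
#' gives 0 consumption, and `h = 0` gives pure exponential depletion
#' `N_0 (1 - exp(-a T))`. For large `a h N_0` the Lambert argument is
#' evaluated in log space to avoid overflow.
#'
#' @param a Attack rate(s), >= 0.
#' @param h Handling time(s), >= 0, in trial periods per prey.
#' @param N0 Initial prey density (count offered), >= 0.
#' @param T Trial duration in trial periods (default 1 = one full trial).
#' @return Expected number of prey eaten, in `[0, min(N0, T/h)]`.
#'   Arguments are recycled to a common length.
#' @examples
#' predict_consumed(a = 4.72, h = 0.063, N0 = c(1, 2, 4, 8, 16, 32))
#' predict_consumed(a = 2, h = 0, N0 = 10)  # 10 * (1 - exp(-2))
#' @export
predict_consumed <- function(a, h, N0, T = 1) {
  n <- max(length(a), length(h), length(N0), length(T))
  a <- rep_len(as.numeric(a), n)
  h <- rep_len(as.numeric(h), n)
  N0 <- rep_len(as.numeric(N0), n)
  T <- rep_len(as.numeric(T), n)
  if (any(!is.finite(a)) || any(a < 0)) stop("`a` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(h)) || any(h < 0)) stop("`h` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(N0)) || any(N0 < 0)) stop("`N0` must be finite and >= 0", call. = FALSE)
  if (any(!is.finite(T)) || any(T <= 0)) stop("`T` must be finite and > 0", call. = FALSE)

  rogers_ne_core(a, h, N0, T)
}

# Unchecked vectorised solver for Rogers' equation; inputs already
# validated/recycled. Hot path for the fitting likelihood. Internal.
rogers_ne_core <- function(a, h, N0, T) {
  n <- max(length(a), length(h), length(N0), length(T))
  if (length(a) != n) a <- rep_len(a, n)
  if (length(h) != n) h <- rep_len(h, n)
  if (length(N0) != n) N0 <- rep_len(N0, n)
  if (length(T) != n) T <- rep_len(T, n)
  ne <- numeric(n)
  zero <- a == 0 | N0 == 0
  expdep <- !zero & h == 0
  gen <- !zero & !expdep

  ne[expdep] <- N0[expdep] * (1 - exp(-a[expdep] * T[expdep]))
  if (any(gen)) {
    ag <- a[gen]; hg <- h[gen]; n0 <- N0[gen]; tg <- T[gen]
    log_arg <- log(ag * hg * n0) - ag * (tg - hg * n0)
    wv <- numeric(length(log_arg))
    small <- log_arg <= 700
    if (any(small)) {
      arg <- exp(log_arg[small])
      # the argument is mathematically >= -1/e (it is positive here);
      # clamp guards against any floating-point undershoot
      wv[small] <- lambert_w0(pmax(arg, -exp(-1) + 1e-15))
    }
    if (any(!small)) wv[!small] <- lambert_w0_explog(log_arg[!small])
    ne[gen] <- n0 - wv / (ag * hg)
  }
  pmin(pmax(ne, 0), N0)
}

#' Maximum feeding rate from a handling time
#'
#' The reciprocal of the handling time, `1/h`: the maximum number of prey
#' a predator can process per trial period, attained as prey density grows.
#'
#' @param h Handling time(s) in trial periods per prey; must be > 0.
#' @return `1/h`, prey per trial period.
#' @examples
#' max_feeding_rate(0.063)  # 15.873 prey per trial period
#' @export
max_feeding_rate <- function(h) {
  if (!is.numeric(h) || any(!is.finite(h)) || any(h <= 0)) {
    stop("`h` must be finite and > 0", call. = FALSE)
  }
  1 / h
}
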