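#' Principal branch of the Lambert W function
#'
#' Computes `W0(x)`, the principal real branch of the inverse of
#' `w -> w * exp(w)`, for `x >= -1/e`. `W0` appears in the closed-form
#' solution of Rogers' random predator equation, where the implicit
#' expected-consumption equation is rearranged into `w * exp(w)` form.
#'
#' The implementation uses a series expansion near the branch point
#' `x = -1/e` and a log-based asymptote for large `x` as starting values,
#' then polishes with Halley's iteration until the defining identity
#' `w * exp(w) = x` holds to better than 1e-12 relative error.
#'
#' Arguments an infinitesimal distance below `-1/e` (floating-point
#' undershoot of a mathematically valid argument) are clamped to the
#' branch point; arguments materially below it are a domain error.
#'
#' @param x Numeric vector, each element `>= -exp(-1)` (up to a small
#'   floating-point tolerance).
#' @return Numeric vector of the same length with `W0(x) >= -1`.
#' @examples
#' lambert_w0(0)                      # 0
#' lambert_w0(exp(1))                 # 1
#' w <- lambert_w0(2.5); w * exp(w)   # 2.5
#' @export
lambert_w0 <- function(x) {
  if (!is.numeric(x)) stop("`x` must be numeric", call. = FALSE)
  branch <- -exp(-1)
  tol_dom <- 1e-12
  if (any(x < branch - tol_dom, na.rm = TRUE)) {
    stop(sprintf("lambert_w0: argument below -1/e (min x = %.17g)", min(x)),
         call. = FALSE)
  }
  na_mask <- is.na(x)
  x <- pmax(x, branch)
  x[na_mask] <- 0

  w <- numeric(length(x))
  # Initial guesses by regime
  near <- x < branch + 0.3
  big <- !near & x > 2
  mid <- !near & !big
  if (any(near)) {
    # series about the branch point: w = -1 + p - p^2/3 + 11 p^3/72 - ...
    p <- sqrt(2 * (exp(1) * x[near] + 1))
    w[near] <- -1 + p - p^2 / 3 + 11 * p^3 / 72
  }
  if (any(big)) {
    l1 <- log(x[big])
    l2 <- log(l1)
    w[big] <- l1 - l2 + l2 / l1
  }
  if (any(mid)) w[mid] <- x[mid] * exp(-x[mid] * 0.5)

  # Halley's method on f(w) = w e^w - x
  exact <- x == branch | x == 0           # w = -1 and w = 0 exactly
  w[x == branch] <- -1
  w[x == 0] <- 0
  active <- which(!exact & !na_mask)
  for (iter in seq_len(60L)) {
    if (length(active) == 0L) break
    wa <- w[active]
    ew <- exp(wa)
    f <- wa * ew - x[active]
    denom <- ew * (wa + 1) - (wa + 2) * f / (2 * wa + 2)
    step <- f / denom
    wa <- wa - step
    w[active] <- wa
    done <- abs(step) <= 1e-14 * pmax(1, abs(wa))
    active <- active[!done]
  }
  w[na_mask] <- NA_real_
  w
}

# W0(exp(y)) for large y, avoiding overflow of exp(y): Newton on
# g(w) = w + log(w) - y. Used by predict_consumed() when the Lambert
# argument exceeds the double-precision exp() range. Internal.
lambert_w0_explog <- function(y) {
  w <- pmax(y - log(pmax(y, 2)), 1)
  for (iter in seq_len(60L)) {
    step <- (w + log(w) - y) / (1 + 1 / w)
    w <- w - step
    if (all(abs(step) <= 1e-14 * pmax(1, abs(w)))) break
  }
  w
}
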