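#' Classify functional-response type from density dependence of
#' proportion consumed
#'
#' Fits a binomial logistic regression of (eaten, surviving) counts on
#' initial prey density for one predator group and applies the standard
#' sign rules: a significantly negative first-order (linear density) term
#' indicates a hyperbolic Type II response; a significantly positive
#' first-order term followed, in a quadratic model, by a significantly
#' negative second-order term indicates a sigmoidal Type III response.
#' Anything else is labelled inconclusive.
#'
#' The models are fitted sequentially: the linear-only model first, and
#' the quadratic model only when the linear term is significantly
#' positive. Successes and failures are modelled as grouped binomial
#' counts (not pre-computed proportions), so density-1 trials are handled
#' exactly.
#'
#' @param trials Data frame of feeding trials with columns
#'   `initial_density` and `eaten` (control rows, flagged by an
#'   `is_control` column, are dropped).
#' @param alpha Two-sided significance level for the sign rules
#'   (default 0.05).
#' @return An object of class `fr_type_test`: list with `first_order`,
#'   `p_first`, `second_order`, `p_second` (NA unless the quadratic model
#'   was fitted), `label` (one of `"type_II"`, `"type_III"`,
#'   `"inconclusive"`), `n_trials` and `alpha`.
#' @examples
#' d <- trout_fry_design(seed = 1)
#' tr <- simulate_trials(d)
#' g <- tr[tr$fish_type == "brown_diploid" & tr$novelty == "novel" &
#'           !tr$is_control, ]
#' classify_fr_type(g)
#' @export
classify_fr_type <- function(trials, alpha = 0.05) {
  trials <- drop_controls(trials)
  need <- c("initial_density", "eaten")
  miss <- setdiff(need, names(trials))
  if (length(miss) > 0) {
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha <= 0 || alpha >= 1) {
    stop("`alpha` must be a single value in (0, 1)", call. = FALSE)
  }
  n0 <- trials$initial_density
  eaten <- trials$eaten
  if (length(unique(n0)) < 2L) {
    stop("insufficient data: need trials at >= 2 distinct prey densities",
         call. = FALSE)
  }
  if (sum(eaten) == 0) {
    stop("degenerate data: zero consumption in every trial", call. = FALSE)
  }
  if (sum(n0 - eaten) == 0) {
    stop("degenerate data: total consumption in every trial", call. = FALSE)
  }

  dat <- data.frame(density = n0, eaten = eaten, surv = n0 - eaten)
  fit1 <- stats::glm(cbind(eaten, surv) ~ density,
                     family = stats::binomial(), data = dat)
  check_separation(fit1)
  s1 <- stats::summary.glm(fit1)$coefficients
  first_order <- s1["density", "Estimate"]
  p_first <- s1["density", "Pr(>|z|)"]

  second_order <- NA_real_
  p_second <- NA_real_
  if (first_order < 0 && p_first < alpha) {
    label <- "type_II"
  } else if (first_order > 0 && p_first < alpha) {
    fit2 <- stats::glm(cbind(eaten, surv) ~ density + I(density^2),
                       family = stats::binomial(), data = dat)
    check_separation(fit2)
    s2 <- stats::summary.glm(fit2)$coefficients
    second_order <- s2["I(density^2)", "Estimate"]
    p_second <- s2["I(density^2)", "Pr(>|z|)"]
    label <- if (second_order < 0 && p_second < alpha) "type_III" else "inconclusive"
  } else {
    label <- "inconclusive"
  }

  structure(
    list(
      first_order = unname(first_order),
      p_first = unname(p_first),
      second_order = unname(second_order),
      p_second = unname(p_second),
      label = label,
      n_trials = nrow(dat),
      alpha = alpha
    ),
    class = "fr_type_test"
  )
}

# Guard against complete separation: logistic coefficients diverge and the
# fit is meaningless. Internal.
check_separation <- function(fit) {
  if (!fit$converged || any(abs(stats::coef(fit)) > 1e3)) {
    stop("logistic type test unstable (complete separation or non-convergence); ",
         "coefficients are not interpretable", call. = FALSE)
  }
  invisible(fit)
}

#' @export
print.fr_type_test <- function(x, ...) {
  cat("Functional-response type test (binomial logistic regression)\n")
  cat(sprintf("  n trials     : %d\n", x$n_trials))
  cat(sprintf("  first-order  : %+.4f (p = %.3g)%s\n",
              x$first_order, x$p_first, signif_stars(x$p_first)))
  if (!is.na(x$second_order)) {
    cat(sprintf("  second-order : %+.4g (p = %.3g)%s\n",
                x$second_order, x$p_second, signif_stars(x$p_second)))
  }
  cat(sprintf("  label        : %s (alpha = %g)\n", x$label, x$alpha))
  invisible(x)
}

# Conventional significance stars. Internal.
signif_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) " ***" else if (p < 0.01) " **" else if (p < 0.05) " *" else ""
}

# Drop control rows (and validate the flag) before group-level analysis.
# Internal.
drop_controls <- function(trials) {
  trials <- as.data.frame(trials)
  if ("is_control" %in% names(trials)) {
    trials <- trials[!as.logical(trials$is_control), , drop = FALSE]
  }
  trials
}
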