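#' Design of a simulated prey-depletion feeding experiment
#'
#' Describes a factorial feeding-trial experiment: predator groups (rows
#' of `groups`, each with its own true attack rate and handling time),
#' a set of initial prey densities with a fixed number of replicate
#' trials each, the trial duration, a predator-free control arm, and the
#' stochastic mechanism generating eaten counts.
#'
#' @param densities Initial prey densities offered
#'   (default `c(1, 2, 4, 8, 16, 32)`).
#' @param reps_per_density Replicate trials per density per group
#'   (default 3).
#' @param duration Trial length in trial periods (default 1).
#' @param groups Data frame with columns `fish_type`, `novelty`,
#'   `attack_rate`, `handling_time`: one row per predator group. Defaults
#'   to a single generic group with `a = 5`, `h = 0.1`.
#' @param mechanism `"binomial"` (eaten ~ Binomial(N0, Ne/N0) around the
#'   Rogers expectation; matches the fitting likelihood) or
#'   `"event_driven"` (a continuous-time search/handle process; a
#'   mechanistically distinct generator for robustness checks).
#' @param control_reps Predator-free control trials per density
#'   (default 3; 0 disables the control arm).
#' @param background_mortality Per-prey probability of death in a control
#'   (and of non-predation death generally; default 0, matching arenas
#'   with no background prey mortality).
#' @param seed Integer seed; mandatory, every simulated dataset is fully
#'   reproducible from its design.
#' @return An object of class `sim_design` (a validated list of the
#'   above).
#' @examples
#' sim_design(seed = 1)
#' @export
sim_design <- function(densities = c(1, 2, 4, 8, 16, 32),
                       reps_per_density = 3,
                       duration = 1,
                       groups = NULL,
                       mechanism = c("binomial", "event_driven"),
                       control_reps = 3,
                       background_mortality = 0,
                       seed) {
  mechanism <- match.arg(mechanism)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L) {
    stop("`seed` is required (single integer)", call. = FALSE)
  }
  if (any(densities < 1) || any(densities != round(densities))) {
    stop("`densities` must be positive integers", call. = FALSE)
  }
  if (reps_per_density < 1) stop("`reps_per_density` must be >= 1", call. = FALSE)
  if (duration <= 0) stop("`duration` must be > 0", call. = FALSE)
  if (control_reps < 0) stop("`control_reps` must be >= 0", call. = FALSE)
  if (background_mortality < 0 || background_mortality > 1) {
    stop("`background_mortality` must be in [0, 1]", call. = FALSE)
  }
  if (is.null(groups)) {
    groups <- data.frame(fish_type = "generic", novelty = "novel",
                         attack_rate = 5, handling_time = 0.1)
  }
  need <- c("fish_type", "novelty", "attack_rate", "handling_time")
  miss <- setdiff(need, names(groups))
  if (length(miss) > 0) {
    stop("`groups` missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(groups$attack_rate < 0) || any(groups$handling_time < 0)) {
    stop("group attack rates and handling times must be >= 0", call. = FALSE)
  }
  structure(
    list(
      densities = as.integer(densities),
      reps_per_density = as.integer(reps_per_density),
      duration = as.numeric(duration),
      groups = as.data.frame(groups),
      mechanism = mechanism,
      control_reps = as.integer(control_reps),
      background_mortality = as.numeric(background_mortality),
      seed = as.integer(seed)
    ),
    class = "sim_design"
  )
}

#' @export
print.sim_design <- function(x, ...) {
  cat("Feeding-trial simulation design\n")
  cat(sprintf("  densities : %s (x %d replicates each)\n",
              paste(x$densities, collapse = ", "), x$reps_per_density))
  cat(sprintf("  groups    : %d; duration %g trial period(s); mechanism %s\n",
              nrow(x$groups), x$duration, x$mechanism))
  cat(sprintf("  controls  : %d per density; background mortality %g\n",
              x$control_reps, x$background_mortality))
  cat(sprintf("  seed      : %d\n", x$seed))
  invisible(x)
}

# Table of attack rates / handling times for the trout-fry comparison:
# three fish types x two prey-novelty treatments. Internal.
trout_fry_params <- function() {
  data.frame(
    fish_type = rep(c("rainbow_diploid", "brown_diploid", "brown_triploid"), 2),
    novelty = rep(c("novel", "not_novel"), each = 3),
    attack_rate = c(13.995, 4.720, 33.970, 4.223, 5.873, 40.915),
    handling_time = c(0.100, 0.063, 0.092, 0.085, 0.045, 0.100)
  )
}

#' Preset design: the six-group trout-fry feeding experiment
#'
#' The factorial design of a comparative trout-fry functional-response
#' experiment: three fish types (diploid rainbow trout, diploid brown
#' trout, triploid brown trout) crossed with two prey-novelty treatments,
#' six prey densities (1, 2, 4, 8, 16, 32) with 3 replicate 4-h trials
#' per density per group (108 predator trials), and a predator-free
#' control arm of 3 trials per density (18 controls). True parameters
#' are the fitted attack rates and handling times reported for each
#' group; time is trial-normalised (1 unit = one 4-h trial).
#'
#' @param seed Integer seed (mandatory).
#' @param ... Overrides passed on to [sim_design()] (e.g. `mechanism`,
#'   `reps_per_density`).
#' @return A [sim_design] object.
#' @examples
#' d <- trout_fry_design(seed = 7)
#' nrow(simulate_trials(d))  # 108 predator trials + 18 controls
#' @export
trout_fry_design <- function(seed, ...) {
  sim_design(groups = trout_fry_params(), seed = seed, ...)
}

#' Simulate prey-depletion feeding trials
#'
#' Draws one full dataset from a [sim_design]: for every group, density
#' and replicate, an eaten count is generated under the design's
#' stochastic mechanism, and predator-free controls are appended.
#'
#' Mechanisms:
#' \describe{
#'   \item{binomial}{`eaten ~ Binomial(N0, Ne/N0)` where `Ne` is the
#'     Rogers depletion-corrected expectation from [predict_consumed()].}
#'   \item{event_driven}{A continuous-time process per trial: while
#'     searching, captures occur at rate `a * n_remaining`; each capture
#'     is followed by a handling block of length `h` during which no
#'     searching occurs; the process runs to the trial duration.}
#' }
#' Controls kill each prey independently with probability
#' `background_mortality` (0 by default, i.e. 100% control survival).
#'
#' @param design A [sim_design].
#' @return Data frame of feeding trials with columns `fish_type`,
#'   `novelty`, `initial_density`, `eaten`, `duration`, `is_control`,
#'   `replicate_id`. Control rows have `fish_type = NA` and
#'   `novelty = NA`.
#' @examples
#' simulate_trials(sim_design(seed = 1))
#' @export
simulate_trials <- function(design) {
  if (!inherits(design, "sim_design")) {
    stop("`design` must be a sim_design", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         envir = globalenv()))
  set.seed(design$seed)

  g <- design$groups
  cells <- expand.grid(
    replicate_id = seq_len(design$reps_per_density),
    initial_density = design$densities,
    group = seq_len(nrow(g))
  )
  a <- g$attack_rate[cells$group]
  h <- g$handling_time[cells$group]
  n0 <- cells$initial_density
  T <- design$duration

  if (design$mechanism == "binomial") {
    ne <- predict_consumed(a, h, n0, T)
    eaten <- stats::rbinom(nrow(cells), size = n0, prob = ne / n0)
  } else {
    eaten <- mapply(sim_event_trial, a, h, n0, MoreArgs = list(T = T))
  }
  # non-predation deaths, if enabled, add to the toll of the eaten
  if (design$background_mortality > 0) {
    extra <- stats::rbinom(nrow(cells), size = n0 - eaten,
                           prob = design$background_mortality)
    eaten <- eaten + extra
  }

  out <- data.frame(
    fish_type = as.character(g$fish_type[cells$group]),
    novelty = as.character(g$novelty[cells$group]),
    initial_density = as.integer(n0),
    eaten = as.integer(eaten),
    duration = T,
    is_control = FALSE,
    replicate_id = cells$replicate_id
  )

  if (design$control_reps > 0) {
    cc <- expand.grid(
      replicate_id = seq_len(design$control_reps),
      initial_density = design$densities
    )
    dead <- stats::rbinom(nrow(cc), size = cc$initial_density,
                          prob = design$background_mortality)
    out <- rbind(out, data.frame(
      fish_type = NA_character_,
      novelty = NA_character_,
      initial_density = as.integer(cc$initial_density),
      eaten = as.integer(dead),
      duration = T,
      is_control = TRUE,
      replicate_id = cc$replicate_id
    ))
  }
  rownames(out) <- NULL
  out
}

# One event-driven trial: exponential search waits at rate a * n, handling
# blocks of length h after each capture, run to time T. Internal.
sim_event_trial <- function(a, h, n0, T) {
  t <- 0
  n <- n0
  eaten <- 0L
  if (a <= 0) return(eaten)
  repeat {
    if (n == 0L) break
    t <- t + stats::rexp(1L, rate = a * n)
    if (t >= T) break
    eaten <- eaten + 1L
    n <- n - 1L
    t <- t + h
    if (t >= T) break
  }
  eaten
}
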