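trials_columns <- c("fish_type", "novelty", "initial_density", "eaten",
                    "duration", "is_control", "replicate_id")

#' Read a feeding-trials table from CSV
#'
#' Reads and validates the shared trials schema: one row per
#' predator-arena trial (or predator-free control), UTF-8 with a header
#' row and '.' decimal separator. Row-level violations (eaten counts
#' exceeding the prey offered, negative counts, non-positive durations)
#' are reported with their row numbers.
#'
#' @param path Path to a CSV file with columns `fish_type`, `novelty`,
#'   `initial_density`, `eaten`, `duration`, `is_control`,
#'   `replicate_id`.
#' @return A validated data frame of feeding trials.
#' @examples
#' tr <- simulate_trials(sim_design(seed = 1))
#' f <- tempfile(fileext = ".csv")
#' write_trials(tr, f)
#' identical(read_trials(f)$eaten, tr$eaten)
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE),
    error = function(e) stop("schema error: cannot parse '", path, "' as CSV (",
                             conditionMessage(e), ")", call. = FALSE)
  )
  validate_trials(df)
}

#' Write a feeding-trials table to CSV
#'
#' @param trials Data frame of feeding trials.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials[, trials_columns], path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Validate a feeding-trials table
#'
#' Checks the schema (required columns) and row-level invariants:
#' `0 <= eaten <= initial_density`, integer non-negative densities and
#' counts, positive durations. Offending rows are listed by number.
#'
#' @param trials Data frame to validate.
#' @return The validated data frame (types coerced), invisibly usable.
#' @export
validate_trials <- function(trials) {
  trials <- as.data.frame(trials)
  miss <- setdiff(trials_columns, names(trials))
  if (length(miss) > 0 || nrow(trials) == 0) {
    stop("schema error: ",
         if (nrow(trials) == 0) "no data rows; " else "",
         if (length(miss) > 0) paste0("missing columns: ",
                                      paste(miss, collapse = ", ")) else "",
         call. = FALSE)
  }
  trials$initial_density <- suppressWarnings(as.numeric(trials$initial_density))
  trials$eaten <- suppressWarnings(as.numeric(trials$eaten))
  trials$duration <- suppressWarnings(as.numeric(trials$duration))
  trials$is_control <- as.logical(trials$is_control)

  bad <- which(
    is.na(trials$initial_density) | trials$initial_density < 0 |
      trials$initial_density != round(trials$initial_density) |
      is.na(trials$eaten) | trials$eaten < 0 |
      trials$eaten != round(trials$eaten) |
      trials$eaten > trials$initial_density |
      is.na(trials$duration) | trials$duration <= 0 |
      is.na(trials$is_control)
  )
  if (length(bad) > 0) {
    stop("validation error in trials table, row(s) ",
         paste(utils::head(bad, 20), collapse = ", "),
         ": need 0 <= eaten <= initial_density (integers), duration > 0, ",
         "and a logical is_control flag", call. = FALSE)
  }
  trials
}

#' Summarise predator-free control trials
#'
#' Computes prey survival in the control arm. With 100% survival, deaths
#' in predator trials are attributable to predation and the summary says
#' so; with any background mortality a warning is emitted and per-density
#' mortality is reported so downstream analysis can proceed annotated.
#'
#' @param trials Data frame of feeding trials (controls flagged by
#'   `is_control`).
#' @return An object of class `fr_control_summary`: list with `status`
#'   (`"ok"`, `"background_mortality"` or `"no_controls"`),
#'   `survival_pct`, `attribute_to_predation` flag, `n_controls` and
#'   `per_density` mortality table.
#' @examples
#' tr <- simulate_trials(sim_design(seed = 1))
#' check_controls(tr)
#' @export
check_controls <- function(trials) {
  trials <- as.data.frame(trials)
  ctrl <- if ("is_control" %in% names(trials)) {
    trials[as.logical(trials$is_control), , drop = FALSE]
  } else {
    trials[0, , drop = FALSE]
  }
  if (nrow(ctrl) == 0) {
    return(structure(
      list(status = "no_controls", survival_pct = NA_real_,
           attribute_to_predation = FALSE, n_controls = 0L,
           per_density = NULL,
           message = "no predator-free controls in the input"),
      class = "fr_control_summary"
    ))
  }
  offered <- sum(ctrl$initial_density)
  dead <- sum(ctrl$eaten)
  survival_pct <- 100 * (1 - dead / offered)
  if (dead == 0) {
    structure(
      list(status = "ok", survival_pct = survival_pct,
           attribute_to_predation = TRUE, n_controls = nrow(ctrl),
           per_density = NULL,
           message = paste("prey survival in predator-free controls was 100%;",
                           "experimental deaths attributable to predation")),
      class = "fr_control_summary"
    )
  } else {
    per_density <- do.call(rbind, lapply(
      split(ctrl, ctrl$initial_density),
      function(d) data.frame(initial_density = d$initial_density[1L],
                             mortality_pct = 100 * sum(d$eaten) /
                               sum(d$initial_density))
    ))
    rownames(per_density) <- NULL
    warning(sprintf(paste0("control prey survival was %.1f%% (< 100%%): ",
                           "deaths cannot all be attributed to predation"),
                    survival_pct), call. = FALSE)
    structure(
      list(status = "background_mortality", survival_pct = survival_pct,
           attribute_to_predation = FALSE, n_controls = nrow(ctrl),
           per_density = per_density,
           message = sprintf(paste0("control prey survival %.1f%%; analysis ",
                                    "proceeds but deaths include background ",
                                    "mortality"), survival_pct)),
      class = "fr_control_summary"
    )
  }
}

#' @export
print.fr_control_summary <- function(x, ...) {
  cat("Predator-free control summary\n")
  cat(sprintf("  controls : %d trials\n", x$n_controls))
  if (!is.na(x$survival_pct)) {
    cat(sprintf("  survival : %.1f%%\n", x$survival_pct))
  }
  cat("  ", x$message, "\n", sep = "")
  if (!is.null(x$per_density)) {
    print(x$per_density)
  }
  invisible(x)
}
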