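TRIAL_COLUMNS <- c("subject_id", "age_group", "recipient", "block_index",
                   "trial_in_block", "chosen_option", "reward")

#' Read and validate trial-level choice data
#'
#' Reads a CSV with the package's trial schema (`subject_id`, `age_group`,
#' `recipient`, `block_index`, `trial_in_block`, `chosen_option`,
#' `reward`) and validates types, value ranges, duplicate
#' (subject, block, trial) keys and per-block trial counts. Errors name
#' the offending rows (numbered as in the data, header excluded).
#'
#' @param path Path to a CSV file.
#' @param strict If TRUE (default), a block with a trial count other than
#'   `n_trials` is an error; otherwise a warning.
#' @param n_trials Expected trials per block (default 16).
#' @return A validated tibble of trial records.
#' @export
read_trials <- function(path, strict = TRUE, n_trials = 16) {
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_guess()))
  validate_trials(raw, strict = strict, n_trials = n_trials)
}

validate_trials <- function(trials, strict = TRUE, n_trials = 16) {
  missing <- setdiff(setdiff(TRIAL_COLUMNS, "age_group"), names(trials))
  if (length(missing)) {
    stop("trial data is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (!"age_group" %in% names(trials)) trials$age_group <- NA_character_
  name_rows <- function(bad, what) {
    stop(what, " on row(s) ", paste(head(which(bad), 10), collapse = ", "),
         if (sum(bad) > 10) " ..." else "", ".", call. = FALSE)
  }
  bad <- !trials$recipient %in% RECIPIENTS
  if (any(bad)) name_rows(bad, "invalid recipient")
  bad <- !trials$reward %in% c(0, 1)
  if (any(bad)) name_rows(bad, "reward outside {0, 1}")
  bad <- !trials$chosen_option %in% c("high", "low")
  if (any(bad)) name_rows(bad, "chosen_option not 'high'/'low'")
  bad <- !is.finite(trials$trial_in_block) |
    trials$trial_in_block < 0 | trials$trial_in_block >= n_trials
  if (any(bad)) name_rows(bad, "trial_in_block out of range")
  key <- paste(trials$subject_id, trials$block_index, trials$trial_in_block)
  bad <- duplicated(key)
  if (any(bad)) name_rows(bad, "duplicated (subject, block, trial) key")
  counts <- trials |>
    dplyr::count(.data$subject_id, .data$block_index)
  short <- counts[counts$n != n_trials, ]
  if (nrow(short)) {
    msg <- paste0("block(s) without ", n_trials, " trials: ",
                  paste(head(paste0(short$subject_id, "/block ",
                                    short$block_index, " (", short$n, ")"),
                             5), collapse = ", "))
    if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
  }
  tibble::as_tibble(trials)[, union(TRIAL_COLUMNS, names(trials))]
}

#' @describeIn read_trials Write trial records to CSV.
#' @param trials A tibble of trial records.
#' @export
write_trials <- function(trials, path) {
  readr::write_csv(trials[, intersect(TRIAL_COLUMNS, names(trials))], path)
  invisible(path)
}

#' Schedule serialisation
#'
#' Schedules round-trip through JSON (one object per block).
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param path Output / input path.
#' @return `read_schedule()` returns the schedule tibble;
#'   `write_schedule()` returns `path` invisibly.
#' @export
write_schedule <- function(schedule, path) {
  jsonlite::write_json(schedule, path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule
#' @export
read_schedule <- function(path) {
  sched <- tibble::as_tibble(jsonlite::read_json(path, simplifyVector = TRUE))
  sched$block_index <- as.integer(sched$block_index)
  sched$n_trials <- as.integer(sched$n_trials)
  check_schedule(sched)
}

#' Write analysis results with provenance
#'
#' Serialises a named list of results (fits, evidences, model-selection
#' outputs, study summaries — tibbles, matrices and scalars all supported)
#' to JSON, embedding the configuration and seed used to produce them.
#'
#' @param results Named list of results.
#' @param path Output path.
#' @param config Optional [run_config()] list stored alongside.
#' @param seed Optional seed stored alongside.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path, config = NULL, seed = NULL) {
  payload <- list(results = results,
                  config = config,
                  seed = seed,
                  written_at = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       force = TRUE, pretty = TRUE)
  invisible(path)
}

#' Analysis configuration
#'
#' Collects the tunable constants of the fitting and simulation pipeline
#' in one list. Defaults are the study conditions: prior initialisation
#' mean 0.1 and variance 100, EM cap 800 iterations with tolerance 0.001,
#' 5 optimisation starts, 2000 Monte-Carlo draws for the integrated BIC,
#' and the full-scale simulation studies; `scale = "ci"` switches the
#' studies to reduced sizes (40 subjects x 3 repetitions identifiability,
#' 300-subject recovery) for quick runs.
#'
#' @param seed Master seed.
#' @param models Model names to fit.
#' @param scale `"paper"` (full-scale studies) or `"ci"` (reduced).
#' @param ... Overrides for any default constant.
#' @return A list of class `pl_config`.
#' @export
run_config <- function(seed = 1, models = list_models(),
                       scale = c("paper", "ci"), ...) {
  scale <- match.arg(scale)
  cfg <- list(
    seed = seed,
    models = models,
    scale = scale,
    max_iter = 800,
    tol = 1e-3,
    init_mean = 0.1,
    init_var = 100,
    init_noise_sd = 0.05,
    var_floor = 1e-6,
    n_starts = 5,
    q0 = 0,
    ibic_samples = 2000,
    bms_mc_samples = 1e6,
    identifiability_subjects = if (scale == "paper") 150 else 40,
    identifiability_reps = if (scale == "paper") 10 else 3,
    recovery_sims = if (scale == "paper") 1296 else 300,
    optimal_alpha_agents = 10000
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pl_config")
}

#' @export
print.pl_config <- function(x, ...) {
  cat("<pl_config> scale =", x$scale, ", seed =", x$seed, "\n")
  utils::str(unclass(x), give.attr = FALSE)
  invisible(x)
}
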