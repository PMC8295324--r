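#' Model identifiability study
#'
#' Simulates cohorts from each candidate model in turn (learning rates
#' from Beta(1.1, 1.1); temperatures from Gamma(1.2, scale 5) truncated
#' by default to the behaviourally plausible range — an untruncated draw
#' has mean 6, which in this softmax convention makes agents choose at
#' random and leaves nothing to identify), fits every candidate to every
#' cohort by
#' hierarchical MAP, and submits the Laplace log evidences to
#' random-effects model selection. Repeating this over `n_reps` independent
#' cohorts yields confusion matrices of average exceedance probability and
#' of best-model counts; identifiable model sets show strong diagonals.
#'
#' @param n_subjects Subjects per simulated cohort (default 150).
#' @param n_reps Repetitions of the whole procedure (default 10).
#' @param models Candidate model names (all four by default).
#' @param seed Integer master seed.
#' @param n_starts Optimisation starts per subject (first EM iteration).
#' @param mc_samples Dirichlet draws per model-selection run.
#' @param beta_bounds Interval truncating the temperature distribution
#'   (default `c(0, 0.3)`, the range observed in human play; `NULL` for
#'   the unbounded gamma).
#' @param verbose Print progress.
#' @return An object of class `pl_identifiability`: `avg_exceedance` and
#'   `best_model_counts` matrices (generative rows x fitted columns),
#'   `n_reps`, and a long `details` tibble of every exceedance value.
#' @export
identifiability_study <- function(n_subjects = 150, n_reps = 10,
                                  models = list_models(), seed = NULL,
                                  n_starts = 5, mc_samples = 1e6,
                                  beta_bounds = c(0, 0.3),
                                  verbose = FALSE) {
  if (length(models) < 2) {
    stop("identifiability needs at least 2 candidate models.", call. = FALSE)
  }
  local_seed_if(seed)
  m <- length(models)
  avg_xp <- matrix(0, m, m, dimnames = list(models, models))
  counts <- matrix(0L, m, m, dimnames = list(models, models))
  details <- list()
  for (rep_i in seq_len(n_reps)) {
    for (g in seq_along(models)) {
      gen <- models[g]
      params <- sample_population(n_subjects, gen, beta_bounds = beta_bounds)
      schedule <- generate_schedule()
      trials <- simulate_population(params, schedule, gen)
      lme <- vapply(models, function(cand) {
        fit <- fit_group(trials, cand, n_starts = n_starts)
        fit$subjects$laplace_log_evidence
      }, numeric(n_subjects))
      if (anyNA(lme)) {
        stop("undefined Laplace evidence in rep ", rep_i,
             ", generative model ", gen, ".", call. = FALSE)
      }
      bms <- bms_random_effects(lme, mc_samples = mc_samples)
      xp <- bms$exceedance_probabilities
      avg_xp[g, ] <- avg_xp[g, ] + xp
      win <- which.max(xp)
      counts[g, win] <- counts[g, win] + 1L
      details[[length(details) + 1L]] <- tibble::tibble(
        rep = rep_i, generative = gen, fitted = models,
        exceedance = unname(xp)
      )
      if (verbose) {
        message(sprintf("rep %d gen %s -> winner %s (xp %.2f)",
                        rep_i, gen, models[win], xp[win]))
      }
    }
  }
  structure(
    list(avg_exceedance = avg_xp / n_reps, best_model_counts = counts,
         n_reps = n_reps, models = models,
         details = dplyr::bind_rows(details)),
    class = "pl_identifiability"
  )
}

#' @export
print.pl_identifiability <- function(x, ...) {
  cat("<pl_identifiability> ", x$n_reps, " repetitions\n",
      "Average exceedance probability (generative rows, fitted cols):\n",
      sep = "")
  print(round(x$avg_exceedance, 3))
  cat("Best-model counts:\n")
  print(x$best_model_counts)
  invisible(x)
}

#' @method autoplot pl_identifiability
#' @export
autoplot.pl_identifiability <- function(object, ...) {
  df <- object$details |>
    dplyr::group_by(.data$generative, .data$fitted) |>
    dplyr::summarise(exceedance = mean(.data$exceedance), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fitted, y = .data$generative,
                                   fill = .data$exceedance)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$exceedance))) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "Fitted model", y = "Generative model",
                  fill = "Mean\nexceedance") +
    ggplot2::theme_minimal()
}

# Stratified uniforms: one draw per stratum, in shuffled stratum order
stratified_uniform <- function(n) {
  (sample.int(n) - runif(n)) / n
}

#' Parameter recovery study
#'
#' Simulates one task session per parameter set from the
#' separate-learning-rates model, refits the whole simulated cohort by
#' hierarchical MAP, and correlates generative with recovered parameter
#' values (Pearson, native space). High diagonal correlations show the
#' task schedule identifies the model's parameters.
#'
#' Parameter sets are stratified by default — each learning-rate slot
#' stratified over (0, 1) and the temperature over the quantiles of
#' Gamma(1.2, scale 5), truncated to `beta_bounds` — so the sets span the
#' whole parameter space evenly; `sampler = "grid"` instead uses a full
#' factorial grid (n_sims must then be a fourth power, e.g. 1296 = 6^4).
#'
#' @param n_sims Number of simulated subjects (default 1296; at least 50).
#' @param model Model to recover (must have one alpha per recipient and a
#'   single temperature, i.e. k = 4).
#' @param sampler `"stratified"` (default) or `"grid"`.
#' @param beta_bounds Interval truncating the temperature distribution
#'   (default `c(0, 0.3)`, the range observed in human play).
#' @param seed Integer master seed.
#' @param n_starts Optimisation starts per subject (first EM iteration).
#' @return An object of class `pl_recovery`: `correlation_matrix`
#'   (generative rows x recovered columns), and a `params` tibble pairing
#'   generative (`gen_*`) with recovered (`fit_*`) values.
#' @export
parameter_recovery_study <- function(n_sims = 1296, model = "3a1b",
                                     sampler = c("stratified", "grid"),
                                     beta_bounds = c(0, 0.3), seed = NULL,
                                     n_starts = 5) {
  model <- as_pl_model(model)
  sampler <- match.arg(sampler)
  if (model$k != 4) {
    stop("parameter recovery targets the k = 4 model (one alpha per ",
         "recipient, one beta).", call. = FALSE)
  }
  if (n_sims < 50) {
    stop("`n_sims` must be at least 50 (correlations are unstable below).",
         call. = FALSE)
  }
  local_seed_if(seed)
  q_beta <- function(u) {
    lo <- pgamma(beta_bounds[1], 1.2, scale = 5)
    hi <- pgamma(beta_bounds[2], 1.2, scale = 5)
    qgamma(lo + u * (hi - lo), 1.2, scale = 5)
  }
  if (sampler == "stratified") {
    gen <- tibble::tibble(
      alpha_self = stratified_uniform(n_sims),
      alpha_other = stratified_uniform(n_sims),
      alpha_no_one = stratified_uniform(n_sims),
      beta = q_beta(stratified_uniform(n_sims))
    )
  } else {
    g <- round(n_sims^(1 / 4))
    if (g^4 != n_sims) {
      stop("grid sampling needs `n_sims` to be a fourth power ",
           "(e.g. 1296 = 6^4).", call. = FALSE)
    }
    mids <- (seq_len(g) - 0.5) / g
    gen <- tidyr::expand_grid(alpha_self = mids, alpha_other = mids,
                              alpha_no_one = mids, beta = q_beta(mids))
  }
  gen$subject_id <- sprintf("s%05d", seq_len(nrow(gen)))
  schedule <- generate_schedule()
  trials <- simulate_population(gen, schedule, model)
  fit <- fit_group(trials, model, n_starts = n_starts)
  rec <- fit$subjects[, c("subject_id", model$par_names)]
  names(rec)[-1] <- paste0("fit_", model$par_names)
  gen_tbl <- gen[, c("subject_id", model$par_names)]
  names(gen_tbl)[-1] <- paste0("gen_", model$par_names)
  params <- dplyr::inner_join(gen_tbl, rec, by = "subject_id")
  cm <- cor(as.matrix(params[, paste0("gen_", model$par_names)]),
            as.matrix(params[, paste0("fit_", model$par_names)]),
            method = "pearson")
  dimnames(cm) <- list(model$par_names, model$par_names)
  structure(
    list(correlation_matrix = cm, params = params,
         n_sims = nrow(gen), model = model),
    class = "pl_recovery"
  )
}

#' @export
print.pl_recovery <- function(x, ...) {
  cat("<pl_recovery> ", x$n_sims, " simulated subjects (",
      x$model$name, ")\n",
      "Generative vs recovered Pearson correlations:\n", sep = "")
  print(round(x$correlation_matrix, 3))
  invisible(x)
}

#' @method autoplot pl_recovery
#' @export
autoplot.pl_recovery <- function(object, ...) {
  df <- as.data.frame(as.table(object$correlation_matrix))
  names(df) <- c("generative", "recovered", "r")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$recovered,
                                   y = .data$generative, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.2f", .data$r))) +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::labs(x = "Recovered parameter", y = "Generative parameter",
                  fill = "Pearson r") +
    ggplot2::theme_minimal()
}

#' Optimal learning rate study
#'
#' Simulates a large population under the separate-learning-rates model
#' (alpha per recipient ~ Beta(1.1, 1.1) spanning (0, 1); temperature ~
#' Gamma(1.2, scale 5) truncated to `beta_bounds`), scores each
#' (agent, recipient) learning rate by the proportion of high-reward
#' choices over that recipient's blocks, and bins performance against the
#' learning rate. The peak of the binned mean curve locates the learning
#' rate that is optimal for this task schedule.
#'
#' @param n_agents Simulated participants (default 10000, giving
#'   `3 * n_agents` learning-rate values).
#' @param beta_bounds Truncation interval for the temperature
#'   (default `c(0, 0.3)`, the range observed in human play).
#' @param n_bins Equal-width alpha bins (default 50); adjacent bins are
#'   merged until every bin holds at least `min_per_bin` points.
#' @param min_per_bin Minimum points per bin (default 100).
#' @param seed Integer master seed.
#' @return An object of class `pl_perf_curve`: `data` (one row per
#'   agent-recipient pair: `alpha`, `accuracy`), `curve` (one row per bin:
#'   mean `alpha`, mean `accuracy`, `n`), `smooth` (a weighted loess fit
#'   of the binned means on a fine grid), and `optimal_alpha` (the peak
#'   of the smoothed curve).
#' @export
optimal_alpha_study <- function(n_agents = 10000, beta_bounds = c(0, 0.3),
                                n_bins = 50, min_per_bin = 100,
                                seed = NULL) {
  local_seed_if(seed)
  model <- model_spec("3a1b")
  params <- sample_population(n_agents, model, beta_bounds = beta_bounds)
  schedule <- generate_schedule()
  trials <- simulate_population(params, schedule, model)
  perf <- trials |>
    dplyr::group_by(.data$subject_id, .data$recipient) |>
    dplyr::summarise(accuracy = mean(.data$chosen_option == "high"),
                     .groups = "drop")
  alpha_long <- params |>
    tidyr::pivot_longer(dplyr::starts_with("alpha_"),
                        names_to = "recipient", names_prefix = "alpha_",
                        values_to = "alpha") |>
    dplyr::select("subject_id", "recipient", "alpha")
  data <- dplyr::inner_join(perf, alpha_long,
                            by = c("subject_id", "recipient"))
  curve <- bin_performance(data$alpha, data$accuracy, n_bins, min_per_bin)
  # the curve is a broad plateau, so the raw binned argmax is noisy; take
  # the peak of a weighted loess smooth of the bin means instead
  smooth <- stats::loess(accuracy ~ alpha, data = curve, weights = curve$n,
                         span = 1, degree = 2)
  grid <- seq(min(curve$alpha), max(curve$alpha), length.out = 512)
  fitted <- stats::predict(smooth, newdata = data.frame(alpha = grid))
  structure(
    list(data = data, curve = curve,
         smooth = tibble::tibble(alpha = grid, accuracy = fitted),
         optimal_alpha = grid[which.max(fitted)],
         n_agents = n_agents),
    class = "pl_perf_curve"
  )
}

# Equal-width bins over (0,1); sparse bins merged into their left
# neighbour so the binned means stay stable.
bin_performance <- function(alpha, accuracy, n_bins, min_per_bin) {
  bin <- pmin(pmax(ceiling(alpha * n_bins), 1L), n_bins)
  counts <- tabulate(bin, n_bins)
  # map each original bin to a merged bin id, walking left to right
  merged <- integer(n_bins)
  cur <- 1L
  acc_n <- 0L
  for (b in seq_len(n_bins)) {
    merged[b] <- cur
    acc_n <- acc_n + counts[b]
    if (acc_n >= min_per_bin && b < n_bins) {
      cur <- cur + 1L
      acc_n <- 0L
    }
  }
  if (acc_n < min_per_bin && cur > 1L) {
    merged[merged == cur] <- cur - 1L  # fold a short tail into the last bin
  }
  tibble::tibble(bin = merged[bin], alpha = alpha, accuracy = accuracy) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(alpha = mean(.data$alpha),
                     accuracy = mean(.data$accuracy),
                     n = dplyr::n(), .groups = "drop")
}

#' @export
print.pl_perf_curve <- function(x, ...) {
  cat("<pl_perf_curve> ", x$n_agents, " agents, ",
      nrow(x$data), " (agent, recipient) learning rates\n",
      "Optimal learning rate (smoothed-curve peak): ",
      sprintf("%.3f", x$optimal_alpha), "\n", sep = "")
  invisible(x)
}

#' @describeIn optimal_alpha_study The binned curve as a tibble.
#' @param x A `pl_perf_curve`.
#' @param ... Unused.
#' @method tidy pl_perf_curve
#' @export
tidy.pl_perf_curve <- function(x, ...) x$curve

#' @method autoplot pl_perf_curve
#' @export
autoplot.pl_perf_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$alpha, y = .data$accuracy)) +
    ggplot2::geom_point(data = object$data, alpha = 0.05, size = 0.3,
                        colour = "steelblue") +
    ggplot2::geom_point(size = 1) +
    ggplot2::geom_line(data = object$smooth, linewidth = 1,
                       colour = "firebrick") +
    ggplot2::geom_vline(xintercept = object$optimal_alpha,
                        linetype = "dashed") +
    ggplot2::labs(x = expression(alpha), y = "Proportion correct") +
    ggplot2::theme_minimal()
}
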