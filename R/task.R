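#' Generate a task schedule
#'
#' Builds one session of the probabilistic reward-learning task: nine blocks
#' of sixteen trials, three blocks per recipient condition (self, other,
#' no one), pseudo-randomly ordered so the same recipient never occurs in
#' two consecutive blocks. Each block pairs a fresh pair of symbols, one
#' rewarded with probability `p_high` and the other with `1 - p_high`.
#'
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param p_high Reward probability of the better symbol (default 0.75).
#' @param n_trials Trials per block (default 16).
#' @param n_blocks_per_recipient Blocks per recipient condition (default 3).
#' @return A tibble with one row per block: `block_index`, `recipient`,
#'   `symbol_pair_id`, `p_high`, `p_low`, `n_trials`.
#' @examples
#' sched <- generate_schedule(seed = 1)
#' sum(sched$n_trials) # 144
#' @export
generate_schedule <- function(seed = NULL, p_high = 0.75, n_trials = 16,
                              n_blocks_per_recipient = 3) {
  stopifnot(p_high > 0, p_high < 1, n_trials >= 1,
            n_blocks_per_recipient >= 1)
  local_seed_if(seed)
  pool <- rep(RECIPIENTS, n_blocks_per_recipient)
  # rejection sampling over orderings: cheap and exact for 3 x 3 blocks
  repeat {
    ord <- sample(pool)
    if (!any(ord[-1] == ord[-length(ord)])) break
  }
  tibble::tibble(
    block_index = seq_along(ord),
    recipient = ord,
    symbol_pair_id = paste0("pair_", seq_along(ord)),
    p_high = p_high,
    p_low = 1 - p_high,
    n_trials = as.integer(n_trials)
  )
}

check_schedule <- function(schedule) {
  required <- c("block_index", "recipient", "p_high", "p_low", "n_trials")
  missing <- setdiff(required, names(schedule))
  if (length(missing)) {
    stop("schedule is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (any(schedule$recipient[-1] == schedule$recipient[-nrow(schedule)])) {
    stop("schedule has two consecutive blocks with the same recipient.",
         call. = FALSE)
  }
  invisible(schedule)
}

# Core vectorised simulator: n agents play the same schedule in parallel.
# alpha_mat: n x n_alpha native learning rates; beta_mat: n x n_beta.
# Choices and rewards are drawn trial by trial; values reset at block start.
simulate_engine <- function(schedule, model, alpha_mat, beta_mat,
                            q0 = 0, subject_ids = NULL) {
  model <- as_pl_model(model)
  check_schedule(schedule)
  n <- nrow(alpha_mat)
  if (is.null(subject_ids)) subject_ids <- sprintf("s%03d", seq_len(n))
  total <- sum(schedule$n_trials)
  rec_out <- character(total * n)
  blk_out <- integer(total * n)
  tib_out <- integer(total * n)
  cho_out <- character(total * n)
  rew_out <- integer(total * n)
  pos <- 0L
  for (b in seq_len(nrow(schedule))) {
    rec <- schedule$recipient[b]
    a <- alpha_mat[, model$alpha_map[[rec]]]
    beta <- pmax(beta_mat[, model$beta_map[[rec]]], 1e-6)
    p_hi <- schedule$p_high[b]
    p_lo <- schedule$p_low[b]
    nt <- schedule$n_trials[b]
    q_high <- rep(q0, n)
    q_low <- rep(q0, n)
    for (t in seq_len(nt)) {
      p_choose_high <- stats::plogis((q_high - q_low) / beta)
      choose_high <- runif(n) < p_choose_high
      reward <- as.integer(runif(n) < ifelse(choose_high, p_hi, p_lo))
      q_high <- ifelse(choose_high, q_high + a * (reward - q_high), q_high)
      q_low <- ifelse(choose_high, q_low, q_low + a * (reward - q_low))
      idx <- pos + seq_len(n)
      rec_out[idx] <- rec
      blk_out[idx] <- schedule$block_index[b]
      tib_out[idx] <- t - 1L
      cho_out[idx] <- ifelse(choose_high, "high", "low")
      rew_out[idx] <- reward
      pos <- pos + n
    }
  }
  tibble::tibble(
    subject_id = rep(subject_ids, times = total),
    recipient = rec_out,
    block_index = blk_out,
    trial_in_block = tib_out,
    chosen_option = cho_out,
    reward = rew_out
  ) |>
    dplyr::arrange(.data$subject_id, .data$block_index, .data$trial_in_block)
}

#' Simulate one agent on a schedule
#'
#' Plays a parameterised delta-rule/softmax agent through a schedule:
#' choices are drawn from the softmax over current values, rewards are
#' Bernoulli with the chosen symbol's contingency, and values reset to `q0`
#' at every block start.
#'
#' @param schedule A schedule tibble from [generate_schedule()].
#' @param model A `pl_model` or model name.
#' @param alpha,beta Native-space parameters, one per slot of the model.
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @param q0 Initial expected value per symbol.
#' @param subject_id Identifier written into the output.
#' @return A tibble of trial records: `subject_id`, `recipient`,
#'   `block_index`, `trial_in_block`, `chosen_option` (`"high"`/`"low"`
#'   relative to the generative contingency), `reward` (0/1).
#' @export
simulate_agent <- function(schedule, model, alpha, beta, seed = NULL,
                           q0 = 0, subject_id = "s001") {
  model <- as_pl_model(model)
  check_native_params(alpha, beta, model)
  local_seed_if(seed)
  simulate_engine(schedule, model,
                  matrix(alpha, nrow = 1), matrix(beta, nrow = 1),
                  q0 = q0, subject_ids = subject_id)
}

#' Sample a population of agent parameters
#'
#' Draws native-space parameters for `n_subjects` agents from the
#' distributions standard in the reinforcement-learning literature:
#' learning rates from Beta(1.1, 1.1) and temperatures from
#' Gamma(shape 1.2, scale 5), the latter optionally truncated to
#' `beta_bounds` via the inverse-CDF method.
#'
#' @param n_subjects Number of agents.
#' @param model A `pl_model` or model name (sets the slot count).
#' @param alpha_shape1,alpha_shape2 Beta distribution shapes for alpha.
#' @param beta_shape,beta_scale Gamma distribution parameters for beta.
#' @param beta_bounds Optional length-2 interval truncating beta.
#' @param seed Integer seed (NULL to use the current RNG stream).
#' @return A tibble with `subject_id` and one column per model parameter
#'   (native space).
#' @examples
#' sample_population(5, "3a1b", seed = 1)
#' @export
sample_population <- function(n_subjects, model = "3a1b",
                              alpha_shape1 = 1.1, alpha_shape2 = 1.1,
                              beta_shape = 1.2, beta_scale = 5,
                              beta_bounds = NULL, seed = NULL) {
  stopifnot(n_subjects > 0)
  model <- as_pl_model(model)
  if (!is.null(beta_bounds)) {
    if (length(beta_bounds) != 2 || beta_bounds[1] >= beta_bounds[2] ||
        beta_bounds[1] < 0) {
      stop("`beta_bounds` must be an interval [lower, upper] with ",
           "0 <= lower < upper.", call. = FALSE)
    }
  }
  local_seed_if(seed)
  draw_beta <- function(n) {
    if (is.null(beta_bounds)) {
      rgamma(n, shape = beta_shape, scale = beta_scale)
    } else {
      lo <- pgamma(beta_bounds[1], shape = beta_shape, scale = beta_scale)
      hi <- pgamma(beta_bounds[2], shape = beta_shape, scale = beta_scale)
      qgamma(lo + runif(n) * (hi - lo), shape = beta_shape,
             scale = beta_scale)
    }
  }
  out <- tibble::tibble(subject_id = sprintf("s%04d", seq_len(n_subjects)))
  for (j in seq_len(model$n_alpha)) {
    out[[model$par_names[j]]] <-
      rbeta(n_subjects, alpha_shape1, alpha_shape2)
  }
  for (j in seq_len(model$n_beta)) {
    out[[model$par_names[model$n_alpha + j]]] <- draw_beta(n_subjects)
  }
  out
}

#' Simulate a cohort of agents
#'
#' Simulates every agent in a parameter table (as produced by
#' [sample_population()]) through a schedule.
#'
#' @param params Tibble with `subject_id` and the model's native parameter
#'   columns.
#' @inheritParams simulate_agent
#' @return A tibble of trial records for all subjects.
#' @export
simulate_population <- function(params, schedule, model, seed = NULL,
                                q0 = 0) {
  model <- as_pl_model(model)
  missing <- setdiff(c("subject_id", model$par_names), names(params))
  if (length(missing)) {
    stop("`params` is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  local_seed_if(seed)
  amat <- as.matrix(params[, model$par_names[model$kind == "alpha"],
                           drop = FALSE])
  bmat <- as.matrix(params[, model$par_names[model$kind == "beta"],
                           drop = FALSE])
  simulate_engine(schedule, model, amat, bmat, q0 = q0,
                  subject_ids = params$subject_id)
}

#' Summarise task performance
#'
#' Performance is the proportion of trials on which the high-probability
#' symbol was chosen. Returns per-recipient (plus overall) accuracy and the
#' trial-position learning curve, averaged over each recipient's blocks.
#'
#' @param trials A tibble of trial records.
#' @return An object of class `pl_performance`: a list with `accuracy`
#'   (tibble: `recipient`, `n_trials`, `accuracy`, including an `"overall"`
#'   row) and `curve` (tibble: `recipient`, `trial_in_block`, `accuracy`).
#' @export
performance_summary <- function(trials) {
  if (is.null(trials) || nrow(trials) == 0) {
    stop("`trials` must contain at least one trial.", call. = FALSE)
  }
  correct <- trials$chosen_option == "high"
  by_rec <- trials |>
    dplyr::mutate(correct = correct) |>
    dplyr::group_by(.data$recipient) |>
    dplyr::summarise(n_trials = dplyr::n(),
                     accuracy = mean(.data$correct), .groups = "drop")
  overall <- tibble::tibble(recipient = "overall",
                            n_trials = nrow(trials),
                            accuracy = mean(correct))
  curve <- trials |>
    dplyr::mutate(correct = correct) |>
    dplyr::group_by(.data$recipient, .data$trial_in_block) |>
    dplyr::summarise(accuracy = mean(.data$correct), .groups = "drop")
  structure(list(accuracy = dplyr::bind_rows(by_rec, overall),
                 curve = curve),
            class = "pl_performance")
}

#' @export
print.pl_performance <- function(x, ...) {
  cat("<pl_performance>\n")
  print(x$accuracy)
  invisible(x)
}

#' @method autoplot pl_performance
#' @export
autoplot.pl_performance <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$trial_in_block + 1,
                               y = .data$accuracy,
                               colour = .data$recipient)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = "dashed") +
    ggplot2::labs(x = "Trial within block",
                  y = "P(choose high-reward symbol)",
                  colour = "Recipient") +
    ggplot2::theme_minimal()
}
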