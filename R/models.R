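#' Model variants: how learning rates and temperatures are shared
#'
#' The model space crosses a delta-rule value update with a softmax choice
#' rule, and varies only in how the learning rate \eqn{\alpha} and the
#' temperature \eqn{\beta} are shared across the three recipient conditions
#' (self, other, no one):
#'
#' * `"1a1b"` — one \eqn{\alpha}, one \eqn{\beta} (2 free parameters);
#' * `"2a1b"` — \eqn{\alpha_{self}} and a shared \eqn{\alpha_{not-self}}
#'   for other and no one, one \eqn{\beta} (3);
#' * `"3a1b"` — a separate \eqn{\alpha} per recipient, one \eqn{\beta} (4);
#' * `"3a3b"` — separate \eqn{\alpha} and \eqn{\beta} per recipient (6).
#'
#' @param name One of `"1a1b"`, `"2a1b"`, `"3a1b"`, `"3a3b"`.
#' @return An object of class `pl_model`: a list with the slot maps
#'   (`alpha_map`, `beta_map`, recipient -> slot index), slot counts
#'   (`n_alpha`, `n_beta`), the total parameter count `k`, and the
#'   parameter names in Gaussian-vector order (`par_names`, alphas first).
#' @examples
#' model_spec("3a1b")$par_names
#' @export
model_spec <- function(name) {
  name <- match.arg(name, list_models())
  amap <- switch(name,
    "1a1b" = c(self = 1L, other = 1L, no_one = 1L),
    "2a1b" = c(self = 1L, other = 2L, no_one = 2L),
    "3a1b" = c(self = 1L, other = 2L, no_one = 3L),
    "3a3b" = c(self = 1L, other = 2L, no_one = 3L)
  )
  bmap <- switch(name,
    "3a3b" = c(self = 1L, other = 2L, no_one = 3L),
    c(self = 1L, other = 1L, no_one = 1L)
  )
  alpha_names <- switch(name,
    "1a1b" = "alpha",
    "2a1b" = c("alpha_self", "alpha_not_self"),
    c("alpha_self", "alpha_other", "alpha_no_one")
  )
  beta_names <- if (name == "3a3b") {
    c("beta_self", "beta_other", "beta_no_one")
  } else {
    "beta"
  }
  structure(
    list(
      name = name,
      alpha_map = amap,
      beta_map = bmap,
      n_alpha = max(amap),
      n_beta = max(bmap),
      k = max(amap) + max(bmap),
      par_names = c(alpha_names, beta_names),
      kind = c(rep("alpha", max(amap)), rep("beta", max(bmap)))
    ),
    class = "pl_model"
  )
}

#' @export
print.pl_model <- function(x, ...) {
  cat("<pl_model ", x$name, ">  k = ", x$k,
      "  parameters: ", paste(x$par_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @rdname model_spec
#' @export
list_models <- function() c("1a1b", "2a1b", "3a1b", "3a3b")

as_pl_model <- function(model) {
  if (inherits(model, "pl_model")) model else model_spec(model)
}

#' Delta-rule value update
#'
#' Updates an expected value toward the obtained reward by a fraction
#' \eqn{\alpha} of the prediction error:
#' \eqn{Q' = Q + \alpha (r - Q)}, \eqn{\delta = r - Q}.
#'
#' @param q Current expected value(s).
#' @param reward Obtained reward(s), typically 0/1.
#' @param alpha Learning rate(s) in `[0, 1]`.
#' @return A list with `q` (updated value) and `delta` (prediction error);
#'   vectorised over its arguments.
#' @examples
#' q_update(0.5, 1, 0.2) # q = 0.6, delta = 0.5
#' @export
q_update <- function(q, reward, alpha) {
  if (any(!is.finite(alpha)) || any(alpha < 0 | alpha > 1)) {
    stop("`alpha` must lie in [0, 1].", call. = FALSE)
  }
  delta <- reward - q
  list(q = q + alpha * delta, delta = delta)
}

#' Softmax choice probabilities
#'
#' Maps expected values to choice probabilities through a temperature-scaled
#' softmax, \eqn{p(a) = e^{Q(a)/\beta} / \sum_{a'} e^{Q(a')/\beta}}. Larger
#' \eqn{\beta} makes choice noisier (more exploratory); as \eqn{\beta \to 0}
#' choice becomes greedy on the best value. Computed with max-subtraction so
#' small temperatures cannot overflow; `beta` is floored at `1e-6`.
#'
#' @param q_values Numeric vector of expected values (one per option).
#' @param beta Temperature, > 0.
#' @return Numeric probability vector summing to 1.
#' @examples
#' choice_probabilities(c(0.6, 0.4), 0.1) # ~ (0.881, 0.119)
#' @export
choice_probabilities <- function(q_values, beta) {
  if (any(!is.finite(q_values))) {
    stop("`q_values` must be finite.", call. = FALSE)
  }
  if (!is.numeric(beta) || length(beta) != 1 || !is.finite(beta) || beta < 0) {
    stop("`beta` must be a single non-negative number.", call. = FALSE)
  }
  z <- q_values / max(beta, 1e-6)
  ez <- exp(z - max(z))
  ez / sum(ez)
}

#' Link functions between Gaussian and native parameter space
#'
#' Fitting happens in unbounded Gaussian space; parameters map to their
#' native ranges through a sigmoid for learning rates (range (0,1)) and an
#' exponential for temperatures (range (0, Inf)). `native_to_gaussian()` is
#' the exact inverse on the open range.
#'
#' @param x Unbounded real value(s).
#' @param v Native-space value(s).
#' @param kind `"alpha"` (sigmoid) or `"beta"` (exponential).
#' @return Transformed numeric vector.
#' @examples
#' link_to_native(0, "alpha") # 0.5
#' link_to_native(0, "beta")  # 1
#' @export
link_to_native <- function(x, kind = c("alpha", "beta")) {
  kind <- match.arg(kind)
  if (any(!is.finite(x))) stop("`x` must be finite.", call. = FALSE)
  if (kind == "alpha") stats::plogis(x) else exp(x)
}

#' @rdname link_to_native
#' @export
native_to_gaussian <- function(v, kind = c("alpha", "beta")) {
  kind <- match.arg(kind)
  if (kind == "alpha") {
    if (any(v <= 0 | v >= 1)) {
      stop("alpha values must lie strictly inside (0, 1).", call. = FALSE)
    }
    stats::qlogis(v)
  } else {
    if (any(v <= 0)) stop("beta values must be strictly positive.", call. = FALSE)
    log(v)
  }
}

# Gaussian vector -> named native values for a model
gaussian_to_native <- function(x, model) {
  model <- as_pl_model(model)
  stopifnot(length(x) == model$k)
  out <- ifelse(model$kind == "alpha", stats::plogis(x), exp(x))
  stats::setNames(out, model$par_names)
}

# Named native values (alpha slots then beta slots) -> Gaussian vector
native_to_gaussian_vec <- function(native, model) {
  model <- as_pl_model(model)
  native <- native[model$par_names]
  if (anyNA(native)) {
    stop("native parameters must be named with: ",
         paste(model$par_names, collapse = ", "), call. = FALSE)
  }
  a <- native_to_gaussian(native[model$kind == "alpha"], "alpha")
  b <- native_to_gaussian(native[model$kind == "beta"], "beta")
  stats::setNames(c(a, b), model$par_names)
}

# Validate native parameter vectors supplied per slot
check_native_params <- function(alpha, beta, model) {
  model <- as_pl_model(model)
  if (length(alpha) != model$n_alpha) {
    stop("expected ", model$n_alpha, " alpha value(s) for model ",
         model$name, ", got ", length(alpha), ".", call. = FALSE)
  }
  if (length(beta) != model$n_beta) {
    stop("expected ", model$n_beta, " beta value(s) for model ",
         model$name, ", got ", length(beta), ".", call. = FALSE)
  }
  if (any(!is.finite(alpha)) || any(alpha <= 0 | alpha >= 1)) {
    stop("alpha values must lie strictly inside (0, 1).", call. = FALSE)
  }
  if (any(!is.finite(beta)) || any(beta <= 0)) {
    stop("beta values must be strictly positive.", call. = FALSE)
  }
  invisible(TRUE)
}

# Encode a single subject's trials for the compiled forward pass.
# Returns 0-based slot indices into the Gaussian parameter vector.
encode_trials <- function(trials, model, allow_empty = FALSE) {
  model <- as_pl_model(model)
  required <- c("recipient", "block_index", "trial_in_block",
                "chosen_option", "reward")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trials are missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(trials) == 0) {
    if (!allow_empty) stop("no trials to encode.", call. = FALSE)
    return(list(new_block = integer(0), alpha_idx = integer(0),
                beta_idx = integer(0), chose_high = integer(0),
                reward = integer(0), n = 0L))
  }
  trials <- dplyr::arrange(trials, .data$block_index, .data$trial_in_block)
  bad_rec <- !trials$recipient %in% RECIPIENTS
  if (any(bad_rec)) {
    stop("unknown recipient value(s): ",
         paste(unique(trials$recipient[bad_rec]), collapse = ", "),
         call. = FALSE)
  }
  per_block <- unlist(lapply(
    split(trials$recipient, trials$block_index),
    function(r) length(unique(r))
  ))
  if (any(per_block > 1)) {
    stop("recipient must be constant within a block.", call. = FALSE)
  }
  if (!all(trials$reward %in% c(0, 1))) {
    stop("reward must be 0 or 1.", call. = FALSE)
  }
  if (!all(trials$chosen_option %in% c("high", "low"))) {
    stop("chosen_option must be 'high' or 'low'.", call. = FALSE)
  }
  list(
    new_block = as.integer(c(1L, diff(trials$block_index) != 0)),
    alpha_idx = as.integer(model$alpha_map[trials$recipient] - 1L),
    beta_idx = as.integer(model$n_alpha +
                            model$beta_map[trials$recipient] - 1L),
    chose_high = as.integer(trials$chosen_option == "high"),
    reward = as.integer(trials$reward),
    n = nrow(trials)
  )
}

#' Negative log-likelihood of a choice sequence
#'
#' Runs the delta-rule/softmax forward pass over one subject's trials,
#' resetting values to `q0` at every block start and using the alpha and
#' beta slot that the model assigns to each block's recipient. Returns the
#' summed negative log-likelihood together with each trial's probability of
#' the choice actually made (used downstream for the choice-probability
#' R-squared).
#'
#' @param trials Tibble of one subject's trials (columns `recipient`,
#'   `block_index`, `trial_in_block`, `chosen_option`, `reward`).
#' @param model A `pl_model` or model name.
#' @param alpha,beta Native-space parameter values, one per slot of the
#'   model (in slot order).
#' @param q0 Initial expected value per symbol (default 0, the standard
#'   initialisation; configurable).
#' @return A list with `nll` and `p_chosen` (per-trial probabilities in
#'   block/trial order).
#' @export
negative_log_likelihood <- function(trials, model, alpha, beta, q0 = 0) {
  model <- as_pl_model(model)
  check_native_params(alpha, beta, model)
  enc <- encode_trials(trials, model)
  x <- c(native_to_gaussian(alpha, "alpha"), native_to_gaussian(beta, "beta"))
  .rl_nll_cpp(enc$new_block, enc$alpha_idx, enc$beta_idx, enc$chose_high,
              enc$reward, as.numeric(x), q0)
}
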