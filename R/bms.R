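#' Random-effects Bayesian model selection
#'
#' Treats the model generating each subject's data as a random effect with
#' population frequencies under a Dirichlet prior, and fits the Dirichlet
#' by variational Bayes from the subjects-by-models matrix of log model
#' evidences (the standard `spm_BMS` computation). Starting from a weight
#' of 1 per model, per-subject model responsibilities
#' \eqn{u_{nm} \propto \exp(\mathrm{lme}_{nm} + \psi(\alpha_m) -
#' \psi(\sum_j \alpha_j))} and weights \eqn{\alpha_m = 1 + \sum_n u_{nm}}
#' are iterated until the largest weight change falls below `tol`.
#' Exceedance probabilities — the posterior probability that each model is
#' the most frequent in the population — are estimated by Monte-Carlo
#' sampling from the fitted Dirichlet.
#'
#' @param log_evidence Numeric matrix, subjects in rows, models in columns
#'   (column names label the models).
#' @param mc_samples Dirichlet draws for the exceedance estimate
#'   (default 1e6).
#' @param tol Convergence threshold on the weight change (default 1e-6).
#' @param max_iter Iteration cap for the variational loop (default 1e4).
#' @param seed Integer seed for the Monte-Carlo draws.
#' @return An object of class `pl_bms` with `dirichlet_weights`,
#'   `expected_frequencies`, `exceedance_probabilities` (all named by
#'   model), `n_vb_iterations` and `mc_samples_used`.
#' @examples
#' lme <- cbind(m1 = c(-100, -102, -98), m2 = c(-110, -109, -111))
#' bms_random_effects(lme, mc_samples = 1e4, seed = 1)
#' @export
bms_random_effects <- function(log_evidence, mc_samples = 1e6, tol = 1e-6,
                               max_iter = 1e4, seed = NULL) {
  log_evidence <- as.matrix(log_evidence)
  if (ncol(log_evidence) < 2) {
    stop("model selection needs at least 2 models.", call. = FALSE)
  }
  if (nrow(log_evidence) < 1) {
    stop("at least one subject is required.", call. = FALSE)
  }
  if (any(!is.finite(log_evidence))) {
    stop("log evidences must all be finite.", call. = FALSE)
  }
  m <- ncol(log_evidence)
  models <- colnames(log_evidence) %||% paste0("model_", seq_len(m))
  alpha0 <- rep(1, m)
  alpha <- alpha0
  iter <- 0L
  repeat {
    iter <- iter + 1L
    w <- sweep(log_evidence, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    w <- exp(w - apply(w, 1, max))
    u <- w / rowSums(w)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol || iter >= max_iter) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }
  local_seed_if(seed)
  draws <- matrix(rgamma(mc_samples * m, shape = rep(alpha, each = mc_samples)),
                  mc_samples, m)
  winner <- max.col(draws, ties.method = "first")
  xp <- tabulate(winner, nbins = m) / mc_samples
  structure(
    list(
      dirichlet_weights = stats::setNames(alpha, models),
      expected_frequencies = stats::setNames(alpha / sum(alpha), models),
      exceedance_probabilities = stats::setNames(xp, models),
      n_vb_iterations = iter,
      mc_samples_used = as.integer(mc_samples)
    ),
    class = "pl_bms"
  )
}

#' @export
print.pl_bms <- function(x, ...) {
  cat("<pl_bms> ", length(x$dirichlet_weights), " models, ",
      x$n_vb_iterations, " VB iterations\n", sep = "")
  print(tidy(x))
  invisible(x)
}

#' @describeIn bms_random_effects Per-model summary as a tibble.
#' @param x A `pl_bms` object.
#' @param ... Unused.
#' @method tidy pl_bms
#' @export
tidy.pl_bms <- function(x, ...) {
  tibble::tibble(
    model = names(x$dirichlet_weights),
    dirichlet_weight = unname(x$dirichlet_weights),
    expected_frequency = unname(x$expected_frequencies),
    exceedance_probability = unname(x$exceedance_probabilities)
  )
}

#' @method autoplot pl_bms
#' @export
autoplot.pl_bms <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$model,
                               y = .data$exceedance_probability)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = 0.95, linetype = "dashed") +
    ggplot2::labs(x = NULL, y = "Exceedance probability") +
    ggplot2::theme_minimal()
}
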