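#' Group-level Gaussian prior
#'
#' One Gaussian (mean, variance) per Gaussian-space parameter slot of a
#' model. The fitting routine initialises these as near-uninformative
#' priors (means 0.1 plus noise, variance 100) and re-estimates them at
#' each maximisation step.
#'
#' @param mean,var Numeric vectors, one entry per parameter slot.
#' @param model Optional `pl_model` (names the slots).
#' @return An object of class `pl_prior` with `mean` and `var` vectors.
#' @export
group_prior <- function(mean, var, model = NULL) {
  if (length(mean) != length(var)) {
    stop("`mean` and `var` must have the same length.", call. = FALSE)
  }
  if (any(!is.finite(var)) || any(var <= 0)) {
    stop("prior variances must be positive and finite.", call. = FALSE)
  }
  if (!is.null(model)) {
    model <- as_pl_model(model)
    if (length(mean) != model$k) {
      stop("prior has ", length(mean), " slots but model ", model$name,
           " has k = ", model$k, ".", call. = FALSE)
    }
    names(mean) <- names(var) <- model$par_names
  }
  structure(list(mean = mean, var = var), class = "pl_prior")
}

#' @export
print.pl_prior <- function(x, ...) {
  cat("<pl_prior>\n")
  print(tibble::tibble(slot = names(x$mean) %||% seq_along(x$mean),
                       mean = unname(x$mean), var = unname(x$var)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Concatenate per-subject encodings for the batched E-step
concat_encodings <- function(encs) {
  list(
    offsets = as.integer(c(0, cumsum(vapply(encs, `[[`, integer(1), "n")))),
    new_block = unlist(lapply(encs, `[[`, "new_block"), use.names = FALSE),
    alpha_idx = unlist(lapply(encs, `[[`, "alpha_idx"), use.names = FALSE),
    beta_idx = unlist(lapply(encs, `[[`, "beta_idx"), use.names = FALSE),
    chose_high = unlist(lapply(encs, `[[`, "chose_high"), use.names = FALSE),
    reward = unlist(lapply(encs, `[[`, "reward"), use.names = FALSE)
  )
}

# Starts array (k x n_starts x n_subjects): first the warm start (or the
# prior mean), then the prior mean, then seeded perturbations of it
make_starts <- function(prior, n_subjects, n_starts, start_sd,
                        warm = NULL) {
  k <- length(prior$mean)
  out <- array(0, c(k, n_starts, n_subjects))
  for (s in seq_len(n_subjects)) {
    cols <- list(if (is.null(warm)) prior$mean else warm[, s])
    while (length(cols) < n_starts) {
      cols[[length(cols) + 1L]] <-
        if (length(cols) == 1) prior$mean
        else prior$mean + rnorm(k, 0, start_sd)
    }
    out[, , s] <- matrix(unlist(cols), nrow = k)
  }
  out
}

run_estep <- function(cat_enc, prior, starts, n_starts, q0,
                      hessian_step = 1e-4) {
  .em_estep_cpp(as.numeric(starts), as.integer(n_starts), cat_enc$offsets,
                cat_enc$new_block, cat_enc$alpha_idx, cat_enc$beta_idx,
                cat_enc$chose_high, cat_enc$reward, q0,
                prior$mean, prior$var, hessian_step = hessian_step)
}

# Assemble a pl_subject_fit from one column of an E-step result
build_subject_fit <- function(res, s, enc, model, prior, q0) {
  x_hat <- res$x[, s]
  fwd <- .rl_nll_cpp(enc$new_block, enc$alpha_idx, enc$beta_idx,
                     enc$chose_high, enc$reward, x_hat, q0)
  pd <- res$pd[s] == 1L
  k <- model$k
  evidence <- if (pd) {
    res$log_lik[s] + res$log_prior[s] + 0.5 * k * log(2 * pi) -
      0.5 * res$logdet[s]
  } else {
    NA_real_
  }
  H <- .map_hessian_cpp(x_hat, enc$new_block, enc$alpha_idx, enc$beta_idx,
                        enc$chose_high, enc$reward, q0, prior$mean,
                        prior$var)
  structure(
    list(
      estimate_gaussian = stats::setNames(x_hat, model$par_names),
      estimate_native = gaussian_to_native(x_hat, model),
      log_lik = res$log_lik[s],
      log_prior = res$log_prior[s],
      log_posterior = res$log_lik[s] + res$log_prior[s],
      hessian = H,
      hessian_pd = pd,
      posterior_var_diag = res$inv_diag[, s],
      laplace_log_evidence = evidence,
      p_chosen = fwd$p_chosen,
      converged = res$converged[s] == 1L,
      n_trials = enc$n,
      model = model$name
    ),
    class = "pl_subject_fit"
  )
}

fit_subject_encoded <- function(enc, model, prior, q0 = 0, n_starts = 5,
                                start_sd = 1) {
  starts <- make_starts(prior, 1L, n_starts, start_sd)
  res <- run_estep(concat_encodings(list(enc)), prior, starts, n_starts, q0)
  build_subject_fit(res, 1L, enc, model, prior, q0)
}

#' Fit one subject by maximum a posteriori estimation
#'
#' Maximises the log-likelihood of the subject's choice sequence plus the
#' log-density of the group-level Gaussian prior, in unbounded Gaussian
#' parameter space, by quasi-Newton optimisation from multiple starts
#' (the prior mean plus seeded perturbations; ties broken by start order).
#' The Hessian of the negative log posterior at the optimum is estimated by
#' central finite differences and used for the Laplace log model evidence.
#'
#' With zero informative data (an empty likelihood) the MAP estimate equals
#' the prior means; with a near-flat prior it approaches the MLE.
#'
#' @param trials One subject's trial records.
#' @param model A `pl_model` or model name.
#' @param prior A `pl_prior` with one slot per model parameter.
#' @param q0 Initial expected value per symbol.
#' @param n_starts Number of optimisation starts (default 5).
#' @param start_sd Standard deviation of the start perturbations.
#' @param seed Integer seed for the start perturbations (NULL = ambient RNG).
#' @return An object of class `pl_subject_fit` with Gaussian- and
#'   native-space estimates, log-likelihood / prior / posterior at the MAP,
#'   the Hessian (and whether it was positive definite), the Laplace log
#'   evidence, per-trial chosen-option probabilities, and a convergence flag.
#' @export
fit_subject_map <- function(trials, model, prior, q0 = 0, n_starts = 5,
                            start_sd = 1, seed = NULL) {
  model <- as_pl_model(model)
  if (length(prior$mean) != model$k) {
    stop("prior slot count (", length(prior$mean),
         ") does not match model k (", model$k, ").", call. = FALSE)
  }
  local_seed_if(seed)
  enc <- encode_trials(trials, model, allow_empty = TRUE)
  fit_subject_encoded(enc, model, prior, q0 = q0, n_starts = n_starts,
                      start_sd = start_sd)
}

#' Laplace approximation of the log model evidence
#'
#' Approximates the log marginal likelihood of one subject's data by a
#' Gaussian expansion around the posterior mode:
#' \deqn{\log p(D) \approx \log p(D|\hat\theta) + \log p(\hat\theta)
#'   + (k/2)\log 2\pi - \tfrac12 \log |H|}
#' where \eqn{H} is the Hessian of the negative log posterior at the MAP
#' estimate. More positive values indicate better fit. The Hessian must be
#' positive definite; otherwise the evidence is undefined and an error is
#' raised.
#'
#' @param log_lik Log-likelihood at the MAP estimate.
#' @param log_prior Log prior density at the MAP estimate.
#' @param hessian k x k Hessian of the negative log posterior at the mode
#'   (a 0 x 0 matrix gives the exact evidence of a parameter-free model).
#' @return The approximate log evidence (a scalar).
#' @export
laplace_evidence <- function(log_lik, log_prior, hessian) {
  hessian <- as.matrix(hessian)
  k <- nrow(hessian)
  if (k == 0) return(log_lik + log_prior)
  ch <- tryCatch(chol(hessian), error = function(e) NULL)
  if (is.null(ch)) {
    stop("Hessian is not positive definite; Laplace evidence undefined.",
         call. = FALSE)
  }
  log_lik + log_prior + 0.5 * k * log(2 * pi) - sum(log(diag(ch)))
}

#' Hierarchical MAP fitting by expectation-maximisation
#'
#' Fits a model to a cohort by alternating per-subject MAP estimation under
#' group-level Gaussian priors (expectation) with re-estimation of those
#' priors from the subject-level estimates (maximisation). Priors are
#' initialised with means 0.1 plus seeded Gaussian noise and variance 100;
#' iteration stops when the summed log posterior changes by less than `tol`
#' or after `max_iter` steps.
#'
#' By default the maximisation step uses Laplace second moments (squared
#' estimates plus inverse-Hessian diagonals) so subject-level uncertainty
#' feeds the group variance; `var_method = "sample"` uses the sample
#' variance of the point estimates only. Variances are floored at
#' `var_floor` to prevent prior collapse. Subjects are re-optimised from
#' warm starts (their previous estimates) after the first iteration.
#'
#' @param trials Trial records for at least two subjects (`subject_id`
#'   column distinguishes them).
#' @param model A `pl_model` or model name.
#' @param max_iter Maximum EM iterations (default 800).
#' @param tol Convergence threshold on the change in summed log posterior
#'   (default 0.001).
#' @param init_mean,init_var,init_noise_sd Prior initialisation constants.
#' @param var_floor Lower bound on group variances.
#' @param var_method `"laplace"` (default) or `"sample"`.
#' @param n_starts Optimisation starts per subject on the first iteration.
#' @param q0 Initial expected value per symbol.
#' @param seed Integer seed controlling initialisation noise and start
#'   perturbations.
#' @param verbose Print per-iteration progress.
#' @return An object of class `pl_group_fit`: final `prior`, per-subject
#'   `fits`, a `subjects` tibble of native-space estimates and evidences,
#'   the posterior `trajectory`, `n_iterations`, `converged`, and the
#'   pooled choice-probability R-squared (`pseudo_r2`).
#' @export
fit_group <- function(trials, model, max_iter = 800, tol = 1e-3,
                      init_mean = 0.1, init_var = 100, init_noise_sd = 0.05,
                      var_floor = 1e-6, var_method = c("laplace", "sample"),
                      n_starts = 5, q0 = 0, seed = NULL, verbose = FALSE) {
  model <- as_pl_model(model)
  var_method <- match.arg(var_method)
  ids <- unique(trials$subject_id)
  if (length(ids) < 2) {
    stop("hierarchical fitting requires at least 2 subjects.", call. = FALSE)
  }
  local_seed_if(seed)
  encs <- lapply(split(trials, trials$subject_id)[ids], encode_trials,
                 model = model)
  cat_enc <- concat_encodings(encs)
  k <- model$k
  n <- length(ids)
  prior <- group_prior(init_mean + rnorm(k, 0, init_noise_sd),
                       rep(init_var, k), model)
  trajectory <- numeric(0)
  converged <- FALSE
  last_total <- -Inf
  res <- NULL
  for (iter in seq_len(max_iter)) {
    # multi-start exploration on the first pass; previous optima are
    # excellent warm starts once the prior is only drifting
    starts <- if (iter == 1) {
      make_starts(prior, n, n_starts, start_sd = 1)
    } else {
      make_starts(prior, n, 1L, start_sd = 1, warm = res$x)
    }
    res <- run_estep(cat_enc, prior, starts, dim(starts)[2], q0)
    total <- sum(res$log_lik + res$log_prior)
    if (!is.finite(total)) {
      stop("non-finite group posterior at iteration ", iter,
           "; aborting.", call. = FALSE)
    }
    trajectory <- c(trajectory, total)
    if (verbose) {
      message(sprintf("iter %3d  sum log posterior %.4f", iter, total))
    }
    if (iter > 1 && abs(total - last_total) < tol) {
      converged <- TRUE
      break
    }
    last_total <- total
    # maximisation: refresh the group Gaussians from the subject estimates
    mu <- rowMeans(res$x)
    if (var_method == "laplace") {
      second_moment <- rowMeans(res$x^2 + res$inv_diag)
    } else {
      second_moment <- rowMeans(res$x^2)
    }
    v <- pmax(second_moment - mu^2, var_floor)
    prior <- group_prior(mu, v, model)
  }
  fits <- lapply(seq_len(n), function(s) {
    build_subject_fit(res, s, encs[[s]], model, prior, q0)
  })
  names(fits) <- ids
  subjects <- purrr::map2_dfr(fits, ids, function(f, id) {
    tibble::as_tibble(as.list(f$estimate_native)) |>
      dplyr::mutate(subject_id = id,
                    log_lik = f$log_lik,
                    log_posterior = f$log_posterior,
                    laplace_log_evidence = f$laplace_log_evidence,
                    converged = f$converged,
                    .before = 1)
  })
  structure(
    list(model = model, prior = prior, fits = fits, subjects = subjects,
         trajectory = trajectory, n_iterations = length(trajectory),
         converged = converged,
         pseudo_r2 = pseudo_r2(fits)),
    class = "pl_group_fit"
  )
}

#' @export
print.pl_group_fit <- function(x, ...) {
  cat("<pl_group_fit> model ", x$model$name, ": ",
      nrow(x$subjects), " subjects, ",
      x$n_iterations, " EM iterations (",
      if (x$converged) "converged" else "iteration cap reached", ")\n",
      "  pooled choice-probability R2: ",
      sprintf("%.1f%%", 100 * x$pseudo_r2), "\n", sep = "")
  invisible(x)
}

#' @describeIn fit_group Per-subject native-space estimates as a tibble.
#' @param x,object A `pl_group_fit`.
#' @param ... Unused.
#' @method tidy pl_group_fit
#' @export
tidy.pl_group_fit <- function(x, ...) {
  x$subjects |>
    tidyr::pivot_longer(dplyr::all_of(x$model$par_names),
                        names_to = "parameter", values_to = "estimate") |>
    dplyr::select("subject_id", "parameter", "estimate",
                  "log_lik", "laplace_log_evidence")
}

#' @describeIn fit_group One-row fit summary.
#' @method glance pl_group_fit
#' @export
glance.pl_group_fit <- function(x, ...) {
  tibble::tibble(
    model = x$model$name,
    k = x$model$k,
    n_subjects = nrow(x$subjects),
    n_iterations = x$n_iterations,
    converged = x$converged,
    total_log_posterior = x$trajectory[length(x$trajectory)],
    mean_laplace_evidence = mean(x$subjects$laplace_log_evidence),
    pseudo_r2 = x$pseudo_r2
  )
}

#' Choice-probability R-squared
#'
#' Pools the fitted per-trial chosen-option probabilities across all
#' subjects and squares their median — a simple summary of how well the
#' model predicts the choices actually made (0.25 for a coin-flipping
#' model, 1 for perfect prediction).
#'
#' @param fits A `pl_group_fit`, or a list of `pl_subject_fit` objects.
#' @return The squared median choice probability (a proportion).
#' @export
pseudo_r2 <- function(fits) {
  if (inherits(fits, "pl_group_fit")) fits <- fits$fits
  if (inherits(fits, "pl_subject_fit")) fits <- list(fits)
  pool <- unlist(lapply(fits, function(f) f$p_chosen))
  if (length(pool) == 0) {
    stop("no per-trial choice probabilities to pool.", call. = FALSE)
  }
  median(pool)^2
}

# iBIC core, exposed for tests: marginal log-likelihood estimates per
# subject (log mean likelihood over prior draws) plus the group penalty.
ibic_from_components <- function(log_marginals, n_group_params, n_obs) {
  if (any(!is.finite(log_marginals))) {
    stop("non-finite marginal likelihood estimate (all samples underflowed).",
         call. = FALSE)
  }
  -2 * sum(log_marginals) + n_group_params * log(n_obs)
}

#' Integrated BIC of a fitted group model
#'
#' Scores a model at the group level by Monte-Carlo integration of each
#' subject's likelihood over the fitted group prior:
#' \deqn{iBIC = -2 \sum_s \log \frac1M \sum_m p(D_s|\theta_m)
#'   + 2k \log N}
#' with \eqn{\theta_m} drawn from the group Gaussians, \eqn{2k} group-level
#' parameters (a mean and a variance per slot) and \eqn{N} the total number
#' of observed trials. Lower is better. The inner average is computed with
#' a stable log-sum-exp.
#'
#' @param trials The cohort's trial records.
#' @param prior The fitted `pl_prior` (or a `pl_group_fit`, from which the
#'   prior and model are taken).
#' @param model A `pl_model` or model name (ignored if `prior` is a fit).
#' @param n_samples Monte-Carlo draws from the prior (default 2000).
#' @param q0 Initial expected value per symbol.
#' @param seed Integer seed for the prior draws.
#' @return The iBIC value (scalar).
#' @export
integrated_bic <- function(trials, prior, model = NULL, n_samples = 2000,
                           q0 = 0, seed = NULL) {
  if (inherits(prior, "pl_group_fit")) {
    model <- prior$model
    prior <- prior$prior
  }
  model <- as_pl_model(model)
  if (n_samples < 100) {
    stop("`n_samples` must be at least 100.", call. = FALSE)
  }
  local_seed_if(seed)
  k <- model$k
  xs <- matrix(rnorm(n_samples * k), n_samples, k)
  xs <- sweep(sweep(xs, 2, sqrt(prior$var), `*`), 2, prior$mean, `+`)
  encs <- lapply(split(trials, trials$subject_id), encode_trials,
                 model = model)
  log_marginals <- vapply(encs, function(enc) {
    .loglik_mc_cpp(xs, enc$new_block, enc$alpha_idx, enc$beta_idx,
                   enc$chose_high, enc$reward, q0)
  }, numeric(1))
  ibic_from_components(log_marginals, n_group_params = 2 * k,
                       n_obs = nrow(trials))
}
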