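test_result <- function(method, statistic, statistic_name, z, n, p,
                        r = NULL, ci = c(NA_real_, NA_real_)) {
  tibble::tibble(
    method = method,
    statistic = statistic,
    statistic_name = statistic_name,
    z = z,
    effect_size_r = r %||% (abs(z) / sqrt(n)),
    conf_low = ci[1],
    conf_high = ci[2],
    p_value = p,
    n = as.integer(n)
  )
}

# Normal-approximation Z for a rank statistic, with continuity correction
rank_z <- function(stat, mu, sigma2) {
  if (sigma2 <= 0) return(0)
  d <- stat - mu
  (d - sign(d) * 0.5) / sqrt(sigma2)
}

boot_ci_r <- function(r_fun, n_boot, seed, conf = 0.95) {
  local_seed_if(seed)
  rs <- vapply(seq_len(n_boot), function(i) r_fun(), numeric(1))
  rs <- rs[is.finite(rs)]
  if (length(rs) < 2) return(c(NA_real_, NA_real_))
  unname(quantile(rs, c((1 - conf) / 2, 1 - (1 - conf) / 2)))
}

signed_rank_core <- function(d) {
  d <- d[d != 0]
  m <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- table(r)
  mu <- m * (m + 1) / 4
  sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
  list(v = v, m = m, z = rank_z(v, mu, sigma2), has_ties = any(ties > 1))
}

#' Wilcoxon signed-rank test with effect size
#'
#' Two-sided paired test. The p-value uses the exact signed-rank
#' distribution when there are at most 25 non-zero differences and no ties
#' in their absolute values, and the continuity-corrected normal
#' approximation otherwise (with tie correction). The effect size is
#' \eqn{r = |Z|/\sqrt{n}} with `n` the number of pairs; its confidence
#' interval is bootstrapped over pairs.
#'
#' @param x Numeric vector: first measurement, or the paired differences
#'   if `y` is NULL.
#' @param y Optional second measurement, same length as `x`.
#' @param n_boot Bootstrap resamples for the CI on r (default 1000).
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `statistic` (V), `z`, `effect_size_r`,
#'   `conf_low`/`conf_high`, `p_value`, `n`.
#' @export
wilcoxon_signed_rank <- function(x, y = NULL, n_boot = 1000, seed = NULL) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) {
      stop("`x` and `y` must have the same length.", call. = FALSE)
    }
    x - y
  }
  d <- d[is.finite(d)]
  n <- length(d)
  if (n < 3) stop("need at least 3 pairs.", call. = FALSE)
  if (all(d == 0)) {
    stop("all differences are zero; the test is undefined.", call. = FALSE)
  }
  core <- signed_rank_core(d)
  p <- if (!core$has_ties && core$m <= 25) {
    min(1, 2 * min(psignrank(core$v, core$m),
                   1 - psignrank(core$v - 1, core$m)))
  } else {
    2 * pnorm(-abs(core$z))
  }
  r_of <- function(dd) {
    if (all(dd == 0)) return(NA_real_)
    abs(signed_rank_core(dd)$z) / sqrt(length(dd))
  }
  ci <- boot_ci_r(function() r_of(d[sample.int(n, replace = TRUE)]),
                  n_boot, seed)
  test_result("Wilcoxon signed-rank", core$v, "V", core$z, n, p, ci = ci)
}

rank_sum_core <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2  # Mann-Whitney U for x
  ties <- table(r)
  mu <- n1 * n2 / 2
  sigma2 <- n1 * n2 / 12 *
    ((n1 + n2 + 1) - sum(ties^3 - ties) / ((n1 + n2) * (n1 + n2 - 1)))
  list(w = w, z = rank_z(w, mu, sigma2), has_ties = any(ties > 1),
       n1 = n1, n2 = n2)
}

#' Wilcoxon rank-sum test with effect size
#'
#' Two-sided independent-samples test on the Mann-Whitney statistic.
#' Exact p when both groups are small and tie-free; otherwise the
#' continuity-corrected, tie-corrected normal approximation. Effect size
#' \eqn{r = |Z|/\sqrt{n_1 + n_2}}, with a bootstrap CI resampling within
#' groups.
#'
#' @param x,y Numeric vectors for the two groups.
#' @inheritParams wilcoxon_signed_rank
#' @return A one-row tibble as in [wilcoxon_signed_rank()] (`statistic`
#'   is W, the Mann-Whitney U for `x`).
#' @export
wilcoxon_rank_sum <- function(x, y, n_boot = 1000, seed = NULL) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    stop("need at least 3 observations per group.", call. = FALSE)
  }
  core <- rank_sum_core(x, y)
  n <- core$n1 + core$n2
  p <- if (!core$has_ties && core$n1 <= 25 && core$n2 <= 25) {
    min(1, 2 * min(pwilcox(core$w, core$n1, core$n2),
                   1 - pwilcox(core$w - 1, core$n1, core$n2)))
  } else {
    2 * pnorm(-abs(core$z))
  }
  r_of <- function(xx, yy) abs(rank_sum_core(xx, yy)$z) / sqrt(n)
  ci <- boot_ci_r(function() {
    r_of(x[sample.int(core$n1, replace = TRUE)],
         y[sample.int(core$n2, replace = TRUE)])
  }, n_boot, seed)
  test_result("Wilcoxon rank-sum", core$w, "W", core$z, n, p, ci = ci)
}

#' Spearman correlation with confidence interval
#'
#' Rank correlation on midranks (average ranks for ties). The p-value uses
#' the t approximation on `n - 2` degrees of freedom; the confidence
#' interval uses the Fisher z transform with variance `1.06 / (n - 3)`
#' (`ci_method = "fisher"`, default) or a seeded pairs bootstrap.
#'
#' @param x,y Numeric vectors of equal length (pairs with missing values
#'   are dropped).
#' @param conf Confidence level (default 0.95).
#' @param ci_method `"fisher"` or `"bootstrap"`.
#' @param n_boot Bootstrap resamples when `ci_method = "bootstrap"`.
#' @param seed Integer seed for the bootstrap.
#' @return A one-row tibble: `rho`, `conf_low`, `conf_high`, `p_value`, `n`.
#' @export
spearman_correlation <- function(x, y, conf = 0.95,
                                 ci_method = c("fisher", "bootstrap"),
                                 n_boot = 1000, seed = NULL) {
  ci_method <- match.arg(ci_method)
  ok <- complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 4) stop("need at least 4 complete pairs.", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant input vector; correlation undefined.", call. = FALSE)
  }
  rho <- cor(rank(x), rank(y))
  tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
  p <- 2 * pt(-abs(tstat), n - 2)
  if (ci_method == "fisher") {
    se <- sqrt(1.06 / (n - 3))
    zq <- qnorm(1 - (1 - conf) / 2)
    ci <- tanh(atanh(rho) + c(-1, 1) * zq * se)
  } else {
    ci <- boot_ci_r(function() {
      idx <- sample.int(n, replace = TRUE)
      if (length(unique(x[idx])) < 2 || length(unique(y[idx])) < 2) {
        return(NA_real_)
      }
      cor(rank(x[idx]), rank(y[idx]))
    }, n_boot, seed, conf = conf)
  }
  tibble::tibble(method = "Spearman", rho = rho,
                 conf_low = ci[1], conf_high = ci[2],
                 p_value = p, n = as.integer(n))
}

#' @describeIn spearman_correlation Partial Spearman correlation: Pearson
#'   correlation of the rank residuals of `x` and `y` after regressing
#'   each on the ranked `covariate` (p from the t approximation on
#'   `n - 3` degrees of freedom).
#' @param covariate Numeric vector partialled out of both `x` and `y`.
#' @export
partial_spearman <- function(x, y, covariate) {
  ok <- complete.cases(x, y, covariate)
  x <- x[ok]; y <- y[ok]; covariate <- covariate[ok]
  n <- length(x)
  if (n < 5) stop("need at least 5 complete triples.", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("constant input vector; correlation undefined.", call. = FALSE)
  }
  rz <- rank(covariate)
  res <- function(v) stats::residuals(stats::lm(rank(v) ~ rz))
  rho <- cor(res(x), res(y))
  df <- n - 3
  tstat <- rho * sqrt(df / max(1 - rho^2, .Machine$double.eps))
  tibble::tibble(method = "partial Spearman", rho = rho,
                 p_value = 2 * pt(-abs(tstat), df), n = as.integer(n))
}

#' Compare two independent correlations
#'
#' Fisher z-transforms each correlation and tests their difference:
#' \eqn{Z = (z_1 - z_2) / \sqrt{1/(n_1-3) + 1/(n_2-3)}}, two-sided.
#'
#' @param r1,r2 The two correlations (strictly inside (-1, 1)).
#' @param n1,n2 Their sample sizes (each > 3).
#' @return A one-row tibble: `z`, `p_value`.
#' @examples
#' compare_independent_correlations(0.21, 76, -0.33, 76) # Z about 3.3
#' @export
compare_independent_correlations <- function(r1, n1, r2, n2) {
  if (abs(r1) >= 1 || abs(r2) >= 1) {
    stop("correlations must lie strictly inside (-1, 1).", call. = FALSE)
  }
  if (n1 <= 3 || n2 <= 3) stop("need n > 3 in each sample.", call. = FALSE)
  z <- (atanh(r1) - atanh(r2)) / sqrt(1 / (n1 - 3) + 1 / (n2 - 3))
  tibble::tibble(method = "Fisher z difference", z = z,
                 p_value = 2 * pnorm(-abs(z)))
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' Step-up adjusted p-values (monotone, capped at 1), via
#' `stats::p.adjust(method = "BH")` after validating the inputs.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the input order.
#' @examples
#' fdr_adjust(c(0.005, 0.2, 0.5, 0.6, 0.8, 0.9)) # smallest becomes 0.03
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1].", call. = FALSE)
  }
  p.adjust(p, method = "BH")
}

#' Power of the two-sample t test
#'
#' Power of a two-sided independent-samples t test at effect size `d`
#' (Cohen), computed from the noncentral t distribution with
#' noncentrality \eqn{d \sqrt{n_1 n_2 / (n_1 + n_2)}}.
#'
#' @param n_per_group Size of the first group (and of the second unless
#'   `n2` is given).
#' @param d Standardised effect size (>= 0).
#' @param alpha Two-sided significance level (default 0.05).
#' @param n2 Optional size of the second group.
#' @return The power (scalar in `[0, 1]`).
#' @examples
#' power_two_sample_t(80, 0.5) # 0.88
#' @export
power_two_sample_t <- function(n_per_group, d, alpha = 0.05,
                               n2 = n_per_group) {
  if (n_per_group < 2 || n2 < 2) stop("need n >= 2 per group.", call. = FALSE)
  if (d < 0) stop("`d` must be non-negative.", call. = FALSE)
  if (alpha <= 0 || alpha >= 1) {
    stop("`alpha` must lie strictly inside (0, 1).", call. = FALSE)
  }
  ncp <- d * sqrt(n_per_group * n2 / (n_per_group + n2))
  df <- n_per_group + n2 - 2
  tc <- qt(1 - alpha / 2, df)
  pt(-tc, df, ncp) + 1 - pt(tc, df, ncp)
}
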