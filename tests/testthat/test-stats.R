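test_that("signed-rank p matches brute-force enumeration for n = 6", {
  d <- c(1.2, -0.4, 2.3, 0.8, -1.7, 3.1)
  # oracle: enumerate all 2^6 sign assignments of |d|
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  v_all <- signs %*% r
  p_exact <- mean(v_all <= min(v_obs, sum(r) - v_obs) |
                    v_all >= max(v_obs, sum(r) - v_obs))
  res <- wilcoxon_signed_rank(d, seed = 1)
  expect_equal(res$p_value, p_exact, tolerance = 1e-12)
  expect_equal(res$statistic, v_obs)
  expect_equal(res$effect_size_r, abs(res$z) / sqrt(6), tolerance = 1e-10)
})

test_that("signed-rank handles identity, errors and large-sample Z", {
  x <- c(5, 3, 8, 6, 2, 9, 4)
  res <- wilcoxon_signed_rank(x, x + rep(c(1e-9, -1e-9), length.out = 7),
                              seed = 1)
  expect_lt(abs(res$z), 1)           # statistic near the null centre
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "zero")
  expect_error(wilcoxon_signed_rank(1:2), "at least 3")
  set.seed(2)
  a <- rnorm(60)
  b <- rnorm(60) + 1
  res <- wilcoxon_signed_rank(a, b, seed = 3)
  ref <- wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-6)
  expect_true(res$conf_low <= res$effect_size_r,
              res$effect_size_r <= res$conf_high)
})

test_that("rank-sum test: separation, exactness and symmetry", {
  g1 <- c(1, 2, 3, 4)
  g2 <- c(10, 11, 12, 13)
  res <- wilcoxon_rank_sum(g1, g2, seed = 1)
  expect_equal(res$statistic, 0)       # complete separation
  expect_equal(res$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  ref <- wilcox.test(g1, g2, exact = TRUE)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
  # ties fall back to the corrected normal approximation
  set.seed(4)
  x <- sample(1:5, 30, TRUE)
  y <- sample(2:6, 35, TRUE)
  res2 <- wilcoxon_rank_sum(x, y, seed = 2)
  ref2 <- wilcox.test(x, y, exact = FALSE, correct = TRUE)
  expect_equal(res2$p_value, ref2$p.value, tolerance = 1e-6)
  expect_equal(res2$effect_size_r, abs(res2$z) / sqrt(65), tolerance = 1e-10)
})

test_that("rank statistics are invariant under monotone transforms", {
  set.seed(5)
  x <- rlnorm(20)
  y <- rlnorm(25)
  a <- wilcoxon_rank_sum(x, y, seed = 6)
  b <- wilcoxon_rank_sum(log(x), log(y), seed = 6)
  expect_equal(a$statistic, b$statistic)
  expect_equal(a$p_value, b$p_value)
})

test_that("spearman correlation: monotone data, ties oracle, CI and errors", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  # midrank oracle: Pearson on average ranks, hand-computed
  xt <- c(1, 2, 2, 4, 5, 6, 7, 7)
  yt <- c(2, 1, 4, 4, 6, 5, 8, 7)
  oracle <- cor(rank(xt), rank(yt))
  expect_equal(spearman_correlation(xt, yt)$rho, oracle, tolerance = 1e-12)
  res <- spearman_correlation(xt, yt)
  se <- sqrt(1.06 / (8 - 3))
  expect_equal(res$conf_low, tanh(atanh(oracle) - qnorm(0.975) * se),
               tolerance = 1e-10)
  expect_error(spearman_correlation(rep(1, 6), 1:6), "constant")
  expect_error(spearman_correlation(1:3, 3:1), "at least 4")
})

test_that("partial spearman approaches the simple rho for an irrelevant
           covariate and removes a shared driver", {
  set.seed(7)
  n <- 400
  x <- rnorm(n)
  y <- 0.6 * x + rnorm(n)
  z_indep <- rnorm(n)
  plain <- spearman_correlation(x, y)$rho
  partial <- partial_spearman(x, y, z_indep)$rho
  expect_equal(partial, plain, tolerance = 0.05)
  # x and y related only through z: partialling z kills the correlation
  z <- rnorm(n)
  x2 <- z + rnorm(n, sd = 0.5)
  y2 <- z + rnorm(n, sd = 0.5)
  expect_gt(spearman_correlation(x2, y2)$rho, 0.5)
  expect_lt(abs(partial_spearman(x2, y2, z)$rho), 0.15)
})

test_that("correlation difference Z test reproduces the reported contrast", {
  expect_equal(compare_independent_correlations(0.3, 50, 0.3, 50)$z, 0)
  res <- compare_independent_correlations(0.21, 76, -0.33, 76)
  expect_equal(res$z, 3.3, tolerance = 0.02)  # reported 3.28 (unrounded rs)
  flipped <- compare_independent_correlations(-0.33, 76, 0.21, 76)
  expect_equal(flipped$z, -res$z)
  expect_error(compare_independent_correlations(1, 10, 0.5, 10))
  expect_error(compare_independent_correlations(0.2, 3, 0.5, 10))
})

test_that("BH adjustment matches a hand-applied step-up rule", {
  p <- c(0.01, 0.02, 0.03, 0.04)
  # hand: sorted p * 4 / rank, cummin from the largest, capped at 1
  hand <- c(0.04, 0.04, 0.04, 0.04)
  expect_equal(fdr_adjust(p), hand)
  expect_equal(fdr_adjust(0.2), 0.2)                 # single p unchanged
  p6 <- c(0.005, 0.2, 0.3, 0.4, 0.5, 0.6)
  expect_equal(fdr_adjust(p6)[1], 0.03)              # 0.005 * 6 / 1
  expect_true(all(fdr_adjust(p6) >= p6))
  shuffled <- c(0.3, 0.005, 0.6, 0.2, 0.5, 0.4)
  expect_equal(fdr_adjust(shuffled)[2], 0.03)        # order-equivariant
  expect_error(fdr_adjust(c(0.5, 1.2)))
})

test_that("t-test power: null case, monotonicity, and reference values", {
  expect_equal(power_two_sample_t(80, 0.5, 0.05), 0.88, tolerance = 0.005)
  expect_equal(power_two_sample_t(40, 0, 0.05), 0.05, tolerance = 1e-10)
  ref <- power.t.test(n = 30, delta = 0.4, sd = 1, sig.level = 0.05)$power
  # power.t.test drops the opposite-tail rejection mass; we include it
  expect_equal(power_two_sample_t(30, 0.4), ref, tolerance = 1e-3)
  grid_n <- sapply(c(10, 20, 40, 80), power_two_sample_t, d = 0.5)
  expect_true(all(diff(grid_n) > 0))
  grid_d <- sapply(c(0.1, 0.3, 0.5, 0.8), function(d)
    power_two_sample_t(50, d))
  expect_true(all(diff(grid_d) > 0))
  expect_error(power_two_sample_t(50, 0.5, alpha = 1.5))
})
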