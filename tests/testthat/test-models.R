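test_that("model specs expose the documented parameter counts and maps", {
  ks <- c("1a1b" = 2L, "2a1b" = 3L, "3a1b" = 4L, "3a3b" = 6L)
  for (nm in names(ks)) {
    m <- model_spec(nm)
    expect_identical(m$k, unname(ks[nm]))
    expect_setequal(names(m$alpha_map), c("self", "other", "no_one"))
    expect_setequal(names(m$beta_map), c("self", "other", "no_one"))
  }
  m2 <- model_spec("2a1b")
  expect_identical(m2$alpha_map[["other"]], m2$alpha_map[["no_one"]])
  expect_false(m2$alpha_map[["self"]] == m2$alpha_map[["other"]])
  expect_error(model_spec("4a4b"))
})

test_that("delta-rule update matches direct evaluation", {
  u <- q_update(0.5, 1, 0.2)
  expect_equal(u$q, 0.6)
  expect_equal(u$delta, 0.5)
  expect_equal(q_update(0.7, 1, 0)$q, 0.7)     # zero learning rate
  expect_equal(q_update(0.7, 0, 0)$q, 0.7)
  u <- q_update(1, 1, 0.83)                     # zero prediction error
  expect_equal(u$q, 1)
  expect_equal(u$delta, 0)
  expect_error(q_update(0.5, 1, 1.2), "alpha")
  expect_error(q_update(0.5, 1, -0.1), "alpha")
})

test_that("q-values stay in [0,1] for binary rewards (property)", {
  set.seed(42)
  for (i in 1:200) {
    q <- runif(1)
    a <- runif(1)
    r <- rbinom(1, 1, 0.5)
    expect_true(dplyr::between(q_update(q, r, a)$q, 0, 1))
  }
})

test_that("softmax probabilities match direct evaluation and limits", {
  p <- choice_probabilities(c(0.6, 0.4), 0.1)
  expect_equal(p[1], 1 / (1 + exp(-2)), tolerance = 1e-12)
  expect_equal(sum(p), 1, tolerance = 1e-12)
  expect_equal(choice_probabilities(c(0.3, 0.3), 0.07), c(0.5, 0.5))
  expect_equal(choice_probabilities(c(0.9, 0.1), 1e9), c(0.5, 0.5),
               tolerance = 1e-6)
  expect_equal(choice_probabilities(c(0.9, 0.1), 1e-12)[1], 1)  # greedy limit
  expect_error(choice_probabilities(c(NA, 0.5), 0.1))
  expect_error(choice_probabilities(c(Inf, 0.5), 0.1))
})

test_that("link functions are the stated bijections", {
  expect_equal(link_to_native(0, "alpha"), 0.5)
  expect_equal(link_to_native(0, "beta"), 1)
  xs <- seq(-10, 10, length.out = 41)
  expect_equal(native_to_gaussian(link_to_native(xs, "alpha"), "alpha"), xs,
               tolerance = 1e-10)
  expect_equal(native_to_gaussian(link_to_native(xs, "beta"), "beta"), xs,
               tolerance = 1e-10)
  expect_error(native_to_gaussian(0, "alpha"))
  expect_error(native_to_gaussian(1, "alpha"))
  expect_error(native_to_gaussian(0, "beta"))
})

test_that("likelihood matches a step-by-step forward pass built from the
           exported primitives", {
  trials <- hand_block()
  alpha <- 0.2
  beta <- 0.1
  q <- c(high = 0, low = 0)   # matches the package default q0 = 0
  nll_manual <- 0
  p_manual <- numeric(3)
  for (i in 1:3) {
    p <- choice_probabilities(c(q["high"], q["low"]), beta)
    chosen <- trials$chosen_option[i]
    p_chosen <- unname(if (chosen == "high") p[1] else p[2])
    nll_manual <- nll_manual - log(p_chosen)
    p_manual[i] <- p_chosen
    q[chosen] <- q_update(q[[chosen]], trials$reward[i], alpha)$q
  }
  out <- negative_log_likelihood(trials, "3a1b", alpha = rep(alpha, 3),
                                 beta = beta)
  expect_equal(out$nll, nll_manual, tolerance = 1e-10)
  expect_equal(out$p_chosen, p_manual, tolerance = 1e-10)
})

test_that("single-trial likelihood is the symmetric coin flip", {
  tr <- hand_block()[1, ]
  out <- negative_log_likelihood(tr, "1a1b", alpha = 0.3, beta = 0.2)
  expect_equal(out$nll, -log(0.5), tolerance = 1e-12)
})

test_that("slot-equivalence: shared-parameter models agree on one condition", {
  sched <- generate_schedule(seed = 77)
  tr <- simulate_agent(sched, "1a1b", alpha = 0.35, beta = 0.12, seed = 78)
  self_only <- dplyr::filter(tr, recipient == "self")
  a <- negative_log_likelihood(self_only, "3a1b", alpha = rep(0.35, 3),
                               beta = 0.12)
  b <- negative_log_likelihood(self_only, "1a1b", alpha = 0.35, beta = 0.12)
  expect_equal(a$nll, b$nll, tolerance = 1e-12)
})

test_that("likelihood factorises over blocks (block order irrelevant)", {
  sched <- generate_schedule(seed = 5)
  tr <- simulate_agent(sched, "3a1b", alpha = c(0.2, 0.5, 0.8), beta = 0.15,
                       seed = 6)
  base <- negative_log_likelihood(tr, "3a1b", c(0.2, 0.5, 0.8), 0.15)$nll
  remap <- sample(9)
  shuffled <- dplyr::mutate(tr, block_index = remap[block_index])
  expect_equal(
    negative_log_likelihood(shuffled, "3a1b", c(0.2, 0.5, 0.8), 0.15)$nll,
    base, tolerance = 1e-10
  )
})

test_that("likelihood validates its inputs", {
  tr <- hand_block()
  expect_error(negative_log_likelihood(tr, "3a1b", c(0.2, 0.2), 0.1),
               "alpha")
  expect_error(negative_log_likelihood(tr, "3a1b", c(0.2, 0.2, 1.5), 0.1),
               "alpha")
  expect_error(negative_log_likelihood(tr, "3a1b", rep(0.2, 3), -1),
               "beta")
  bad <- dplyr::mutate(tr, recipient = c("self", "other", "self"))
  expect_error(negative_log_likelihood(bad, "3a1b", rep(0.2, 3), 0.1),
               "constant within a block")
})

test_that("nll is finite across extreme Gaussian-space parameters", {
  sched <- generate_schedule(seed = 9)
  tr <- simulate_agent(sched, "1a1b", alpha = 0.5, beta = 0.2, seed = 10)
  for (x in c(-20, -5, 0, 5, 20)) {
    out <- negative_log_likelihood(tr, "1a1b",
                                   alpha = link_to_native(x, "alpha"),
                                   beta = link_to_native(x, "beta"))
    expect_true(is.finite(out$nll))
  }
})
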