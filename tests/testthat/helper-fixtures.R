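# Shared fixtures, all built in code.

# A tiny hand-built block: known choices and rewards, self condition.
hand_block <- function() {
  tibble::tibble(
    subject_id = "s001",
    recipient = "self",
    block_index = 1L,
    trial_in_block = 0:2,
    chosen_option = c("high", "high", "low"),
    reward = c(1L, 0L, 0L)
  )
}

# Small simulated cohort cached per session (used by several fit tests).
small_cohort <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sched <- generate_schedule(seed = 401)
      pop <- sample_population(12, "3a1b", beta_bounds = c(0.01, 0.3),
                               seed = 402)
      cache <<- simulate_population(pop, sched, "3a1b", seed = 403)
    }
    cache
  }
})

# Flat prior for near-MLE fitting
flat_prior <- function(model) {
  model <- model_spec(model)
  group_prior(rep(0, model$k), rep(1e8, model$k), model)
}
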