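# Shared fixture builders for the test suite.

# two trial rates with exact mean m and exact SD s
two_trials <- function(m, s) c(m + s / sqrt(2), m - s / sqrt(2))

# trial-level tuning data on the standard nine-depth grid with exact
# per-depth means and SDs (two trials per depth)
tuning_fixture <- function(means, sds = rep(0, 9),
                           depths = seq(-2, 2, by = 0.5)) {
  stopifnot(length(means) == length(depths), length(sds) == length(depths))
  rate <- unlist(mapply(two_trials, means, sds, SIMPLIFY = FALSE))
  list(rate = rate, depth = rep(depths, each = 2L))
}

# exhaustive pair-counting ROC oracle (preferred group second)
roc_oracle <- function(a, b) {
  cmp <- outer(b, a, ">") + 0.5 * outer(b, a, "==")
  mean(cmp)
}

# a small default population/session/metrics bundle, memoized per test run
small_bundle <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      conditions <- build_condition_table()
      pop <- sample_population(population_spec(40, seed = 7))
      session <- simulate_session(pop, conditions, n_reps = 25, seed = 8)
      tuning <- simulate_tuning(pop, n_reps = 6, seed = 9)
      cache <<- list(conditions = conditions, pop = pop, session = session,
                     tuning = tuning)
    }
    cache
  }
})
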