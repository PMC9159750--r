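test_that("ROC area matches the pair-counting oracle and its symmetries", {
  expect_equal(roc_area(c(1, 3), c(2, 4))$area, 0.75)
  expect_equal(roc_area(1:5, 1:5)$area, 0.5)
  expect_equal(roc_area(1:5, 6:10)$area, 1.0)
  set.seed(41)
  for (i in 1:300) {
    a <- sample(0:6, sample(1:8, 1), replace = TRUE)
    b <- sample(0:6, sample(1:8, 1), replace = TRUE)
    r <- roc_area(a, b)
    expect_identical(r$area, roc_oracle(a, b))
    # complement under group swap
    expect_equal(roc_area(b, a)$area, 1 - r$area)
  }
  expect_error(roc_area(numeric(0), 1), "non-empty")
})

test_that("neurometric performance pools stationary trials and averages six levels", {
  set.seed(42)
  deltas <- standard_delta_set()
  n_rep <- 40
  delta <- rep(deltas, each = n_rep)
  dyn <- rep(c(TRUE, FALSE), length.out = length(delta))
  dyn[delta == 0] <- TRUE
  # condition-independent responses: NP near 0.5
  rate <- rnorm(length(delta), 20, 4)
  res <- neurometric_performance(rate, delta, dyn)
  expect_identical(length(res$roc_by_delta), 6L)
  expect_lt(abs(res$np - 0.5), 0.05)
  # engineered dynamic preference at every level: NP > 0.5 with all areas > 0.5
  rate2 <- rate + ifelse(dyn & delta != 0, 10, 0)
  res2 <- neurometric_performance(rate2, delta, dyn)
  expect_true(all(res2$roc_by_delta > 0.5))
  expect_gt(res2$np, 0.5)
  # swapping the group labels complements NP
  res3 <- neurometric_performance(rate2, delta, !dyn & delta != 0)
  expect_equal(res3$np, 1 - res2$np)
  keep <- delta != 1.53
  expect_error(neurometric_performance(rate[keep], delta[keep], dyn[keep],
                                       expected_deltas = deltas), "\\+1.53")
})

test_that("detection probability separates choices and flags eligibility", {
  # strictly higher rates on every chose-in-RF trial
  rate <- c(rnorm(10, 30, 1), rnorm(10, 10, 1))
  choice <- rep(c(TRUE, FALSE), each = 10)
  res <- detection_probability(rate, choice, seed = 1)
  expect_equal(res$dp, 1.0)
  expect_true(res$eligible)
  expect_lte(res$p_value, 0.05)
  # too few choices on one side: ineligible but still reported
  res2 <- detection_probability(c(rnorm(3, 30), rnorm(20, 10)),
                                rep(c(TRUE, FALSE), c(3, 20)), seed = 1)
  expect_false(res2$eligible)
  expect_true(is.finite(res2$dp))
  # choice-independent rates: DP near 0.5, permutation p well above floor
  set.seed(43)
  rate3 <- rnorm(80)
  choice3 <- rep(c(TRUE, FALSE), 40)
  res3 <- detection_probability(rate3, choice3, seed = 2)
  expect_lt(abs(res3$dp - 0.5), 0.2)
  expect_gt(res3$p_value, 0.05)
})

test_that("choice-sorted time course localizes an injected response step", {
  n_per <- 30
  base_rate <- rep(60, 4 * n_per)
  phase <- rep(c(0, 180), each = 2 * n_per)
  choice <- rep(c(TRUE, FALSE, TRUE, FALSE), each = n_per)
  stepg <- function(t) 1 + 0.8 * (t >= 0.4)
  counts <- matrix(NA_real_, length(base_rate), 210)
  for (i in seq_along(base_rate)) {
    g <- if (choice[i]) stepg else NULL
    counts[i, ] <- simulate_rasters(base_rate[i], gain = g, seed = 1000 + i)
  }
  attr(counts, "time_s") <- (seq_len(210) - 0.5) * 0.01
  res <- choice_sorted_timecourse(counts, 0.01, phase, choice)
  for (ph in c("phase_0", "phase_180")) {
    expect_false(res[[ph]]$omitted)
    first_sig <- res$time_s[which(res[[ph]]$significant)[1]]
    expect_gte(first_sig, 0.4 - 0.08)   # centered smoothing can lead the step
    expect_lte(first_sig, 0.55 + 0.15)
    # difference trace is near zero before the step
    pre <- res$time_s < 0.25
    expect_lt(max(abs(res[[ph]]$difference[pre])), 0.5)
  }
  # identical rasters in both choice groups: flat zero difference, no hits
  same <- counts
  same[!choice, ] <- same[choice, ]
  res0 <- choice_sorted_timecourse(same, 0.01, phase, choice)
  expect_equal(res0$phase_0$difference, rep(0, 210))
  expect_false(any(res0$phase_0$significant))
  # undersampled phase-by-choice cells are omitted and flagged
  res1 <- choice_sorted_timecourse(counts[c(1, 61:120), , drop = FALSE], 0.01,
                                   phase[c(1, 61:120)], choice[c(1, 61:120)])
  expect_true(res1$phase_0$omitted)
})

test_that("detection probability and neurometric performance use disjoint trials", {
  b <- small_bundle()
  tr <- b$session$trials
  amb <- tr$delta_depth_deg == 0
  # DP input set and NP input set cannot overlap by construction
  expect_identical(intersect(which(amb), which(tr$delta_depth_deg != 0)),
                   integer(0))
  m <- neuron_metrics(b$session, b$tuning)
  # with choice coupling on, choice-predictive activity tracks selectivity
  el <- m$dp_eligible
  ct <- suppressWarnings(stats::cor.test(m$dp[el], m$np[el],
                                         method = "spearman"))
  expect_gt(ct$estimate, 0)
  expect_lt(ct$p.value, 0.05)
})
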