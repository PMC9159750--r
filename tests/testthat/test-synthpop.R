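test_that("population sampling is seed-deterministic with the requested mixture", {
  spec <- population_spec(1000, fraction_opposite = 0.5, near_bias_mp = 0.75,
                          seed = 3)
  pop1 <- sample_population(spec)
  pop2 <- sample_population(spec)
  expect_identical(pop1, pop2)
  frac_opp <- mean(pop1$congruency == "opposite")
  expect_gt(frac_opp, 0.45)
  expect_lt(frac_opp, 0.55)
  expect_gt(mean(pop1$mp_pref < 0), 0.70)
  # congruency encodes the sign relation of the two preferred depths
  expect_identical(pop1$congruency == "opposite",
                   sign(pop1$bd_pref) != sign(pop1$mp_pref))
  all_cong <- sample_population(population_spec(50, fraction_opposite = 0,
                                                seed = 4))
  expect_true(all(sign(all_cong$bd_pref) == sign(all_cong$mp_pref)))
  expect_error(sample_population(population_spec(1)), "at least 2")
})

test_that("tuning mean is a baseline-anchored symmetric bump", {
  n <- sample_population(population_spec(5, seed = 1))[1, ]
  expect_equal(tuning_mean(n, "BD", n$bd_pref), n$baseline + n$bd_gain)
  d <- seq(0, 1, by = 0.1)
  lo <- pmax(-2, n$mp_pref - d)
  hi <- pmin(2, n$mp_pref + d)
  keep <- (n$mp_pref - d) >= -2 & (n$mp_pref + d) <= 2
  expect_equal(tuning_mean(n, "MP", lo[keep]), tuning_mean(n, "MP", hi[keep]))
  flat <- n
  flat$bd_gain <- 0
  expect_equal(tuning_mean(flat, "BD", c(-2, 0, 2)), rep(flat$baseline, 3))
  expect_error(tuning_mean(n, "BD", 2.5), "within")
})

test_that("detection mean reduces to the stationary response at zero conflict and
           rewards cue conflict for opposite cells", {
  pop <- sample_population(population_spec(60, seed = 5))
  ct <- build_condition_table()
  dyn <- ct[ct$kind == "dynamic", ]
  sta <- ct[ct$kind == "stationary", ]
  for (i in c(1, 17, 40)) {
    n <- pop[i, ]
    # zero-conflict dynamic equals a stationary object at the pedestal
    expect_equal(detection_mean(n, -0.45, -0.45),
                 detection_mean(n, standard_pedestal(), standard_pedestal()))
    expect_true(all(detection_mean(n, ct$d_bd_deg, ct$d_mp_deg) >= 0))
  }
  # an opposite cell with near MP / moderate far BD preference responds more
  # to its best cue-conflict stimulus than to any stationary depth
  opp <- pop[1, ]
  opp$mp_pref <- -1.2; opp$bd_pref <- 0.3
  opp$mp_gain <- 20; opp$bd_gain <- 40
  best_dyn <- max(detection_mean(opp, dyn$d_bd_deg, dyn$d_mp_deg))
  best_sta <- max(detection_mean(opp, sta$d_bd_deg, sta$d_mp_deg))
  expect_gt(best_dyn, best_sta)
})

test_that("simulated sessions are deterministic and honor the decision model", {
  ct <- build_condition_table()
  pop <- sample_population(population_spec(8, seed = 2))
  s1 <- simulate_session(pop, ct, n_reps = 10, seed = 42)
  s2 <- simulate_session(pop, ct, n_reps = 10, seed = 42)
  expect_identical(s1$trials, s2$trials)
  expect_identical(s1$rates, s2$rates)
  s3 <- simulate_session(pop, ct, n_reps = 10, seed = 43)
  expect_false(identical(s1$trials$choice_in_rf, s3$trials$choice_in_rf))

  # near-infinite sensitivity, no lapse: perfect on all nonzero conflicts
  sharp <- simulate_session(pop, ct, n_reps = 30,
                            behavior = behavior_spec(sensitivity = 1e6,
                                                     lapse = 0,
                                                     choice_coupling = 0),
                            seed = 44)
  nz <- sharp$trials$delta_depth_deg != 0
  expect_true(all(sharp$trials$correct[nz]))

  # zero sensitivity: chance at every level (pooled binomial check)
  flat <- simulate_session(pop, ct, n_reps = 60,
                           behavior = behavior_spec(sensitivity = 0, lapse = 0,
                                                    choice_coupling = 0,
                                                    neural_coupling = 0),
                           seed = 45)
  pc <- mean(flat$trials$correct)
  n <- nrow(flat$trials)
  expect_lt(abs(pc - 0.5), 3 * sqrt(0.25 / n))

  # accuracy at zero conflict is at chance under the default observer
  dflt <- simulate_session(pop, ct, n_reps = 120, seed = 46)
  amb <- dflt$trials$delta_depth_deg == 0
  ci <- stats::binom.test(sum(dflt$trials$correct[amb]), sum(amb))$conf.int
  expect_true(ci[1] < 0.5 && 0.5 < ci[2])
})

test_that("simulated rasters integrate to the requested rates", {
  counts <- simulate_rasters(rep(80, 200), duration_s = 2, bin_s = 0.01,
                             seed = 1)
  expect_identical(dim(counts), c(200L, 200L))
  rate_hat <- mean(rowSums(counts)) / 2
  expect_lt(abs(rate_hat - 80), 3 * sqrt(80 / (2 * 200)))
  # time-varying gain shows up in the expected window
  stepg <- function(t) 1 + (t >= 1)
  counts2 <- simulate_rasters(rep(50, 300), duration_s = 2, bin_s = 0.01,
                              gain = stepg, seed = 2)
  tc <- attr(counts2, "time_s")
  expect_gt(mean(counts2[, tc > 1]), 1.5 * mean(counts2[, tc < 1]))
})
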