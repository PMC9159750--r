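test_that("depth-sign index matches hand-computed values and bounds", {
  # far depths at 20, near at 10, every per-depth SD 5: each pair contributes
  # (20 - 10) / (10 + 5), so the index is 2/3
  fx <- tuning_fixture(means = c(10, 10, 10, 10, 15, 20, 20, 20, 20),
                       sds = rep(5, 9))
  res <- compute_dsdi(fx$rate, fx$depth, seed = NULL)
  expect_equal(res$dsdi, 2 / 3)
  # symmetric curve: index 0
  sym <- tuning_fixture(means = c(5, 9, 14, 9, 2, 9, 14, 9, 5),
                        sds = rep(2, 9))
  expect_equal(compute_dsdi(sym$rate, sym$depth, seed = NULL)$dsdi, 0)
  # |DSDI| < 1 whenever any dispersion is present
  set.seed(31)
  for (i in 1:50) {
    fx <- tuning_fixture(means = runif(9, 0, 60), sds = runif(9, 0.5, 8))
    d <- compute_dsdi(fx$rate, fx$depth, seed = NULL)$dsdi
    expect_lt(abs(d), 1)
  }
  # degenerate pairs (equal responses, zero SD) contribute zero evidence
  flat <- tuning_fixture(means = rep(12, 9), sds = rep(0, 9))
  expect_identical(compute_dsdi(flat$rate, flat$depth, seed = NULL)$dsdi, 0)
  expect_error(compute_dsdi(fx$rate[1:10], fx$depth[1:10]), "symmetric")
})

test_that("depth-sign index is shift-invariant and negates under axis reversal", {
  set.seed(32)
  for (i in 1:25) {
    fx <- tuning_fixture(means = runif(9, 5, 50), sds = runif(9, 1, 6))
    d0 <- compute_dsdi(fx$rate, fx$depth, seed = NULL)$dsdi
    d_shift <- compute_dsdi(fx$rate + 37.5, fx$depth, seed = NULL)$dsdi
    d_rev <- compute_dsdi(fx$rate, -fx$depth, seed = NULL)$dsdi
    expect_equal(d_shift, d0)
    expect_equal(d_rev, -d0)
  }
})

test_that("conflict-tuning index matches hand computation and is antisymmetric", {
  deltas <- c(-1.53, -0.57, -0.21, 0.21, 0.57, 1.53)
  # positive side 12, negative side 8, SDs 2: (12-8)/(4+2) = 2/3
  rate <- unlist(lapply(deltas, function(d) two_trials(ifelse(d > 0, 12, 8), 2)))
  dd <- rep(deltas, each = 2)
  expect_equal(compute_dsdi_dyn(rate, dd, seed = NULL)$dsdi, 2 / 3)
  # sign-independent responses: 0
  rate_flat <- unlist(lapply(deltas, function(d) two_trials(10, 2)))
  expect_equal(compute_dsdi_dyn(rate_flat, dd, seed = NULL)$dsdi, 0)
  # zero-conflict trials are ignored
  expect_equal(compute_dsdi_dyn(c(rate, 1000, 1000), c(dd, 0, 0),
                                seed = NULL)$dsdi, 2 / 3)
  # reflecting responses about the conflict axis negates the index
  rate_neg <- unlist(lapply(deltas, function(d) two_trials(ifelse(d > 0, 8, 12), 2)))
  expect_equal(compute_dsdi_dyn(rate_neg, dd, seed = NULL)$dsdi, -2 / 3)
})

test_that("permutation test hits its floor for strong tuning and respects the sign rule", {
  strong <- tuning_fixture(means = c(50, 45, 40, 35, 25, 15, 10, 8, 5),
                           sds = rep(1, 9))
  res <- compute_dsdi(strong$rate, strong$depth, n_perm = 1000, seed = 2)
  expect_lt(res$dsdi, 0) # near-preferring
  expect_lte(res$p_value, 1 / 1000)
  # positive-index neuron: same floor on the other tail
  res2 <- compute_dsdi(rev(strong$rate), strong$depth, n_perm = 1000, seed = 2)
  expect_gt(res2$dsdi, 0)
  expect_lte(res2$p_value, 1 / 1000)
  expect_warning(permutation_test_dsdi(strong$rate, strong$depth, n_perm = 50),
                 "coarse")
})

test_that("congruency classification follows the correlation of depth means", {
  fx <- tuning_fixture(means = c(40, 35, 28, 20, 14, 10, 8, 7, 6),
                       sds = rep(2, 9))
  same <- compute_congruency(fx$rate, fx$depth, fx$rate, fx$depth)
  expect_equal(same$r_mp_bd, 1)
  expect_identical(same$class, "congruent")
  expect_equal(same$delta_dsdi, 0)
  # negating the curve about its mean gives perfect anticorrelation
  bd_means <- c(40, 35, 28, 20, 14, 10, 8, 7, 6)
  mir <- tuning_fixture(means = 2 * mean(bd_means) - bd_means,
                        sds = rep(2, 9))
  opp <- compute_congruency(fx$rate, fx$depth, mir$rate, mir$depth)
  expect_equal(opp$r_mp_bd, -1)
  expect_identical(opp$class, "opposite")
  flat <- tuning_fixture(means = rep(10, 9), sds = rep(1, 9))
  expect_error(compute_congruency(fx$rate, fx$depth, flat$rate, flat$depth),
               "zero variance")
})

test_that("peak response ratio compares condition-mean maxima", {
  rate <- c(10, 14, 30, 34, 20, 24) # condition means 12, 32, 22
  cond <- rep(c("d1", "d2", "s1"), each = 2)
  kind <- rep(c("dynamic", "dynamic", "stationary"), each = 2)
  expect_equal(peak_response_ratio(rate, cond, kind), 32 / 22)
  # identical dynamic and stationary response sets: ratio 1
  expect_equal(peak_response_ratio(c(5, 7, 5, 7), c("a", "a", "b", "b"),
                                   c("dynamic", "dynamic", "stationary",
                                     "stationary")), 1)
})

test_that("population-level congruency structure emerges on default synthetic data", {
  b <- small_bundle()
  m <- neuron_metrics(b$session, b$tuning)
  # conflict preference tracks the difference of the cue indices
  ct1 <- suppressWarnings(
    stats::cor.test(m$dsdi_dyn, m$delta_dsdi, method = "spearman"))
  expect_gt(ct1$estimate, 0)
  expect_lt(ct1$p.value, 0.05)
  # opposite cells are preferentially driven by dynamic objects
  opp <- b$pop$congruency == "opposite"
  wt <- stats::wilcox.test(m$peak_ratio[opp], m$peak_ratio[!opp],
                           alternative = "greater")
  expect_lt(wt$p.value, 0.05)
})
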