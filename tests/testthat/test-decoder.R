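# helper: hand-built moments object over the standard 16 conditions
make_moments <- function(mu, sigma, np) {
  ct <- build_condition_table()
  structure(list(mu = mu, sigma = sigma, np = np, conditions = ct,
                 neuron_id = sprintf("n%02d", seq_len(nrow(mu)))),
            class = "population_moments")
}

test_that("noise-correlation model matches the printed formula and is a valid root", {
  nz <- noise_correlation_matrix(c(0.5, 0.5, 0.78, 0.23))
  expect_equal(nz$R[1, 2], 0.55)
  expect_equal(nz$R[3, 4], -0.055)
  expect_equal(diag(nz$R), rep(1, 4))
  expect_equal(nz$Q %*% nz$Q, nz$R, tolerance = 1e-8)
  # identical NP values: uniform 0.55 off-diagonal, already PSD
  nz2 <- noise_correlation_matrix(rep(0.7, 12))
  expect_equal(nz2$R, 0.55 + 0.45 * diag(12))
  expect_false(nz2$psd_repaired)
  # the model is positive semidefinite for any NP set in [0, 1]: the
  # absolute-difference kernel is conditionally negative definite, so the
  # smallest eigenvalue is bounded below by the 0.45 diagonal excess and no
  # repair is ever needed
  set.seed(99)
  for (i in 1:10) {
    nz3 <- noise_correlation_matrix(runif(sample(5:40, 1)))
    expect_false(nz3$psd_repaired)
    expect_gte(min(eigen(nz3$R, symmetric = TRUE,
                         only.values = TRUE)$values), 0.45 - 1e-9)
    expect_equal(nz3$Q %*% nz3$Q, nz3$R, tolerance = 1e-8)
  }
  expect_error(noise_correlation_matrix(0.5), "at least 2")
  expect_error(noise_correlation_matrix(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("pseudo-population sampling reproduces the requested moments", {
  set.seed(51)
  n_neu <- 12
  mu <- matrix(runif(n_neu * 16, 10, 60), n_neu)
  sig <- matrix(runif(n_neu * 16, 3, 8), n_neu)
  np <- runif(n_neu, 0.2, 0.8)
  mom <- make_moments(mu, sig, np)
  # zero dispersion: responses equal the condition means exactly
  sim0 <- simulate_population_trials(make_moments(mu, 0 * sig, np), NULL,
                                     200, seed = 1)
  expect_equal(sim0$responses, t(mu[, sim0$cond_idx]),
               ignore_attr = TRUE)
  # independent mode: empirical means within Monte-Carlo tolerance
  sim <- simulate_population_trials(mom, NULL, 30000, seed = 2)
  for (cond in c(1, 8, 16)) {
    idx <- sim$cond_idx == cond
    emp <- colMeans(sim$responses[idx, ])
    expect_true(all(abs(emp - mu[, cond]) < 4 * sig[, cond] / sqrt(sum(idx))))
  }
  # correlated mode: empirical noise correlations approach the model
  # (homogeneous SDs so correlations transfer exactly)
  nz <- noise_correlation_matrix(np)
  simc <- simulate_population_trials(make_moments(mu, 0 * sig + 5, np), nz,
                                     40000, seed = 3)
  resid <- simc$responses - t(mu[, simc$cond_idx])
  emp_r <- stats::cor(resid)
  expect_lt(max(abs(emp_r - nz$R)), 0.03)
})

test_that("linear decoder separates separable classes and guesses on none", {
  set.seed(52)
  n_neu <- 10
  sig <- matrix(5, n_neu, 16)
  np <- runif(n_neu, 0.3, 0.7)
  ct <- build_condition_table()
  # identical moments everywhere: chance performance
  mu_flat <- matrix(30, n_neu, 16)
  sim <- simulate_population_trials(make_moments(mu_flat, sig, np), NULL,
                                    20000, seed = 4)
  res <- train_linear_decoder(sim, seed = 5)
  # an uninformative decoder cannot beat majority guessing (9 of 15
  # non-ambiguous conditions are stationary) and detects every conflict
  # level at the same rate
  expect_lt(res$accuracy, 0.63)
  hits <- res$accuracy_by_delta$accuracy
  expect_lt(max(abs(hits - mean(hits))), 0.06)
  # widely separated class means: near-perfect performance
  mu_sep <- mu_flat
  mu_sep[, ct$kind == "dynamic" & ct$delta_depth_deg != 0] <- 90
  sim2 <- simulate_population_trials(make_moments(mu_sep, sig, np), NULL,
                                     20000, seed = 6)
  res2 <- train_linear_decoder(sim2, seed = 7)
  expect_gt(res2$accuracy, 0.99)
  # ambiguous trials never enter training or the accuracy table
  expect_false(0 %in% res2$accuracy_by_delta$delta_depth_deg)
  expect_identical(res2$n_train + res2$n_test, 20000L)
  expect_gt(length(res2$ambiguous$pred_dyn), 0L)
})

test_that("pooled-covariance discriminant agrees with the reference LDA", {
  set.seed(53)
  n <- 400
  m0 <- c(0, 0, 0, 0)
  m1 <- c(1, 0.5, -0.5, 0.2)
  x0 <- matrix(rnorm(4 * n), n, 4) + rep(m0, each = n)
  x1 <- matrix(rnorm(4 * n), n, 4) + rep(m1, each = n)
  fit <- mtobjmotion:::.fisher_lda(x0, x1)
  ref <- MASS::lda(rbind(x0, x1), grouping = rep(c(0, 1), each = n))
  xt <- matrix(rnorm(4 * 500), 500, 4) + rep(m1 / 2, each = 500)
  mine <- as.integer(drop(xt %*% fit$w) - fit$threshold > 0)
  theirs <- as.integer(predict(ref, xt)$class) - 1L
  expect_gte(mean(mine == theirs), 0.99)
})

test_that("predicted detection probability reflects readout weights and noise mode", {
  b <- small_bundle()
  mom <- population_moments(b$session)
  nz <- noise_correlation_matrix(mom$np)
  dc <- decode_population(mom, nz, n_samples = 12000, n_sims = 4, seed = 8)
  di <- decode_population(mom, NULL, n_samples = 12000, n_sims = 4, seed = 8)
  # correlated noise strengthens the association of predicted DP with
  # selectivity
  expect_gt(stats::cor(dc$dp_pred$dp_pred, mom$np, method = "spearman"),
            stats::cor(di$dp_pred$dp_pred, mom$np, method = "spearman"))
  # under independent noise the sign of DP_pred - 0.5 follows the weight sign
  # for confidently non-zero weights
  w <- di$weights
  strong <- abs(w) > stats::quantile(abs(w), 0.5)
  agree <- sign(di$dp_pred$dp_pred - 0.5) == sign(w)
  expect_gte(mean(agree[strong]), 0.8)
})

test_that("tercile split uses printed subgroup sizes and subgroup decoding runs", {
  expect_identical(as.integer(table(tercile_split(rnorm(97)))), c(33L, 32L, 32L))
  expect_identical(as.integer(table(tercile_split(rnorm(9)))), c(3L, 3L, 3L))
  b <- small_bundle()
  mom <- population_moments(b$session)
  m <- neuron_metrics(b$session, b$tuning)
  sg <- subgroup_decoding(mom, m$peak_ratio, n_sims = 5, n_samples = 3000,
                          seed = 9)
  expect_named(sg, c("lowest", "middle", "highest", "mixed"))
  for (g in sg) {
    expect_true(g$accuracy$mean > 0.5 && g$accuracy$mean <= 1)
    expect_identical(length(g$accuracy$sims), 5L)
  }
  # mixed subgroup redraws neurons, so most neurons appear in some simulation
  expect_gt(sum(sg$mixed$dp_pred$n_sims > 0), nrow(mom$mu) / 2)
  expect_error(subgroup_decoding(mom, m$peak_ratio[-1]), "one value per neuron")
})
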