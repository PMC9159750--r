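# Pseudo-population decoding: the NP-structured noise-correlation model, the
# mean+Q*noise*SD trial simulator, a pooled-covariance linear-discriminant
# readout, predicted detection probabilities from the decoder's choices, and
# subgroup (tercile) decoding.

#' Noise-correlation model from neurometric performance values
#'
#' Off-diagonal correlations follow `r_ij = 1.1 * (0.5 - |NP_i - NP_j|)`, so
#' pairs of neurons with similar NP have stronger correlated noise. If the
#' resulting matrix is not positive semidefinite it is repaired by clipping
#' negative eigenvalues to zero, reconstructing, and rescaling to unit
#' diagonal. `Q` is the symmetric (principal) matrix square root of the
#' (repaired) correlation matrix.
#'
#' @param np Neurometric performance values in \[0, 1\], length >= 2.
#' @return List with `R` (correlation matrix), `Q` (its symmetric square
#'   root), and `psd_repaired` flag.
#' @export
noise_correlation_matrix <- function(np) {
  if (length(np) < 2L) stop("need at least 2 neurons")
  if (any(np < 0 | np > 1)) stop("`np` values must lie in [0, 1]")
  R <- 1.1 * (0.5 - abs(outer(np, np, "-")))
  diag(R) <- 1
  eg <- eigen(R, symmetric = TRUE)
  repaired <- FALSE
  if (min(eg$values) < -1e-10) {
    repaired <- TRUE
    vals <- pmax(eg$values, 0)
    R <- eg$vectors %*% (vals * t(eg$vectors))
    d <- sqrt(diag(R))
    R <- R / outer(d, d)
    diag(R) <- 1
    eg <- eigen(R, symmetric = TRUE)
  }
  Q <- eg$vectors %*% (sqrt(pmax(eg$values, 0)) * t(eg$vectors))
  list(R = R, Q = Q, psd_repaired = repaired)
}

#' Per-condition response moments of a population
#'
#' Mean and SD of each neuron's firing rate in every in-RF condition of a
#' (recorded or simulated) session, together with each neuron's neurometric
#' performance. Only neurons observed in all conditions with at least
#' `min_reps` trials each are included (the decoding-eligibility rule).
#'
#' @param session An `"mt_session"` from [simulate_session()], or a list with
#'   `trials`, `rates`, `conditions` of the same shape.
#' @param min_reps Minimum trials per condition (default 2, for the SD).
#' @return List of class `"population_moments"` with `mu` and `sigma`
#'   (neurons x conditions), `np` (per neuron), `conditions` (the condition
#'   table rows, matched to columns), and `neuron_id`.
#' @export
population_moments <- function(session, min_reps = 2L) {
  trials <- session$trials
  rates <- session$rates
  conditions <- session$conditions
  cond_idx <- match(trials$condition_id, conditions$condition_id)
  if (anyNA(cond_idx)) stop("trials reference unknown condition ids")
  counts <- tabulate(cond_idx, nbins = nrow(conditions))
  if (any(counts < min_reps)) {
    stop(sprintf("conditions with insufficient trials: %s",
                 paste(conditions$condition_id[counts < min_reps],
                       collapse = ", ")))
  }
  n_neu <- ncol(rates)
  mu <- matrix(NA_real_, n_neu, nrow(conditions),
               dimnames = list(colnames(rates), conditions$condition_id))
  sig <- mu
  for (c in seq_len(nrow(conditions))) {
    block <- rates[cond_idx == c, , drop = FALSE]
    mu[, c] <- colMeans(block)
    sig[, c] <- col_sds(block)
  }
  np <- vapply(seq_len(n_neu), function(i) {
    neurometric_performance(rates[, i], trials$delta_depth_deg,
                            trials$dynamic_in_rf)$np
  }, numeric(1))
  structure(list(mu = mu, sigma = sig, np = np,
                 conditions = conditions, neuron_id = colnames(rates)),
            class = "population_moments")
}

#' Simulate pseudo-population trials from response moments
#'
#' Each simulated trial draws one of the in-RF conditions uniformly with
#' replacement; the population response is `mu(cond) + Q %*% r_rand * sigma(cond)`
#' with `r_rand` i.i.d. standard normal (`Q` the noise-model square root, or
#' the identity for independent noise). Responses are not truncated.
#'
#' @param moments A [population_moments()].
#' @param noise A [noise_correlation_matrix()] result, or `NULL` for
#'   independent noise.
#' @param n_samples Number of simulated trials (>= 1).
#' @param seed Integer seed.
#' @return List with `responses` (trials x neurons), `cond_idx` (condition row
#'   per trial), and the `conditions` table.
#' @export
simulate_population_trials <- function(moments, noise = NULL, n_samples,
                                       seed = 1L) {
  stopifnot(inherits(moments, "population_moments"))
  if (n_samples < 1) stop("`n_samples` must be >= 1")
  n_cond <- ncol(moments$mu)
  n_neu <- nrow(moments$mu)
  with_seed(seed, {
    cond_idx <- sample_int(n_cond, n_samples, replace = TRUE)
    e <- matrix(stats::rnorm(n_neu * n_samples), n_neu)
    if (!is.null(noise)) e <- noise$Q %*% e
    resp <- t(moments$mu[, cond_idx, drop = FALSE] +
                e * moments$sigma[, cond_idx, drop = FALSE])
    colnames(resp) <- moments$neuron_id
    list(responses = resp, cond_idx = cond_idx,
         conditions = moments$conditions)
  })
}

# two-class linear discriminant with pooled covariance (pseudo-inverse when
# singular); returns weights w and threshold c with empirical-prior offset,
# classifying to class 1 when w'x - c > 0
.fisher_lda <- function(x0, x1) {
  m0 <- colMeans(x0)
  m1 <- colMeans(x1)
  n0 <- nrow(x0); n1 <- nrow(x1)
  s_pooled <- ((n0 - 1) * stats::cov(x0) + (n1 - 1) * stats::cov(x1)) /
    (n0 + n1 - 2)
  s_inv <- tryCatch(solve(s_pooled), error = function(e) MASS::ginv(s_pooled))
  w <- drop(s_inv %*% (m1 - m0))
  c0 <- sum(w * (m1 + m0)) / 2 - log(n1 / n0)
  list(w = w, threshold = c0)
}

#' Train and evaluate a linear decoder on pseudo-population trials
#'
#' Trials are split into training (`split`) and test sets. A pooled-covariance
#' linear discriminant is trained to classify dynamic-in-RF versus
#' stationary-in-RF responses; ambiguous (zero-conflict) trials are excluded
#' from training but retained in the test set so the decoder's choices on them
#' can be scored. Ties at the decision boundary are broken by a seeded coin
#' flip.
#'
#' @param sim Output of [simulate_population_trials()].
#' @param split Training fraction (default 0.9).
#' @param seed Integer seed (split and tie-breaks).
#' @return List of class `"decode_result"` with `weights`, `threshold`,
#'   `accuracy` (overall test proportion correct, ambiguous excluded),
#'   `accuracy_by_delta` (data frame), `ambiguous` (test-set responses,
#'   decoder choices), and `n_train`, `n_test`.
#' @export
train_linear_decoder <- function(sim, split = 0.9, seed = 1L) {
  conds <- sim$conditions
  is_dyn <- conds$kind == "dynamic"
  is_ambig <- is_dyn & conds$delta_depth_deg == 0
  lab_dyn <- is_dyn[sim$cond_idx] & !is_ambig[sim$cond_idx]
  lab_sta <- !is_dyn[sim$cond_idx]
  ambig <- is_ambig[sim$cond_idx]
  n <- nrow(sim$responses)
  with_seed(seed, {
    train <- rep(FALSE, n)
    train[sample_int(n, round(split * n))] <- TRUE
    tr_dyn <- train & lab_dyn
    tr_sta <- train & lab_sta
    if (sum(tr_dyn) == 0L || sum(tr_sta) == 0L) {
      stop("a class has no training trials")
    }
    fit <- .fisher_lda(sim$responses[tr_sta, , drop = FALSE],
                       sim$responses[tr_dyn, , drop = FALSE])
    score <- drop(sim$responses %*% fit$w) - fit$threshold
    tie <- score == 0
    if (any(tie)) score[tie] <- ifelse(stats::runif(sum(tie)) < 0.5, 1, -1) * 1e-12
    pred_dyn <- score > 0

    test <- !train
    correct <- (pred_dyn & lab_dyn) | (!pred_dyn & lab_sta)
    acc <- mean(correct[test & !ambig])
    deltas <- conds$delta_depth_deg[sim$cond_idx]
    deltas[lab_sta] <- NA # stationary trials have no conflict level
    lv <- sort(unique(deltas[test & lab_dyn]))
    abd <- data.frame(
      delta_depth_deg = lv,
      accuracy = vapply(lv, function(d) {
        mean(pred_dyn[test & lab_dyn & deltas == d])
      }, numeric(1)),
      n = vapply(lv, function(d) sum(test & lab_dyn & deltas == d), integer(1))
    )
    structure(
      list(weights = fit$w, threshold = fit$threshold, accuracy = acc,
           accuracy_by_delta = abd,
           ambiguous = list(responses = sim$responses[test & ambig, , drop = FALSE],
                            pred_dyn = pred_dyn[test & ambig]),
           n_train = sum(train), n_test = sum(test)),
      class = "decode_result"
    )
  })
}

# per-neuron predicted DP from one decode: ambiguous test trials sorted by
# the decoder's choice, dynamic-predicted group preferred
.dp_pred_once <- function(result) {
  amb <- result$ambiguous
  if (length(amb$pred_dyn) == 0L) stop("no ambiguous trials in the test set")
  if (all(amb$pred_dyn) || !any(amb$pred_dyn)) {
    return(rep(NA_real_, ncol(amb$responses)))
  }
  vapply(seq_len(ncol(amb$responses)), function(i) {
    .roc_area_num(amb$responses[!amb$pred_dyn, i],
                  amb$responses[amb$pred_dyn, i])
  }, numeric(1))
}

#' Decode a population repeatedly and summarize
#'
#' Runs `n_sims` independent simulate-train-test cycles and aggregates
#' decoder accuracy, per-conflict-level accuracy, per-neuron readout weights,
#' and per-neuron predicted detection probabilities (DP_pred: ambiguous
#' test-set responses sorted by the decoder's choice) with 95% CIs over
#' simulations.
#'
#' @param moments A [population_moments()].
#' @param noise A [noise_correlation_matrix()] result or `NULL` (independent).
#' @param n_samples Simulated trials per cycle (default 100000).
#' @param n_sims Number of cycles (default 100).
#' @param split Training fraction (default 0.9).
#' @param seed Integer seed.
#' @return List with `accuracy` (mean, ci), `accuracy_by_delta` (data frame of
#'   means), `dp_pred` (data frame: per-neuron mean, ci_lo, ci_hi, n_sims
#'   used), `weights` (per-neuron mean), and `n_sims`.
#' @export
decode_population <- function(moments, noise = NULL, n_samples = 100000,
                              n_sims = 100, split = 0.9, seed = 1L) {
  seeds <- with_seed(seed, sample_int(.Machine$integer.max %/% 2, 2 * n_sims))
  acc <- numeric(n_sims)
  dp_mat <- matrix(NA_real_, n_sims, nrow(moments$mu))
  w_mat <- matrix(NA_real_, n_sims, nrow(moments$mu))
  abd_sum <- NULL
  for (s in seq_len(n_sims)) {
    sim <- simulate_population_trials(moments, noise, n_samples,
                                      seed = seeds[2 * s - 1])
    res <- train_linear_decoder(sim, split = split, seed = seeds[2 * s])
    acc[s] <- res$accuracy
    dp_mat[s, ] <- .dp_pred_once(res)
    w_mat[s, ] <- res$weights
    abd_sum <- if (is.null(abd_sum)) res$accuracy_by_delta else {
      stopifnot(all(abd_sum$delta_depth_deg == res$accuracy_by_delta$delta_depth_deg))
      within(abd_sum, accuracy <- accuracy + res$accuracy_by_delta$accuracy)
    }
  }
  abd_sum$accuracy <- abd_sum$accuracy / n_sims
  ci <- function(x) stats::quantile(x, c(0.025, 0.975), na.rm = TRUE, names = FALSE)
  dp_ci <- apply(dp_mat, 2L, ci)
  list(
    accuracy = list(mean = mean(acc), ci = ci(acc)),
    accuracy_by_delta = abd_sum[, c("delta_depth_deg", "accuracy")],
    dp_pred = data.frame(
      neuron_id = moments$neuron_id,
      dp_pred = colMeans(dp_mat, na.rm = TRUE),
      ci_lo = dp_ci[1, ], ci_hi = dp_ci[2, ],
      n_sims = colSums(!is.na(dp_mat))
    ),
    weights = colMeans(w_mat),
    n_sims = n_sims
  )
}

# subset a population_moments object
.subset_moments <- function(moments, idx) {
  structure(list(mu = moments$mu[idx, , drop = FALSE],
                 sigma = moments$sigma[idx, , drop = FALSE],
                 np = moments$np[idx], conditions = moments$conditions,
                 neuron_id = moments$neuron_id[idx]),
            class = "population_moments")
}

#' Tercile membership by a grouping statistic
#'
#' Sorted ascending; the lowest tercile takes `ceiling(n/3)` neurons and the
#' remainder is split equally (97 neurons give 33/32/32).
#'
#' @param stat Grouping statistic per neuron.
#' @return Integer vector of tercile labels (1 = lowest) in neuron order.
#' @export
tercile_split <- function(stat) {
  n <- length(stat)
  sizes <- c(ceiling(n / 3), rep((n - ceiling(n / 3)) / 2, 2))
  if (any(sizes != floor(sizes))) {
    sizes <- c(ceiling(n / 3), floor((n - ceiling(n / 3)) / 2),
               n - ceiling(n / 3) - floor((n - ceiling(n / 3)) / 2))
  }
  labels <- rep(seq_len(3L), times = sizes)
  out <- integer(n)
  out[order(stat)] <- labels
  out
}

#' Subgroup decoding
#'
#' Decodes tercile subgroups of the population defined by a grouping statistic
#' (for example the peak dynamic:stationary response ratio, or the tuning
#' congruency correlation), plus a "mixed" subgroup that redraws a random
#' subset of the same size as the upper terciles on every simulation. Each
#' subgroup uses its own NP-structured correlated-noise model.
#'
#' @param moments A [population_moments()].
#' @param stat Grouping statistic, one value per neuron in `moments`.
#' @param n_sims Simulations per subgroup (default 500).
#' @param n_samples Simulated trials per simulation (default 10000).
#' @param split Training fraction (default 0.9).
#' @param correlated Use the NP-structured noise model (default TRUE).
#' @param seed Integer seed.
#' @return List with per-subgroup (`lowest`, `middle`, `highest`, `mixed`)
#'   elements: `accuracy` (mean, ci, per-sim values) and `dp_pred` (per-neuron
#'   mean over the simulations that included the neuron).
#' @export
subgroup_decoding <- function(moments, stat, n_sims = 500, n_samples = 10000,
                              split = 0.9, correlated = TRUE, seed = 1L) {
  n <- nrow(moments$mu)
  if (length(stat) != n) stop("`stat` must have one value per neuron")
  if (anyNA(stat)) stop("`stat` contains missing values")
  if (n < 9L) stop("need at least 9 neurons for terciles")
  terc <- tercile_split(stat)
  mixed_size <- sum(terc == 3L)
  seeds <- with_seed(seed, sample_int(.Machine$integer.max %/% 2,
                                      4 * n_sims * 3))
  si <- 0L
  next_seed <- function() {
    si <<- si + 1L
    seeds[si]
  }

  run_group <- function(idx_fun, fixed_idx = NULL) {
    acc <- numeric(n_sims)
    dp_sum <- numeric(n)
    dp_cnt <- numeric(n)
    noise_cache <- NULL
    for (s in seq_len(n_sims)) {
      idx <- if (is.null(fixed_idx)) idx_fun() else fixed_idx
      sub <- .subset_moments(moments, idx)
      noise <- NULL
      if (correlated) {
        if (!is.null(fixed_idx)) {
          if (is.null(noise_cache)) noise_cache <- noise_correlation_matrix(sub$np)
          noise <- noise_cache
        } else {
          noise <- noise_correlation_matrix(sub$np)
        }
      }
      sim <- simulate_population_trials(sub, noise, n_samples, seed = next_seed())
      res <- train_linear_decoder(sim, split = split, seed = next_seed())
      acc[s] <- res$accuracy
      dp <- .dp_pred_once(res)
      ok <- !is.na(dp)
      dp_sum[idx[ok]] <- dp_sum[idx[ok]] + dp[ok]
      dp_cnt[idx[ok]] <- dp_cnt[idx[ok]] + 1
    }
    dp_mean <- ifelse(dp_cnt > 0, dp_sum / dp_cnt, NA_real_)
    list(accuracy = list(mean = mean(acc),
                         ci = stats::quantile(acc, c(0.025, 0.975),
                                              names = FALSE),
                         sims = acc),
         dp_pred = data.frame(neuron_id = moments$neuron_id,
                              dp_pred = dp_mean, n_sims = dp_cnt))
  }

  groups <- list(
    lowest = run_group(NULL, which(terc == 1L)),
    middle = run_group(NULL, which(terc == 2L)),
    highest = run_group(NULL, which(terc == 3L)),
    mixed = run_group(function() sort(with_seed(next_seed(),
                                                sample_int(n, mixed_size))))
  )
  groups
}
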