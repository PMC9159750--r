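# Depth-sign indices, their permutation test, and tuning congruency between
# the binocular-disparity and motion-parallax cues.

# per-depth means and SDs from trial-level rates; depths must be sorted keys
.depth_stats <- function(rate, depth) {
  ud <- sort(unique(depth))
  mean_r <- vapply(ud, function(d) mean(rate[depth == d]), numeric(1))
  sd_r <- vapply(ud, function(d) {
    r <- rate[depth == d]
    if (length(r) < 2L) stop("need >= 2 trials per depth to compute an SD")
    stats::sd(r)
  }, numeric(1))
  list(depth = ud, mean = mean_r, sd = sd_r)
}

# core index: average over symmetric pairs of the signed normalized
# difference (positive-side minus negative-side mean response, normalized by
# that difference's magnitude plus the average of the two per-depth SDs);
# a pair with zero difference and zero SD contributes 0
.dsdi_from_stats <- function(mean_r, sd_r, depth) {
  pos <- which(depth > 0)
  terms <- vapply(pos, function(i) {
    j <- which(abs(depth + depth[i]) < 1e-9)
    if (length(j) != 1L) {
      stop(sprintf("depth %+g has no symmetric partner", depth[i]))
    }
    diff <- mean_r[i] - mean_r[j]
    s_avg <- (sd_r[i] + sd_r[j]) / 2
    den <- abs(diff) + s_avg
    if (den == 0) 0 else diff / den
  }, numeric(1))
  mean(terms)
}

#' Depth-sign discrimination index (DSDI)
#'
#' For each pair of depths symmetric about zero, the difference between mean
#' responses at the far and near depths is normalized by its own magnitude
#' plus the average of the two per-depth response SDs; the index is the
#' average of these terms over the pairs. It lies in (-1, +1); negative values
#' indicate a near preference. Computed from trial-level rates on a depth grid
#' symmetric about zero (standard grid: -2..2 deg in 0.5-deg steps, whose four
#' nonzero magnitude pairs enter the average).
#'
#' @param rate Trial firing rates (spikes/s).
#' @param depth Depth label (deg) per trial; the set of unique values must be
#'   symmetric about zero, with >= 2 trials per depth.
#' @param n_perm Number of permutations for the significance test (default
#'   1000); values below 100 trigger a warning.
#' @param seed Integer seed for the permutation test; `NULL` skips the test.
#' @return List with `dsdi`, `p_value` (one-sided permutation p, or `NA` if
#'   `seed` is `NULL`), and `n_permutations`.
#' @export
compute_dsdi <- function(rate, depth, n_perm = 1000, seed = 1L) {
  st <- .depth_stats(rate, depth)
  if (!isTRUE(all.equal(sort(st$depth), sort(-st$depth)))) {
    stop("depth grid must be symmetric about zero")
  }
  dsdi <- .dsdi_from_stats(st$mean, st$sd, st$depth)
  p <- NA_real_
  if (!is.null(seed)) {
    p <- permutation_test_dsdi(rate, depth, n_perm = n_perm, seed = seed)
  }
  list(dsdi = dsdi, p_value = p,
       n_permutations = if (is.null(seed)) 0L else as.integer(n_perm))
}

#' DSDI for dynamic-object (cue-conflict) responses
#'
#' The same index computed over depth-conflict values instead of depths:
#' positive minus negative conflict of each symmetric magnitude pair
#' (standard pairs +-0.21, +-0.57, +-1.53), averaged over the three pairs.
#' Zero-conflict trials are excluded.
#'
#' @param rate Trial firing rates on dynamic-object trials.
#' @param delta_depth Depth-conflict label (deg) per trial.
#' @inheritParams compute_dsdi
#' @return As [compute_dsdi()].
#' @export
compute_dsdi_dyn <- function(rate, delta_depth, n_perm = 1000, seed = 1L) {
  keep <- delta_depth != 0
  compute_dsdi(rate[keep], delta_depth[keep], n_perm = n_perm, seed = seed)
}

#' Permutation test for a depth-sign index
#'
#' Trial rates are shuffled across depth labels (jointly over all depths,
#' preserving per-depth trial counts) and the index recomputed `n_perm` times.
#' The p value is one-sided by the sign of the measured index: for a negative
#' index, the proportion of shuffled indices below it; for a positive index,
#' the proportion above it.
#'
#' @inheritParams compute_dsdi
#' @return One-sided permutation p value.
#' @export
permutation_test_dsdi <- function(rate, depth, n_perm = 1000, seed = 1L) {
  if (n_perm < 100) warning("`n_perm` < 100 gives a coarse p value")
  st <- .depth_stats(rate, depth)
  observed <- .dsdi_from_stats(st$mean, st$sd, st$depth)
  ud <- st$depth
  idx_by_depth <- lapply(ud, function(d) which(depth == d))
  counts <- lengths(idx_by_depth)
  n <- length(rate)
  pos <- which(ud > 0)
  pair_of <- vapply(pos, function(i) which(abs(ud + ud[i]) < 1e-9), integer(1))

  null_dsdi <- with_seed(seed, {
    # each row of `perm` is one shuffled assignment of trials to depth slots
    perm <- t(vapply(seq_len(n_perm), function(...) sample_int(n, n),
                     integer(n)))
    rates_perm <- matrix(rate[perm], nrow = n_perm)
    offs <- c(0L, cumsum(counts))
    mean_m <- matrix(NA_real_, n_perm, length(ud))
    sd_m <- matrix(NA_real_, n_perm, length(ud))
    for (k in seq_along(ud)) {
      cols <- (offs[k] + 1L):offs[k + 1L]
      block <- rates_perm[, cols, drop = FALSE]
      mean_m[, k] <- rowMeans(block)
      sd_m[, k] <- row_sds(block)
    }
    terms <- matrix(NA_real_, n_perm, length(pos))
    for (t in seq_along(pos)) {
      i <- pos[t]; j <- pair_of[t]
      diff <- mean_m[, i] - mean_m[, j]
      den <- abs(diff) + (sd_m[, i] + sd_m[, j]) / 2
      terms[, t] <- ifelse(den == 0, 0, diff / den)
    }
    rowMeans(terms)
  })
  if (observed < 0) mean(null_dsdi < observed) else mean(null_dsdi > observed)
}

#' Tuning congruency between the two depth cues
#'
#' Pearson correlation (`r_mp_bd`) between the two cues' nine depth-tuning
#' means, with classification as congruent (significantly positive) or
#' opposite (significantly negative) at alpha = 0.05; also reports the
#' difference of the two cues' depth-sign indices and, when detection-task
#' responses are supplied, the ratio of peak mean response to dynamic versus
#' stationary objects.
#'
#' @param bd_rate,bd_depth Trial rates and depth labels for the disparity cue.
#' @param mp_rate,mp_depth Trial rates and depth labels for the parallax cue.
#' @param detection_rate Optional trial rates from the detection task.
#' @param detection_condition Condition identifier per detection trial (mean
#'   rates are taken within condition before the peak is located).
#' @param detection_kind Condition kind (`"dynamic"`/`"stationary"`) per
#'   detection trial.
#' @param seed Seed for the DSDI permutation tests (`NULL` skips them).
#' @return List with `r_mp_bd`, `p_value`, `class`
#'   (`"congruent"`/`"opposite"`/`"unclassified"`), `dsdi_bd`, `dsdi_mp`,
#'   `delta_dsdi` (MP minus BD), and `peak_ratio` (`NA` without detection
#'   trials).
#' @export
compute_congruency <- function(bd_rate, bd_depth, mp_rate, mp_depth,
                               detection_rate = NULL,
                               detection_condition = NULL,
                               detection_kind = NULL, seed = NULL) {
  bd <- .depth_stats(bd_rate, bd_depth)
  mp <- .depth_stats(mp_rate, mp_depth)
  if (!isTRUE(all.equal(bd$depth, mp$depth))) {
    stop("the two cues must be measured on the same depth grid")
  }
  if (stats::sd(bd$mean) == 0 || stats::sd(mp$mean) == 0) {
    stop("tuning-curve means have zero variance; correlation undefined")
  }
  ct <- stats::cor.test(mp$mean, bd$mean, method = "pearson")
  cls <- if (ct$p.value < 0.05) {
    if (ct$estimate > 0) "congruent" else "opposite"
  } else "unclassified"
  dsdi_bd <- compute_dsdi(bd_rate, bd_depth, seed = seed)$dsdi
  dsdi_mp <- compute_dsdi(mp_rate, mp_depth, seed = seed)$dsdi
  peak_ratio <- NA_real_
  if (!is.null(detection_rate)) {
    if (is.null(detection_kind) || is.null(detection_condition) ||
        length(detection_kind) != length(detection_rate) ||
        length(detection_condition) != length(detection_rate)) {
      stop("`detection_condition` and `detection_kind` must accompany `detection_rate`")
    }
    peak_ratio <- peak_response_ratio(detection_rate, detection_condition,
                                      detection_kind)
  }
  list(r_mp_bd = unname(ct$estimate), p_value = ct$p.value, class = cls,
       dsdi_bd = dsdi_bd, dsdi_mp = dsdi_mp,
       delta_dsdi = dsdi_mp - dsdi_bd, peak_ratio = peak_ratio)
}

#' Peak dynamic:stationary response ratio
#'
#' Largest per-condition mean response over dynamic (cue-conflict) conditions
#' divided by the largest per-condition mean over stationary conditions.
#'
#' @param rate Trial firing rates from the detection task.
#' @param condition Condition identifier per trial.
#' @param kind `"dynamic"` or `"stationary"` per trial.
#' @return Positive scalar; 1 when the two condition sets drive the neuron
#'   equally at their best.
#' @export
peak_response_ratio <- function(rate, condition, kind) {
  means <- tapply(rate, condition, mean)
  kind_by_cond <- tapply(kind, condition, function(k) k[1])
  dyn <- means[kind_by_cond == "dynamic"]
  sta <- means[kind_by_cond == "stationary"]
  if (length(dyn) == 0L || length(sta) == 0L) {
    stop("detection trials must include dynamic and stationary conditions")
  }
  max(dyn) / max(sta)
}
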