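# Ideal-observer and choice-related metrics: ROC area, neurometric
# performance over depth-conflict levels, detection probability on ambiguous
# trials, and choice-sorted response time courses.

# rank-based ROC area with the 1/2 tie convention: P(draw from `preferred`
# exceeds a draw from `other`) + 0.5 * P(tie)
.roc_area_num <- function(other, preferred) {
  n_o <- length(other)
  n_p <- length(preferred)
  r <- rank(c(other, preferred))
  (sum(r[(n_o + 1L):(n_o + n_p)]) - n_p * (n_p + 1) / 2) / (n_o * n_p)
}

#' Area under the ROC curve for two response distributions
#'
#' Equals the probability that a random draw from the preferred group
#' (`group_b`) exceeds a random draw from `group_a`, with ties counted 1/2
#' (the rank-sum construction). Swapping the groups maps the area to its
#' complement.
#'
#' @param group_a Responses of the non-preferred group.
#' @param group_b Responses of the preferred group (e.g. dynamic-in-RF, or
#'   chosen-in-RF).
#' @return List with `area` in \[0, 1\], `n_a`, `n_b`.
#' @export
roc_area <- function(group_a, group_b) {
  if (length(group_a) == 0L || length(group_b) == 0L) {
    stop("both groups must be non-empty")
  }
  list(area = .roc_area_num(group_a, group_b),
       n_a = length(group_a), n_b = length(group_b))
}

#' Neurometric performance (NP) for one neuron
#'
#' For each nonzero depth-conflict level, the ROC area compares responses on
#' trials with the dynamic object in the receptive field (RF) at that level
#' against all trials with a stationary object in the RF (the dynamic object
#' in the opposite hemifield), pooled over stationary depths. NP is the
#' unweighted mean of the per-level areas; values above 0.5 indicate a
#' preference for dynamic objects. Zero-conflict trials never enter (they are
#' reserved for the detection-probability analysis).
#'
#' @param rate Trial firing rates.
#' @param delta_depth Depth conflict (deg) of the trial's dynamic object.
#' @param dynamic_in_rf Logical; was the dynamic object in the RF?
#' @param expected_deltas Optional nonzero conflict levels the design
#'   promises; missing levels raise an error naming them.
#' @return List with `np`, and `roc_by_delta` (named per-level areas).
#' @export
neurometric_performance <- function(rate, delta_depth, dynamic_in_rf,
                                    expected_deltas = NULL) {
  stopifnot(length(rate) == length(delta_depth),
            length(rate) == length(dynamic_in_rf))
  nonzero <- delta_depth != 0
  sta_pool <- rate[nonzero & !dynamic_in_rf]
  if (length(sta_pool) == 0L) stop("no stationary-in-RF trials available")
  levels <- sort(unique(delta_depth[nonzero]))
  if (!is.null(expected_deltas)) {
    miss <- setdiff(setdiff(expected_deltas, 0), levels)
    if (length(miss)) {
      stop("missing conflict levels: ", paste(sprintf("%+.2f", miss),
                                              collapse = ", "))
    }
  }
  areas <- vapply(levels, function(d) {
    dyn <- rate[nonzero & dynamic_in_rf & delta_depth == d]
    if (length(dyn) == 0L) {
      stop(sprintf("no dynamic-in-RF trials at delta depth %+g", d))
    }
    .roc_area_num(sta_pool, dyn)
  }, numeric(1))
  names(areas) <- sprintf("%+.2f", levels)
  list(np = mean(areas), roc_by_delta = areas)
}

#' Detection probability (DP) for one neuron
#'
#' Uses only ambiguous (zero-conflict) trials, on which the two stimuli are
#' identical stationary objects at the pedestal depth. Responses are z-scored
#' (pooling both self-motion phases), sorted by the animal's choice, and DP is
#' the ROC area with the chose-in-RF group preferred. The neuron is eligible
#' only if there are at least `min_choices` choices on each side. Significance
#' is a two-sided permutation test that shuffles choice labels.
#'
#' @param rate Firing rates on ambiguous trials.
#' @param choice_in_rf Logical; did the animal choose the RF object?
#' @param min_choices Minimum choices per side for eligibility (default 5).
#' @param n_perm Number of label permutations (default 1000).
#' @param seed Integer seed for the permutation test; `NULL` skips it.
#' @return List with `dp`, `p_value`, `n_in`, `n_out`, `eligible`.
#' @export
detection_probability <- function(rate, choice_in_rf, min_choices = 5,
                                  n_perm = 1000, seed = 1L) {
  stopifnot(length(rate) == length(choice_in_rf))
  n_in <- sum(choice_in_rf)
  n_out <- sum(!choice_in_rf)
  if (n_in == 0L || n_out == 0L) {
    return(list(dp = NA_real_, p_value = NA_real_, n_in = n_in,
                n_out = n_out, eligible = FALSE))
  }
  z <- if (stats::sd(rate) > 0) (rate - mean(rate)) / stats::sd(rate) else rate - mean(rate)
  dp <- .roc_area_num(z[!choice_in_rf], z[choice_in_rf])
  eligible <- n_in >= min_choices && n_out >= min_choices
  p <- NA_real_
  if (!is.null(seed)) {
    # under label permutation the pooled ranks are fixed: resample which
    # ranks belong to the chose-in-RF group
    r <- rank(z)
    n <- length(z)
    null_dp <- with_seed(seed, {
      vapply(seq_len(n_perm), function(...) {
        (sum(r[sample_int(n, n_in)]) - n_in * (n_in + 1) / 2) / (n_in * n_out)
      }, numeric(1))
    })
    lo <- mean(null_dp <= dp)
    hi <- mean(null_dp >= dp)
    p <- min(1, max(2 * min(lo, hi), 1 / n_perm))
  }
  list(dp = dp, p_value = p, n_in = n_in, n_out = n_out, eligible = eligible)
}

#' Choice-sorted response time course on ambiguous trials
#'
#' Peri-stimulus rate traces are boxcar-smoothed, z-scored with a session-wide
#' mean and SD, then averaged within each self-motion phase by choice. For
#' each phase the difference trace between choices is tested per time point
#' (two-sided Wilcoxon rank-sum at `alpha`). Phase-by-choice cells with fewer
#' than two trials are omitted and flagged.
#'
#' @param counts Spike-count matrix, trials x bins (see [simulate_rasters()]).
#' @param bin_s Bin width (s).
#' @param phase_deg Self-motion phase (0/180) per trial.
#' @param choice_in_rf Logical choice per trial.
#' @param boxcar_s Smoothing window (s), default 0.15.
#' @param alpha Per-time-point significance level, default 0.05.
#' @return List with `time_s` and, per phase, mean/SE z-traces by choice, the
#'   difference trace (in minus out), per-bin `significant` flags, and an
#'   `omitted` flag for undersampled cells.
#' @export
choice_sorted_timecourse <- function(counts, bin_s, phase_deg, choice_in_rf,
                                     boxcar_s = 0.15, alpha = 0.05) {
  stopifnot(nrow(counts) == length(phase_deg),
            nrow(counts) == length(choice_in_rf))
  if (!all(phase_deg %in% c(0, 180))) stop("`phase_deg` must be 0 or 180")
  if (length(unique(phase_deg)) < 2L) stop("both self-motion phases must be present")
  k <- max(1L, round(boxcar_s / bin_s))
  smoothed <- boxcar_rows(counts / bin_s, k)
  mu <- mean(smoothed)
  sdv <- stats::sd(as.vector(smoothed))
  z <- if (sdv > 0) (smoothed - mu) / sdv else smoothed - mu
  tc <- attr(counts, "time_s")
  if (is.null(tc)) tc <- (seq_len(ncol(counts)) - 0.5) * bin_s

  per_phase <- lapply(c(0, 180), function(ph) {
    res <- list(phase_deg = ph, omitted = FALSE)
    for (ch in c(TRUE, FALSE)) {
      idx <- phase_deg == ph & choice_in_rf == ch
      nm <- if (ch) "in_rf" else "out_rf"
      if (sum(idx) < 2L) {
        res$omitted <- TRUE
        res[[paste0("mean_", nm)]] <- NULL
        next
      }
      zz <- z[idx, , drop = FALSE]
      res[[paste0("mean_", nm)]] <- colMeans(zz)
      res[[paste0("se_", nm)]] <- col_sds(zz) / sqrt(nrow(zz))
    }
    if (!res$omitted) {
      res$difference <- res$mean_in_rf - res$mean_out_rf
      zin <- z[phase_deg == ph & choice_in_rf, , drop = FALSE]
      zout <- z[phase_deg == ph & !choice_in_rf, , drop = FALSE]
      res$p_value <- vapply(seq_len(ncol(z)), function(b) {
        x <- zin[, b]; y <- zout[, b]
        if (length(unique(c(x, y))) == 1L) return(1) # all tied: no evidence
        suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$p.value)
      }, numeric(1))
      res$significant <- res$p_value < alpha
    }
    res
  })
  names(per_phase) <- c("phase_0", "phase_180")
  c(list(time_s = tc), per_phase)
}
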