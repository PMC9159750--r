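# Synthetic MT population: Gaussian depth-tuning bumps per cue, a
# congruent/opposite cell mixture with a near bias for motion-parallax
# preferences, trial-level detection responses, and choices coupled to a
# shared noise source so that choice-predictive activity can arise.

#' Population specification
#'
#' Defaults follow the qualitative structure of the recorded MT sample:
#' roughly half the cells have mismatched ("opposite") depth-sign preferences
#' for the two cues, and motion-parallax preferences are biased toward near.
#'
#' @param n_neurons Number of neurons (>= 2).
#' @param fraction_opposite Probability a neuron's disparity preference has
#'   the opposite sign to its motion-parallax preference.
#' @param near_bias_mp Probability the motion-parallax preferred depth is near
#'   (negative).
#' @param seed Integer seed used by [sample_population()].
#' @return A list of class `"population_spec"`.
#' @export
population_spec <- function(n_neurons = 100, fraction_opposite = 0.5,
                            near_bias_mp = 0.75, seed = 1L) {
  if (n_neurons < 2) stop("`n_neurons` must be at least 2")
  if (fraction_opposite < 0 || fraction_opposite > 1) {
    stop("`fraction_opposite` must lie in [0, 1]")
  }
  if (near_bias_mp < 0 || near_bias_mp > 1) stop("`near_bias_mp` must lie in [0, 1]")
  structure(
    list(n_neurons = as.integer(n_neurons),
         fraction_opposite = fraction_opposite,
         near_bias_mp = near_bias_mp, seed = seed),
    class = "population_spec"
  )
}

#' Behavior / choice-generation specification
#'
#' Choices are generated from a noisy decision variable
#' `sensitivity * |delta depth| * sign(dynamic in RF) + choice_coupling * z + e`,
#' where `z` is a shared standard-normal latent that is also injected into
#' every neuron's trial response (scaled by `neural_coupling` and by the
#' neuron's dynamic-preference sign). This minimal mechanism makes neurons
#' that prefer dynamic objects fire more on trials where the animal reports
#' the dynamic object in their receptive field, so detection probabilities
#' above 0.5 arise for those cells. Under `monocular = TRUE` the disparity cue
#' is absent and the stimulus term is dropped, forcing chance performance.
#'
#' @param sensitivity Evidence slope on `|delta depth|` (1/deg), >= 0.
#' @param lapse Lapse probability in \[0, 0.5\].
#' @param choice_coupling Weight of the shared latent in the decision variable.
#' @param neural_coupling Weight of the shared latent in neural responses
#'   (units of `sqrt(mean rate)`).
#' @param monocular Logical; simulate monocular (disparity-free) viewing.
#' @return A list of class `"behavior_spec"`.
#' @export
behavior_spec <- function(sensitivity = 2.6, lapse = 0.02,
                          choice_coupling = 1.0, neural_coupling = 0.5,
                          monocular = FALSE) {
  if (sensitivity < 0) stop("`sensitivity` must be >= 0")
  if (lapse < 0 || lapse > 0.5) stop("`lapse` must lie in [0, 0.5]")
  structure(
    list(sensitivity = sensitivity, lapse = lapse,
         choice_coupling = choice_coupling, neural_coupling = neural_coupling,
         monocular = isTRUE(monocular)),
    class = "behavior_spec"
  )
}

#' Draw a synthetic population of MT neurons
#'
#' Each neuron gets a baseline rate, and per-cue Gaussian tuning (preferred
#' depth, width, gain) for binocular disparity (BD) and motion parallax (MP).
#' The MP preferred-depth sign is near with probability `near_bias_mp`; the BD
#' sign matches it for congruent cells and is flipped for opposite cells.
#' Disparity response gains are substantially larger than motion-parallax
#' gains (as observed in MT, where parallax is carried by slow retinal speeds),
#' and preferred-depth magnitudes are larger for parallax than for disparity,
#' consistent with the experimental choice of the pedestal depth as the
#' average midpoint between the two cues' preferred depths.
#'
#' @param spec A [population_spec()].
#' @return Data frame with one row per neuron: `neuron_id`, `baseline`,
#'   `bd_pref`, `bd_width`, `bd_gain`, `mp_pref`, `mp_width`, `mp_gain`,
#'   `congruency` (`"congruent"`/`"opposite"`), `noise_k` (rate-noise scale).
#' @export
sample_population <- function(spec = population_spec()) {
  stopifnot(inherits(spec, "population_spec"))
  n <- spec$n_neurons
  with_seed(spec$seed, {
    opp <- stats::runif(n) < spec$fraction_opposite
    sign_mp <- ifelse(stats::runif(n) < spec$near_bias_mp, -1, 1)
    sign_bd <- ifelse(opp, -sign_mp, sign_mp)
    data.frame(
      neuron_id = sprintf("n%03d", seq_len(n)),
      baseline = stats::runif(n, 5, 15),
      bd_pref = sign_bd * stats::runif(n, 0.1, 1.0),
      bd_width = stats::runif(n, 0.6, 1.4),
      bd_gain = stats::runif(n, 20, 60),
      mp_pref = sign_mp * stats::runif(n, 0.6, 1.8),
      mp_width = stats::runif(n, 0.6, 1.4),
      mp_gain = stats::runif(n, 5, 25),
      congruency = ifelse(opp, "opposite", "congruent"),
      noise_k = 1.0,
      stringsAsFactors = FALSE
    )
  })
}

#' Mean tuning-curve response of one neuron
#'
#' Gaussian bump over equivalent disparity:
#' `baseline + gain * exp(-(depth - preferred)^2 / (2 * width^2))`.
#'
#' @param neuron One row of [sample_population()] output (data frame or list).
#' @param cue `"BD"` or `"MP"`.
#' @param depth Depth(s) in deg equivalent disparity, within \[-2, 2\].
#' @return Mean firing rate(s), spikes/s.
#' @export
tuning_mean <- function(neuron, cue = c("BD", "MP"), depth) {
  cue <- match.arg(cue)
  if (any(abs(depth) > 2 + 1e-9)) stop("`depth` must lie within [-2, 2] deg")
  p <- if (cue == "BD") {
    list(pref = neuron$bd_pref, width = neuron$bd_width, gain = neuron$bd_gain)
  } else {
    list(pref = neuron$mp_pref, width = neuron$mp_width, gain = neuron$mp_gain)
  }
  neuron$baseline + p$gain * exp(-(depth - p$pref)^2 / (2 * p$width^2))
}

#' Mean detection-task response of one neuron to an in-RF stimulus
#'
#' Rectified additive cue combination: each cue contributes its tuning bump at
#' the cue-specific depth. For a stationary object (`d_bd == d_mp`) this
#' reduces to the congruent sum of both cues at the object's depth; a neuron
#' with mismatched tuning can therefore respond more to some cue-conflict
#' (dynamic) stimuli than to any stationary one.
#'
#' @param neuron One row of [sample_population()] output.
#' @param d_bd Disparity-defined depth (deg); vectorized.
#' @param d_mp Motion-parallax-defined depth (deg); same length as `d_bd`.
#' @param w_bd,w_mp Cue weights (default 1).
#' @return Mean firing rate(s), spikes/s (non-negative).
#' @export
detection_mean <- function(neuron, d_bd, d_mp, w_bd = 1, w_mp = 1) {
  bump_bd <- tuning_mean(neuron, "BD", d_bd) - neuron$baseline
  bump_mp <- tuning_mean(neuron, "MP", d_mp) - neuron$baseline
  pmax(0, neuron$baseline + w_bd * bump_bd + w_mp * bump_mp)
}

# matrix of detection-task means: neurons x conditions
.detection_mean_matrix <- function(neurons, conditions, w_bd = 1, w_mp = 1) {
  out <- matrix(NA_real_, nrow(neurons), nrow(conditions),
                dimnames = list(neurons$neuron_id, conditions$condition_id))
  for (i in seq_len(nrow(neurons))) {
    out[i, ] <- detection_mean(neurons[i, ], conditions$d_bd_deg,
                               conditions$d_mp_deg, w_bd, w_mp)
  }
  out
}

# dynamic-preference sign per neuron: does the cell's mean response over
# dynamic (cue-conflict) conditions exceed its mean over stationary ones?
.dynamic_preference_sign <- function(neurons, conditions) {
  m <- .detection_mean_matrix(neurons, conditions)
  dyn <- conditions$kind == "dynamic" & conditions$delta_depth_deg != 0
  sta <- conditions$kind == "stationary"
  sign(rowMeans(m[, dyn, drop = FALSE]) - rowMeans(m[, sta, drop = FALSE]))
}

#' Simulate depth-tuning measurements
#'
#' Trial responses on the nine-point depth grid for each cue, with Gaussian
#' rate noise of SD `noise_k * sqrt(mean)` truncated at zero.
#'
#' @param neurons Output of [sample_population()].
#' @param depths Depth grid (deg), default -2..2 in steps of 0.5.
#' @param n_reps Trials per depth per cue (default 8).
#' @param seed Integer seed.
#' @return Long data frame: `neuron_id`, `cue`, `depth_deg`, `rep`, `rate_hz`.
#' @export
simulate_tuning <- function(neurons, depths = seq(-2, 2, by = 0.5),
                            n_reps = 8, seed = 1L) {
  if (n_reps < 2) stop("`n_reps` must be >= 2 (SDs are needed downstream)")
  with_seed(seed, {
    grid <- expand.grid(rep = seq_len(n_reps), depth_deg = depths,
                        cue = c("BD", "MP"), neuron_id = neurons$neuron_id,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- numeric(nrow(grid))
    for (i in seq_len(nrow(neurons))) {
      idx <- grid$neuron_id == neurons$neuron_id[i]
      g <- grid[idx, ]
      mu[idx] <- ifelse(g$cue == "BD",
                        tuning_mean(neurons[i, ], "BD", g$depth_deg),
                        tuning_mean(neurons[i, ], "MP", g$depth_deg))
      k <- neurons$noise_k[i]
      mu[idx] <- pmax(0, mu[idx] + k * sqrt(mu[idx]) * stats::rnorm(sum(idx)))
    }
    data.frame(neuron_id = grid$neuron_id, cue = grid$cue,
               depth_deg = grid$depth_deg, rep = grid$rep, rate_hz = mu,
               stringsAsFactors = FALSE)
  })
}

#' Simulate a detection-task session
#'
#' For each depth-conflict value, `n_reps` trials are generated. On each trial
#' the dynamic object is placed in the receptive field (RF) with probability
#' 0.5 (otherwise a stationary object at a random standard depth occupies the
#' RF and the dynamic object sits in the opposite hemifield); the self-motion
#' phase is 0 or 180 equiprobably. Each neuron's rate is drawn about its
#' [detection_mean()] for the in-RF condition with noise
#' `sqrt(mean) * (noise_k * eta + neural_coupling * s * z)`, where `eta` is
#' private noise, `z` the shared latent, and `s` the neuron's
#' dynamic-preference sign. The choice follows the decision model described in
#' [behavior_spec()]. At zero conflict both objects are stationary at the
#' pedestal and the "correct" side is an arbitrary label, so accuracy is at
#' chance by construction.
#'
#' @param neurons Output of [sample_population()].
#' @param conditions Output of [build_condition_table()].
#' @param n_reps Trials per depth-conflict value (default 35).
#' @param behavior A [behavior_spec()].
#' @param seed Integer seed.
#' @return A list of class `"mt_session"` with elements `trials` (data frame:
#'   `trial_id`, `condition_id`, `delta_depth_deg`, `phase_deg`,
#'   `dynamic_in_rf`, `choice_in_rf`, `correct`, `monocular`), `rates`
#'   (trials x neurons matrix, spikes/s), `neurons`, and `conditions`.
#' @export
simulate_session <- function(neurons, conditions = build_condition_table(),
                             n_reps = 35, behavior = behavior_spec(),
                             seed = 1L) {
  stopifnot(inherits(behavior, "behavior_spec"))
  if (nrow(conditions) == 0L) stop("`conditions` must be non-empty")
  if (n_reps < 1) stop("`n_reps` must be >= 1")
  dyn_rows <- which(conditions$kind == "dynamic")
  sta_rows <- which(conditions$kind == "stationary")
  if (length(dyn_rows) == 0L || length(sta_rows) == 0L) {
    stop("`conditions` must contain both dynamic and stationary conditions")
  }
  mean_mat <- .detection_mean_matrix(neurons, conditions)
  s_sign <- .dynamic_preference_sign(neurons, conditions)

  with_seed(seed, {
    deltas <- conditions$delta_depth_deg[dyn_rows]
    n_trials <- length(deltas) * n_reps
    delta <- rep(deltas, each = n_reps)
    dyn_cond <- rep(dyn_rows, each = n_reps)
    dynamic_in_rf <- stats::runif(n_trials) < 0.5
    sta_in_rf <- sta_rows[sample_int(length(sta_rows), n_trials, replace = TRUE)]
    cond_row <- ifelse(dynamic_in_rf, dyn_cond, sta_in_rf)
    # at zero conflict both objects are identical stationary-pedestal stimuli;
    # the in-RF stimulus is the delta = 0 dynamic condition either way
    cond_row[delta == 0] <- dyn_cond[delta == 0]
    phase <- ifelse(stats::runif(n_trials) < 0.5, 0, 180)

    z <- stats::rnorm(n_trials)
    signal <- if (behavior$monocular) 0 else behavior$sensitivity * abs(delta)
    evid <- signal * ifelse(dynamic_in_rf, 1, -1) +
      behavior$choice_coupling * z + stats::rnorm(n_trials)
    choice_in_rf <- evid > 0
    lapse_trial <- stats::runif(n_trials) < behavior$lapse
    choice_in_rf[lapse_trial] <- stats::runif(sum(lapse_trial)) < 0.5
    correct <- choice_in_rf == dynamic_in_rf

    mu <- t(mean_mat[, cond_row, drop = FALSE]) # trials x neurons
    eta <- matrix(stats::rnorm(n_trials * nrow(neurons)), n_trials)
    shared <- outer(z, s_sign * behavior$neural_coupling)
    rates <- pmax(mu + sqrt(mu) * (eta * rep(neurons$noise_k,
                                             each = n_trials) + shared), 0)
    colnames(rates) <- neurons$neuron_id

    trials <- data.frame(
      trial_id = seq_len(n_trials),
      condition_id = conditions$condition_id[cond_row],
      delta_depth_deg = delta,
      phase_deg = phase,
      dynamic_in_rf = dynamic_in_rf,
      choice_in_rf = choice_in_rf,
      correct = correct,
      monocular = behavior$monocular,
      stringsAsFactors = FALSE
    )
    structure(list(trials = trials, rates = rates, neurons = neurons,
                   conditions = conditions),
              class = "mt_session")
  })
}

#' Simulate spike-count rasters for a set of trials
#'
#' Homogeneous (optionally gain-modulated) Poisson counts per time bin at each
#' trial's firing rate, for the choice-sorted time-course analysis.
#'
#' @param rate_hz Per-trial firing rates (spikes/s).
#' @param duration_s Trial duration (s), default 2.1.
#' @param bin_s Bin width (s), default 0.01.
#' @param gain Optional function of time (s) returning a rate multiplier.
#' @param seed Integer seed.
#' @return Matrix of spike counts, trials x bins; bin centers in
#'   `attr(, "time_s")`.
#' @export
simulate_rasters <- function(rate_hz, duration_s = 2.1, bin_s = 0.01,
                             gain = NULL, seed = 1L) {
  n_bins <- floor(duration_s / bin_s)
  tc <- (seq_len(n_bins) - 0.5) * bin_s
  g <- if (is.null(gain)) rep(1, n_bins) else vapply(tc, gain, numeric(1))
  with_seed(seed, {
    lam <- outer(rate_hz, g * bin_s)
    counts <- matrix(stats::rpois(length(lam), lam), nrow = length(rate_hz))
    attr(counts, "time_s") <- tc
    counts
  })
}
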