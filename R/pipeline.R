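# Per-neuron metric tables and the seeded end-to-end pipeline.

#' Per-neuron tuning and detection metrics
#'
#' Computes, for every neuron of a session: depth-sign indices for both cues
#' (with optional permutation p values), the cue-congruency correlation and
#' class, the dynamic-object depth-sign index, the peak dynamic:stationary
#' response ratio, neurometric performance, and detection probability.
#'
#' @param session An `"mt_session"` from [simulate_session()].
#' @param tuning Tuning trials from [simulate_tuning()] (long data frame).
#' @param n_perm Permutations for the DSDI and DP tests (default 1000).
#' @param seed Integer seed for the permutation tests; `NULL` skips them
#'   (p-value columns become `NA`), which is much faster for population-level
#'   summaries that only need the indices.
#' @param min_choices DP eligibility threshold (default 5).
#' @return Data frame, one row per neuron: `neuron_id`, `dsdi_bd`, `p_bd`,
#'   `dsdi_mp`, `p_mp`, `dsdi_dyn`, `r_mp_bd`, `p_r`, `class`, `delta_dsdi`,
#'   `peak_ratio`, `np`, `dp`, `dp_p`, `n_in`, `n_out`, `dp_eligible`.
#' @export
neuron_metrics <- function(session, tuning, n_perm = 1000, seed = NULL,
                           min_choices = 5) {
  tr <- session$trials
  conds <- session$conditions
  cond <- conds[match(tr$condition_id, conds$condition_id), ]
  ids <- colnames(session$rates)
  seeds <- if (is.null(seed)) NULL else {
    with_seed(seed, sample_int(.Machine$integer.max %/% 2, length(ids)))
  }
  rows <- lapply(seq_along(ids), function(i) {
    id <- ids[i]
    tun <- tuning[tuning$neuron_id == id, ]
    bd <- tun[tun$cue == "BD", ]
    mp <- tun[tun$cue == "MP", ]
    rate <- session$rates[, i]
    si <- if (is.null(seeds)) NULL else seeds[i]
    cong <- compute_congruency(bd$rate_hz, bd$depth_deg, mp$rate_hz,
                               mp$depth_deg, detection_rate = rate,
                               detection_condition = tr$condition_id,
                               detection_kind = cond$kind, seed = NULL)
    p_bd <- p_mp <- NA_real_
    if (!is.null(si)) {
      p_bd <- permutation_test_dsdi(bd$rate_hz, bd$depth_deg, n_perm, si)
      p_mp <- permutation_test_dsdi(mp$rate_hz, mp$depth_deg, n_perm, si + 1L)
    }
    # dynamic-object tuning: in-RF dynamic responses keyed by conflict level
    dyn_in <- tr$dynamic_in_rf & cond$kind == "dynamic"
    dsdi_dyn <- compute_dsdi_dyn(rate[dyn_in], tr$delta_depth_deg[dyn_in],
                                 seed = NULL)$dsdi
    np <- neurometric_performance(rate, tr$delta_depth_deg,
                                  tr$dynamic_in_rf)$np
    amb <- tr$delta_depth_deg == 0
    dp <- detection_probability(rate[amb], tr$choice_in_rf[amb],
                                min_choices = min_choices, n_perm = n_perm,
                                seed = if (is.null(si)) NULL else si + 2L)
    data.frame(neuron_id = id, dsdi_bd = cong$dsdi_bd, p_bd = p_bd,
               dsdi_mp = cong$dsdi_mp, p_mp = p_mp, dsdi_dyn = dsdi_dyn,
               r_mp_bd = cong$r_mp_bd, p_r = cong$p_value, class = cong$class,
               delta_dsdi = cong$delta_dsdi, peak_ratio = cong$peak_ratio,
               np = np, dp = dp$dp, dp_p = dp$p_value, n_in = dp$n_in,
               n_out = dp$n_out, dp_eligible = dp$eligible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Default pipeline configuration
#'
#' @return Named list of pipeline parameters: the stimulus design (conflict
#'   set, stationary grid, pedestal), population and behavior specifications,
#'   repetition counts, and decoding sizes.
#' @export
default_config <- function() {
  list(
    delta_set = standard_delta_set(),
    stationary_depths = standard_stationary_depths(),
    pedestal = standard_pedestal(),
    n_neurons = 100, fraction_opposite = 0.5, near_bias_mp = 0.75,
    tuning_reps = 8, detection_reps = 35,
    sensitivity = 2.6, lapse = 0.02,
    choice_coupling = 1.0, neural_coupling = 0.5,
    decode_mode = "correlated", decode_samples = 20000, decode_sims = 10,
    decode_split = 0.9,
    subgroup_sims = 100, subgroup_samples = 6000,
    n_perm = 1000
  )
}

#' Run the full analysis pipeline on synthetic data
#'
#' Seeded end-to-end run: build the condition table, draw a population,
#' simulate tuning and detection sessions, compute per-neuron metrics, the
#' psychometric curve and a choice-regression example, then population
#' decoding (correlated or independent noise) and subgroup decoding by peak
#' response ratio. When `out_dir` is given, all tables are written as
#' schema-versioned CSVs plus a run manifest recording every seed.
#'
#' @param config List as from [default_config()] (partial lists are merged
#'   over the defaults).
#' @param seed Master integer seed; all stage seeds derive from it.
#' @param out_dir Optional output directory.
#' @return List with `conditions`, `neurons`, `tuning`, `session`, `metrics`,
#'   `selection`, `psychometric`, `regression`, `decode`, `subgroups`, and
#'   `seeds`.
#' @export
run_pipeline <- function(config = list(), seed = 1L, out_dir = NULL) {
  cfg <- utils::modifyList(default_config(), config)
  seeds <- with_seed(seed, as.list(sample_int(.Machine$integer.max %/% 2, 6)))
  names(seeds) <- c("population", "tuning", "session", "behavior", "decode",
                    "subgroup")

  conditions <- build_condition_table(cfg$delta_set, cfg$stationary_depths,
                                      cfg$pedestal)
  neurons <- sample_population(population_spec(
    cfg$n_neurons, cfg$fraction_opposite, cfg$near_bias_mp,
    seed = seeds$population))
  tuning <- simulate_tuning(neurons, n_reps = cfg$tuning_reps,
                            seed = seeds$tuning)
  beh <- behavior_spec(cfg$sensitivity, cfg$lapse, cfg$choice_coupling,
                       cfg$neural_coupling)
  session <- simulate_session(neurons, conditions, cfg$detection_reps, beh,
                              seed = seeds$session)
  metrics <- neuron_metrics(session, tuning, n_perm = cfg$n_perm, seed = NULL)
  trials_long <- session_to_trials(session)
  selection <- apply_selection(trials_long, conditions)

  psych <- psychometric(session$trials$delta_depth_deg,
                        session$trials$correct)
  beh_trials <- simulate_behavior_session(seed = seeds$behavior)
  regression <- choice_regression(beh_trials)

  keep <- metrics$neuron_id %in% selection$decoding_eligible
  moments <- population_moments(list(
    trials = session$trials, rates = session$rates[, keep, drop = FALSE],
    conditions = conditions))
  noise <- if (identical(cfg$decode_mode, "correlated")) {
    noise_correlation_matrix(moments$np)
  } else NULL
  decode <- decode_population(moments, noise, n_samples = cfg$decode_samples,
                              n_sims = cfg$decode_sims,
                              split = cfg$decode_split, seed = seeds$decode)
  subgroups <- subgroup_decoding(moments, metrics$peak_ratio[keep],
                                 n_sims = cfg$subgroup_sims,
                                 n_samples = cfg$subgroup_samples,
                                 split = cfg$decode_split,
                                 seed = seeds$subgroup)

  out <- list(conditions = conditions, neurons = neurons, tuning = tuning,
              session = session, metrics = metrics, selection = selection,
              psychometric = psych, regression = regression, decode = decode,
              subgroups = subgroups, seeds = seeds)
  if (!is.null(out_dir)) write_pipeline_outputs(out, out_dir)
  out
}

#' Write pipeline outputs to disk
#'
#' @param result A [run_pipeline()] result.
#' @param out_dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(out_dir, f)
  utils::write.csv(result$conditions, p("conditions.csv"), row.names = FALSE)
  write_trials(session_to_trials(result$session), p("trials.csv"))
  write_tuning(result$tuning, p("tuning.csv"))
  utils::write.csv(result$metrics, p("neuron_metrics.csv"), row.names = FALSE)
  utils::write.csv(result$psychometric, p("behavior_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(result$decode$accuracy_by_delta, p("decode_performance.csv"),
                   row.names = FALSE)
  utils::write.csv(result$decode$dp_pred, p("dp_pred.csv"), row.names = FALSE)
  utils::write.csv(result$selection$audit, p("selection_audit.csv"),
                   row.names = FALSE)
  manifest <- data.frame(stage = names(result$seeds),
                         seed = unlist(result$seeds))
  utils::write.csv(manifest, p("run_manifest.csv"), row.names = FALSE)
  invisible(out_dir)
}
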