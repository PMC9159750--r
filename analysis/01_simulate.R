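#!/usr/bin/env Rscript
# Stage 1: build the stimulus design and simulate the synthetic study.
#
# Constructs the 16-condition cue-conflict design (7 conflict levels split
# symmetrically about the -0.45 deg pedestal plus 9 stationary depths),
# draws the default 100-neuron MT population (half opposite cells, 75%
# near-preferring for motion parallax), and simulates depth-tuning blocks
# and a detection-task session (35 repetitions per conflict level).
# Writes the raw tables under results/data/.

library(mtobjmotion)

SEED <- 1L
out <- file.path("results", "data")
dir.create(out, showWarnings = FALSE, recursive = TRUE)

conditions <- build_condition_table()
cat(sprintf("design: %d in-RF conditions; dynamic depths span [%.3f, %.3f] deg\n",
            nrow(conditions),
            min(conditions$d_mp_deg[conditions$kind == "dynamic"]),
            max(conditions$d_bd_deg[conditions$kind == "dynamic"])))

pop <- sample_population(population_spec(100, seed = SEED))
cat(sprintf("population: %d neurons, %.0f%% opposite, %.0f%% near-preferring MP\n",
            nrow(pop), 100 * mean(pop$congruency == "opposite"),
            100 * mean(pop$mp_pref < 0)))

# canonical dataset seeds used throughout the workflow and test suite
session <- simulate_session(pop, conditions, n_reps = 35, seed = SEED + 1L)
tuning <- simulate_tuning(pop, n_reps = 8, seed = SEED + 2L)
cat(sprintf("session: %d trials (%d ambiguous), %d neurons\n",
            nrow(session$trials),
            sum(session$trials$delta_depth_deg == 0), ncol(session$rates)))

write.csv(conditions, file.path(out, "conditions.csv"), row.names = FALSE)
write.csv(pop, file.path(out, "population.csv"), row.names = FALSE)
write_tuning(tuning, file.path(out, "tuning.csv"))
write_trials(session_to_trials(session), file.path(out, "trials.csv"))
cat("wrote", out, "\n")
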