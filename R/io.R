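# Delimited-text interchange formats with schema validation, the
# neuron-selection filters, and the end-to-end seeded pipeline.

.SCHEMA_VERSION <- "1"

.trial_cols <- c(session_id = "character", neuron_id = "character",
                 trial_id = "integer", condition_id = "character",
                 delta_depth_deg = "numeric", dynamic_in_rf = "logical",
                 phase_deg = "numeric", rate_hz = "numeric",
                 choice_in_rf = "logical", correct = "logical",
                 monocular = "logical")

.tuning_cols <- c(neuron_id = "character", cue = "character",
                  depth_deg = "numeric", rep = "integer", rate_hz = "numeric")

.write_with_header <- function(df, path, table) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# mtobjmotion %s schema v%s", table, .SCHEMA_VERSION), con)
  utils::write.csv(df, con, row.names = FALSE)
}

.read_with_header <- function(path, table, col_types) {
  header <- readLines(path, n = 1L)
  expect <- sprintf("# mtobjmotion %s schema v%s", table, .SCHEMA_VERSION)
  if (!identical(header, expect)) {
    stop(sprintf("'%s' is not a %s file with schema v%s (header: %s)",
                 path, table, .SCHEMA_VERSION, header))
  }
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(names(col_types), names(df))
  if (length(missing)) {
    stop("missing columns: ", paste(missing, collapse = ", "))
  }
  df
}

.fail_rows <- function(bad, what) {
  if (any(bad)) {
    stop(sprintf("%s at row(s): %s", what,
                 paste(utils::head(which(bad), 10L), collapse = ", ")))
  }
}

#' Write / read trial-level detection data
#'
#' CSV with a schema-version header comment. Columns: `session_id`,
#' `neuron_id`, `trial_id`, `condition_id`, `delta_depth_deg` (the trial's
#' dynamic-object conflict, wherever that object was), `dynamic_in_rf`,
#' `phase_deg`, `rate_hz`, `choice_in_rf`, `correct`, `monocular`. Reading
#' validates the schema and
#' fails with row-level diagnostics on negative or missing rates, duplicate
#' `(session, neuron, trial)` keys, and (when a condition table is given)
#' unknown condition ids.
#'
#' @param trials Data frame in the trials schema.
#' @param path File path.
#' @param conditions Optional [build_condition_table()] output for condition
#'   id validation.
#' @return `read_trials()` returns the validated data frame.
#' @export
write_trials <- function(trials, path) {
  stopifnot(all(names(.trial_cols) %in% names(trials)))
  .write_with_header(trials[, names(.trial_cols)], path, "trials")
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path, conditions = NULL) {
  df <- .read_with_header(path, "trials", .trial_cols)
  .fail_rows(is.na(df$rate_hz), "missing rate")
  .fail_rows(df$rate_hz < 0, "negative rate")
  key <- paste(df$session_id, df$neuron_id, df$trial_id)
  .fail_rows(duplicated(key), "duplicate (session, neuron, trial) key")
  .fail_rows(!df$phase_deg %in% c(0, 180), "phase must be 0 or 180")
  if (!is.null(conditions)) {
    .fail_rows(!df$condition_id %in% conditions$condition_id,
               "unknown condition id")
  }
  .fail_rows(is.na(df$delta_depth_deg), "missing conflict level")
  for (col in c("dynamic_in_rf", "choice_in_rf", "correct", "monocular")) {
    df[[col]] <- as.logical(df[[col]])
    .fail_rows(is.na(df[[col]]), sprintf("non-logical `%s`", col))
  }
  df
}

#' Write / read tuning-curve trial data
#'
#' CSV schema: `neuron_id`, `cue` (`BD`/`MP`), `depth_deg`, `rep`, `rate_hz`.
#'
#' @param tuning Data frame in the tuning schema.
#' @param path File path.
#' @return `read_tuning()` returns the validated data frame.
#' @export
write_tuning <- function(tuning, path) {
  stopifnot(all(names(.tuning_cols) %in% names(tuning)))
  .write_with_header(tuning[, names(.tuning_cols)], path, "tuning")
  invisible(path)
}

#' @rdname write_tuning
#' @export
read_tuning <- function(path) {
  df <- .read_with_header(path, "tuning", .tuning_cols)
  .fail_rows(is.na(df$rate_hz), "missing rate")
  .fail_rows(df$rate_hz < 0, "negative rate")
  .fail_rows(!df$cue %in% c("BD", "MP"), "cue must be BD or MP")
  df
}

#' Flatten a simulated session to the trials schema
#'
#' @param session An `"mt_session"`.
#' @param session_id Session label.
#' @return Long data frame, one row per neuron x trial.
#' @export
session_to_trials <- function(session, session_id = "s001") {
  tr <- session$trials
  n_neu <- ncol(session$rates)
  data.frame(
    session_id = session_id,
    neuron_id = rep(colnames(session$rates), each = nrow(tr)),
    trial_id = rep(tr$trial_id, n_neu),
    condition_id = rep(tr$condition_id, n_neu),
    delta_depth_deg = rep(tr$delta_depth_deg, n_neu),
    dynamic_in_rf = rep(tr$dynamic_in_rf, n_neu),
    phase_deg = rep(tr$phase_deg, n_neu),
    rate_hz = as.vector(session$rates),
    choice_in_rf = rep(tr$choice_in_rf, n_neu),
    correct = rep(tr$correct, n_neu),
    monocular = rep(tr$monocular, n_neu),
    stringsAsFactors = FALSE
  )
}

#' Rebuild a session object from long trial data
#'
#' Inverse of [session_to_trials()]: reshapes a validated long trials table
#' (one row per neuron x trial) back into the `"mt_session"` form used by the
#' metric functions.
#'
#' @param trials Long data frame in the trials schema (one session).
#' @param conditions A [build_condition_table()] output.
#' @return An `"mt_session"` list with `trials`, `rates`, `conditions`.
#' @export
trials_to_session <- function(trials, conditions) {
  if (length(unique(trials$session_id)) != 1L) {
    stop("`trials` must contain exactly one session")
  }
  ids <- unique(trials$neuron_id)
  t_ids <- sort(unique(trials$trial_id))
  first <- trials[trials$neuron_id == ids[1], ]
  first <- first[match(t_ids, first$trial_id), ]
  if (!all(first$condition_id %in% conditions$condition_id)) {
    stop("trials reference unknown condition ids")
  }
  rates <- vapply(ids, function(id) {
    sub <- trials[trials$neuron_id == id, ]
    sub$rate_hz[match(t_ids, sub$trial_id)]
  }, numeric(length(t_ids)))
  colnames(rates) <- ids
  tr <- data.frame(
    trial_id = t_ids,
    condition_id = first$condition_id,
    delta_depth_deg = first$delta_depth_deg,
    phase_deg = first$phase_deg,
    dynamic_in_rf = first$dynamic_in_rf,
    choice_in_rf = first$choice_in_rf,
    correct = first$correct,
    monocular = first$monocular,
    stringsAsFactors = FALSE
  )
  structure(list(trials = tr, rates = rates, conditions = conditions),
            class = "mt_session")
}

#' Neuron selection criteria
#'
#' @param min_choices_per_side Minimum choices toward each target on ambiguous
#'   trials for detection-probability eligibility (default 5).
#' @param require_standard_delta_set Require the standard depth-conflict set.
#' @param require_all_stationary_depths Require trials at every standard
#'   stationary depth (decoding eligibility).
#' @return A list of class `"selection_criteria"`.
#' @export
selection_criteria <- function(min_choices_per_side = 5,
                               require_standard_delta_set = TRUE,
                               require_all_stationary_depths = TRUE) {
  if (min_choices_per_side < 1) stop("`min_choices_per_side` must be >= 1")
  structure(list(min_choices_per_side = min_choices_per_side,
                 require_standard_delta_set = require_standard_delta_set,
                 require_all_stationary_depths = require_all_stationary_depths),
            class = "selection_criteria")
}

#' Apply selection criteria to trial-level data
#'
#' Evaluates, per neuron: whether the standard depth-conflict set was used,
#' whether there are at least `min_choices_per_side` choices toward each
#' target on ambiguous trials (detection-probability eligibility), and whether
#' stationary objects were observed at every standard depth (decoding
#' eligibility). Returns the eligible id sets and a per-neuron audit log of
#' exclusion reasons.
#'
#' @param trials Long trials data frame (see [read_trials()]).
#' @param conditions A [build_condition_table()] output.
#' @param criteria A [selection_criteria()].
#' @return List with `dp_eligible`, `decoding_eligible` (character vectors of
#'   neuron ids) and `audit` (data frame: neuron_id, flags, reasons).
#' @export
apply_selection <- function(trials, conditions,
                            criteria = selection_criteria()) {
  stopifnot(inherits(criteria, "selection_criteria"))
  cond <- conditions[match(trials$condition_id, conditions$condition_id), ]
  std_deltas <- standard_delta_set()
  std_sta <- standard_stationary_depths()
  ids <- unique(trials$neuron_id)
  audit <- do.call(rbind, lapply(ids, function(id) {
    sub <- trials$neuron_id == id
    deltas_seen <- unique(cond$delta_depth_deg[sub & cond$kind == "dynamic"])
    has_std <- all(std_deltas %in% deltas_seen)
    amb <- sub & cond$kind == "dynamic" & cond$delta_depth_deg == 0
    n_in <- sum(trials$choice_in_rf[amb])
    n_out <- sum(!trials$choice_in_rf[amb])
    sta_seen <- unique(cond$d_bd_deg[sub & cond$kind == "stationary"])
    all_sta <- all(vapply(std_sta, function(d) {
      any(abs(sta_seen - d) < 1e-9)
    }, logical(1)))
    reasons <- character(0)
    if (criteria$require_standard_delta_set && !has_std) {
      reasons <- c(reasons, "nonstandard_delta_set")
    }
    dp_ok <- n_in >= criteria$min_choices_per_side &&
      n_out >= criteria$min_choices_per_side
    if (!dp_ok) reasons <- c(reasons, "min_choices")
    if (criteria$require_all_stationary_depths && !all_sta) {
      reasons <- c(reasons, "missing_stationary_depths")
    }
    data.frame(neuron_id = id, has_standard_delta_set = has_std,
               n_choices_in = n_in, n_choices_out = n_out,
               all_stationary_depths = all_sta,
               reasons = paste(reasons, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  std_ok <- if (criteria$require_standard_delta_set) {
    audit$has_standard_delta_set
  } else rep(TRUE, nrow(audit))
  dp_ok <- std_ok &
    audit$n_choices_in >= criteria$min_choices_per_side &
    audit$n_choices_out >= criteria$min_choices_per_side
  dec_ok <- std_ok & if (criteria$require_all_stationary_depths) {
    audit$all_stationary_depths
  } else rep(TRUE, nrow(audit))
  list(dp_eligible = audit$neuron_id[dp_ok],
       decoding_eligible = audit$neuron_id[dec_ok],
       audit = audit)
}
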