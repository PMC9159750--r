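# Behavioral analyses: psychometric performance curves and the per-location
# logistic choice regression on |d_BD|, |d_MP| and |delta depth|, plus a
# session generator with known regression weights for recovery studies.

#' Psychometric performance curve
#'
#' Percent correct per signed depth-conflict level with exact binomial 95%
#' confidence intervals. At zero conflict the "correct" side is an arbitrary
#' label, so performance is at chance by construction.
#'
#' @param delta_depth Depth conflict (deg) per trial.
#' @param correct Logical per trial.
#' @return Data frame with `delta_depth_deg`, `n_trials`, `percent_correct`,
#'   `ci_lo`, `ci_hi` (percent); levels with no trials are omitted.
#' @export
psychometric <- function(delta_depth, correct) {
  stopifnot(length(delta_depth) == length(correct))
  levels <- sort(unique(delta_depth))
  rows <- lapply(levels, function(d) {
    ok <- correct[delta_depth == d]
    n <- length(ok)
    if (n == 0L) return(NULL)
    bt <- stats::binom.test(sum(ok), n)
    data.frame(delta_depth_deg = d, n_trials = n,
               percent_correct = 100 * mean(ok),
               ci_lo = 100 * bt$conf.int[1], ci_hi = 100 * bt$conf.int[2])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Simulate a behavioral session with known choice-regression weights
#'
#' On each trial a dynamic object (with a depth conflict drawn from
#' `delta_set` and cue depths split about the pedestal) occupies one of two
#' locations and a stationary object (random depth from the grid) the other.
#' The probability of choosing location 1 follows the per-location logistic
#' model: intercept plus chosen-location weights on that location's `|d_BD|`,
#' `|d_MP|`, `|delta depth|` and not-chosen weights on the other location's
#' predictors.
#'
#' @param n_trials Number of trials.
#' @param beta0 Intercept.
#' @param beta_chosen,beta_notchosen Length-3 numeric vectors of weights on
#'   (`|d_BD|`, `|d_MP|`, `|delta depth|`) for the candidate location itself
#'   and for the other location.
#' @param delta_set,stationary_depths,pedestal Stimulus design values.
#' @param seed Integer seed.
#' @return Data frame with one row per trial x location: `trial_id`, `loc`,
#'   `abs_d_bd`, `abs_d_mp`, `abs_delta`, `chosen`.
#' @export
simulate_behavior_session <- function(n_trials = 400, beta0 = 0,
                                      beta_chosen = c(0.2, 0.2, 1.5),
                                      beta_notchosen = c(-0.1, -0.1, -1.5),
                                      delta_set = standard_delta_set(),
                                      stationary_depths = standard_stationary_depths(),
                                      pedestal = standard_pedestal(),
                                      seed = 1L) {
  stopifnot(length(beta_chosen) == 3L, length(beta_notchosen) == 3L)
  with_seed(seed, {
    delta <- delta_set[sample_int(length(delta_set), n_trials, replace = TRUE)]
    sp <- split_pedestal(pedestal, delta)
    sta <- stationary_depths[sample_int(length(stationary_depths), n_trials,
                                        replace = TRUE)]
    dyn_loc <- ifelse(stats::runif(n_trials) < 0.5, 1L, 2L)
    # predictors per location
    x <- function(loc) {
      is_dyn <- dyn_loc == loc
      cbind(abs_d_bd = ifelse(is_dyn, abs(sp$d_bd), abs(sta)),
            abs_d_mp = ifelse(is_dyn, abs(sp$d_mp), abs(sta)),
            abs_delta = ifelse(is_dyn, abs(delta), 0))
    }
    x1 <- x(1L); x2 <- x(2L)
    eta <- beta0 + x1 %*% beta_chosen + x2 %*% beta_notchosen
    choose1 <- stats::runif(n_trials) < stats::plogis(drop(eta))
    long <- rbind(
      data.frame(trial_id = seq_len(n_trials), loc = 1L, x1,
                 chosen = choose1),
      data.frame(trial_id = seq_len(n_trials), loc = 2L, x2,
                 chosen = !choose1)
    )
    long[order(long$trial_id, long$loc), ]
  })
}

#' Per-location logistic choice regression
#'
#' For each candidate location `i`, fits a binary logistic regression of
#' "location `i` chosen" on the `3 * N` predictors `|d_BD|`, `|d_MP|`,
#' `|delta depth|` of every location `j` (maximum likelihood, no penalty).
#' Betas are then averaged over the chosen-location terms (`j == i`) and over
#' the not-chosen terms (`j != i`). With `normalize = TRUE` each predictor is
#' z-scored before fitting so betas are per-SD effects (raw-scale fits are
#' always reported as well). Fits that fail to converge or show separation are
#' flagged and excluded from the averages.
#'
#' @param trials Long data frame as from [simulate_behavior_session()]:
#'   columns `trial_id`, `loc`, `abs_d_bd`, `abs_d_mp`, `abs_delta`, `chosen`.
#' @param normalize Z-score predictors before fitting (default TRUE).
#' @param alpha Significance level for the significant-fraction summaries.
#' @return List with `fits` (per-location coefficient tables: estimate, SE,
#'   p, on the normalized scale when `normalize`), `raw_fits`, `chosen`
#'   and `notchosen` (averaged betas, named `bd`, `mp`, `delta`),
#'   `significant_fraction` (per predictor, chosen and not-chosen terms
#'   pooled separately), `n_locations`, and `valid` (per-location logical).
#' @export
choice_regression <- function(trials, normalize = TRUE, alpha = 0.05) {
  need <- c("trial_id", "loc", "abs_d_bd", "abs_d_mp", "abs_delta", "chosen")
  if (!all(need %in% names(trials))) {
    stop("`trials` must have columns ", paste(need, collapse = ", "))
  }
  locs <- sort(unique(trials$loc))
  n_loc <- length(locs)
  if (!n_loc %in% c(2L, 4L)) stop("the design must have 2 or 4 locations")
  ids <- sort(unique(trials$trial_id))
  # wide predictor matrix: 3 predictors per location
  pred_names <- as.vector(outer(c("bd", "mp", "delta"), locs,
                                function(p, l) paste0(p, "_", l)))
  wide <- matrix(NA_real_, length(ids), 3L * n_loc,
                 dimnames = list(NULL, pred_names))
  chosen_loc <- integer(length(ids))
  for (k in seq_along(locs)) {
    sub <- trials[trials$loc == locs[k], ]
    sub <- sub[match(ids, sub$trial_id), ]
    wide[, paste0(c("bd", "mp", "delta"), "_", locs[k])] <-
      as.matrix(sub[, c("abs_d_bd", "abs_d_mp", "abs_delta")])
    chosen_loc[sub$chosen] <- locs[k]
  }
  if (anyNA(wide)) stop("every trial must have predictors for every location")

  fit_one <- function(xmat, i) {
    y <- chosen_loc == locs[i]
    df <- data.frame(y = y, xmat)
    fit <- suppressWarnings(
      stats::glm(y ~ ., data = df, family = stats::binomial())
    )
    coefs <- summary(fit)$coefficients
    valid <- fit$converged && all(abs(stats::coef(fit)[-1]) < 25)
    list(coefficients = coefs, valid = valid)
  }
  scale_x <- function(m) {
    s <- apply(m, 2L, stats::sd)
    s[s == 0] <- 1
    sweep(m, 2L, s, "/")
  }
  xin <- if (normalize) scale_x(wide) else wide
  fits <- lapply(seq_along(locs), function(i) fit_one(xin, i))
  raw_fits <- if (normalize) {
    lapply(seq_along(locs), function(i) fit_one(wide, i))
  } else fits
  valid <- vapply(fits, `[[`, logical(1), "valid")

  gather <- function(which_terms) {
    # which_terms: "chosen" (j == i) or "notchosen" (j != i)
    est <- matrix(NA_real_, 0L, 3L)
    pvals <- c()
    for (i in seq_along(locs)) {
      if (!valid[i]) next
      co <- fits[[i]]$coefficients
      js <- if (which_terms == "chosen") locs[i] else setdiff(locs, locs[i])
      for (j in js) {
        rn <- paste0(c("bd", "mp", "delta"), "_", j)
        est <- rbind(est, co[rn, "Estimate"])
        pvals <- c(pvals, co[rn, "Pr(>|z|)"])
      }
    }
    list(mean = if (nrow(est)) colMeans(est) else rep(NA_real_, 3L),
         p = pvals, n_terms = nrow(est))
  }
  ch <- gather("chosen")
  nc <- gather("notchosen")
  names(ch$mean) <- names(nc$mean) <- c("bd", "mp", "delta")
  sig_frac <- function(g) {
    if (g$n_terms == 0L) return(stats::setNames(rep(NA_real_, 3L),
                                                c("bd", "mp", "delta")))
    m <- matrix(g$p < alpha, ncol = 3L, byrow = TRUE)
    stats::setNames(colMeans(m), c("bd", "mp", "delta"))
  }
  list(fits = fits, raw_fits = raw_fits,
       chosen = ch$mean, notchosen = nc$mean,
       significant_fraction = list(chosen = sig_frac(ch),
                                   notchosen = sig_frac(nc)),
       n_locations = n_loc, valid = valid)
}

#' Confidence-interval coverage of the choice regression
#'
#' Simulates many behavioral sessions from known weights, fits the location-1
#' regression in each, and reports the fraction of sessions whose 95% Wald
#' intervals cover the true weights (location-1 chosen-location and
#' not-chosen-location terms).
#'
#' @param n_sessions Number of simulated sessions (default 200).
#' @param n_trials Trials per session (default 400).
#' @inheritParams simulate_behavior_session
#' @return Named coverage proportions for the six slope weights, plus
#'   `n_valid` sessions used.
#' @export
choice_regression_coverage <- function(n_sessions = 200, n_trials = 400,
                                       beta0 = 0,
                                       beta_chosen = c(0.2, 0.2, 1.5),
                                       beta_notchosen = c(-0.1, -0.1, -1.5),
                                       seed = 1L) {
  truth <- c(bd_1 = beta_chosen[1], mp_1 = beta_chosen[2],
             delta_1 = beta_chosen[3], bd_2 = beta_notchosen[1],
             mp_2 = beta_notchosen[2], delta_2 = beta_notchosen[3])
  seeds <- with_seed(seed, sample_int(.Machine$integer.max %/% 2, n_sessions))
  hits <- matrix(NA, n_sessions, length(truth),
                 dimnames = list(NULL, names(truth)))
  valid <- logical(n_sessions)
  for (s in seq_len(n_sessions)) {
    tr <- simulate_behavior_session(n_trials, beta0, beta_chosen,
                                    beta_notchosen, seed = seeds[s])
    res <- choice_regression(tr, normalize = FALSE)
    valid[s] <- res$valid[1]
    if (!valid[s]) next
    co <- res$fits[[1]]$coefficients
    est <- co[names(truth), "Estimate"]
    se <- co[names(truth), "Std. Error"]
    hits[s, ] <- truth >= est - 1.96 * se & truth <= est + 1.96 * se
  }
  list(coverage = colMeans(hits[valid, , drop = FALSE]),
       n_valid = sum(valid))
}
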