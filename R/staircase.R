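# Two-down/one-up adaptive staircase for 4AFC letter acuity.
#
# The letter size drops one step (0.125 logMAR by default) after two
# consecutive correct responses and rises one step after any error. Such
# a transformed up-down rule equilibrates where two successive corrects
# are as likely as not, p^2 = 1/2, i.e. at the 70.7%-correct level. A
# run ends after a fixed number of reversals (default 8) and the
# threshold is the mean of the last six reversal levels.
#
# The track itself moves on NOMINAL levels (exact multiples of the step
# below the start); what a display can actually draw is the nearest
# ACHIEVABLE level on the pixel grid, so reversal levels are logged as
# achieved values. A reversal is recorded when a level change reverses
# the direction of the previous level change, and is logged at the level
# from which the new step departs.

#' Configure a transformed up-down staircase
#'
#' @param step_logmar Step size in logMAR (default 0.125).
#' @param n_down Consecutive correct responses required before a
#'   downward (harder) step; 2 gives the 70.7% rule.
#' @param n_up Errors per upward step (1 in this design).
#' @param n_reversals_stop Reversals that end a run (default 8).
#' @param n_reversals_used Late reversals averaged for the threshold
#'   (default 6; must not exceed `n_reversals_stop`).
#' @param start_logmar Starting level (default 0.8, comfortably
#'   suprathreshold for CM letters; use ~0.2 for LM).
#' @param n_alternatives Response alternatives (4 for HOTV).
#' @param max_trials Safety cap on trials per run (default 200); runs
#'   ended by the cap are flagged unconverged.
#' @return A `staircase_config`.
#' @export
staircase_config <- function(step_logmar = 0.125, n_down = 2, n_up = 1,
                             n_reversals_stop = 8, n_reversals_used = 6,
                             start_logmar = 0.8, n_alternatives = 4,
                             max_trials = 200) {
  if (step_logmar <= 0) nl_stop("step_logmar must be > 0")
  if (n_down < 1 || n_up != 1) {
    nl_stop("only n-down/1-up rules are supported (n_down >= 1, n_up = 1)")
  }
  if (n_reversals_used > n_reversals_stop) {
    nl_stop("n_reversals_used (", n_reversals_used,
            ") cannot exceed n_reversals_stop (", n_reversals_stop, ")")
  }
  if (max_trials < 1) nl_stop("max_trials must be >= 1")
  structure(
    list(step_logmar = step_logmar,
         n_down = as.integer(n_down), n_up = as.integer(n_up),
         n_reversals_stop = as.integer(n_reversals_stop),
         n_reversals_used = as.integer(n_reversals_used),
         start_logmar = start_logmar,
         n_alternatives = as.integer(n_alternatives),
         max_trials = as.integer(max_trials)),
    class = "staircase_config"
  )
}

#' Initialise a staircase state
#'
#' @param config A [staircase_config()].
#' @param min_level Optional floor on the nominal level (e.g. the
#'   geometry floor); downward steps stop there.
#' @return A `staircase_state`.
#' @export
staircase_new <- function(config, min_level = -Inf) {
  structure(
    list(level = config$start_logmar,
         consecutive_correct = 0L,
         last_direction = "none",
         reversal_levels = numeric(0),
         n_trials = 0L,
         min_level = min_level,
         finished = FALSE),
    class = "staircase_state"
  )
}

#' @export
print.staircase_state <- function(x, ...) {
  cat(sprintf(paste0("<staircase_state> level %+.3f logMAR, %d trials, ",
                     "%d reversals%s\n"),
              x$level, x$n_trials, length(x$reversal_levels),
              if (x$finished) " (finished)" else ""))
  invisible(x)
}

#' Apply one response to a staircase
#'
#' Two consecutive correct responses move the level down one step and
#' reset the counter; any error moves it up one step and resets the
#' counter; a single correct response only advances the counter. When a
#' level change reverses the direction of the previous change, the level
#' the step departs from (its achieved value, if supplied) is appended to
#' the reversal record. The run finishes at `n_reversals_stop` reversals
#' or `max_trials` trials.
#'
#' @param state A `staircase_state` (not finished).
#' @param correct Logical response for the current trial.
#' @param config The [staircase_config()].
#' @param achieved_level The achieved (post-quantisation) level actually
#'   presented on this trial; defaults to the nominal level. Used for
#'   reversal logging only.
#' @return The updated `staircase_state`.
#' @export
#' @examples
#' cfg <- staircase_config(start_logmar = 0.5)
#' st <- staircase_new(cfg)
#' for (r in c(TRUE, TRUE, FALSE)) st <- staircase_update(st, r, cfg)
#' st$reversal_levels # one reversal, at 0.375
staircase_update <- function(state, correct, config,
                             achieved_level = state$level) {
  if (state$finished) nl_stop("staircase already finished")
  state$n_trials <- state$n_trials + 1L
  delta <- 0
  if (correct) {
    state$consecutive_correct <- state$consecutive_correct + 1L
    if (state$consecutive_correct >= config$n_down) {
      delta <- -config$step_logmar
      state$consecutive_correct <- 0L
    }
  } else {
    delta <- config$step_logmar
    state$consecutive_correct <- 0L
  }
  if (delta != 0) {
    new_level <- max(state$min_level, state$level + delta)
    if (new_level != state$level) {
      direction <- if (delta < 0) "down" else "up"
      if (state$last_direction != "none" &&
          direction != state$last_direction) {
        state$reversal_levels <- c(state$reversal_levels, achieved_level)
      }
      state$last_direction <- direction
      state$level <- new_level
    }
  }
  if (length(state$reversal_levels) >= config$n_reversals_stop ||
      state$n_trials >= config$max_trials) {
    state$finished <- TRUE
  }
  state
}

#' Estimate the acuity threshold from a finished staircase
#'
#' The threshold is the arithmetic mean of the last `n_reversals_used`
#' reversal levels (in logMAR). A run that ended with fewer reversals
#' than that (e.g. stopped by the trial cap) is estimated from all
#' available reversals and flagged `converged = FALSE`.
#'
#' @param state A finished `staircase_state`.
#' @param config The [staircase_config()].
#' @return A `threshold_estimate` with fields `threshold_logmar`,
#'   `reversal_levels_used`, `n_trials`, `converged`.
#' @export
estimate_threshold <- function(state, config) {
  rev <- state$reversal_levels
  if (length(rev) == 0) {
    nl_stop("cannot estimate a threshold from a run with no reversals")
  }
  n_use <- min(config$n_reversals_used, length(rev))
  used <- utils::tail(rev, n_use)
  converged <- length(rev) >= config$n_reversals_stop &&
    length(rev) >= config$n_reversals_used
  structure(
    list(threshold_logmar = mean(used),
         reversal_levels_used = used,
         n_trials = state$n_trials,
         converged = converged),
    class = "threshold_estimate"
  )
}

#' @export
print.threshold_estimate <- function(x, ...) {
  cat(sprintf("<threshold_estimate> %+.4f logMAR from %d reversals, %d trials%s\n",
              x$threshold_logmar, length(x$reversal_levels_used), x$n_trials,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' Run a full adaptive staircase against a simulated observer
#'
#' Repeats present -> respond -> update until the run finishes. On each
#' trial a letter is drawn uniformly from HOTV, the nominal level is
#' quantised to the nearest achievable letter size for the geometry
#' (clamped at the geometry floor), and the observer responds: a
#' [psychometric_observer()] via its psychometric function, a
#' [template_observer()] via template matching on a stimulus built by
#' `stim_factory`.
#'
#' @param observer A [psychometric_observer()] or [template_observer()].
#' @param geometry A [viewing_geometry()].
#' @param config A [staircase_config()].
#' @param seed Integer seed for letter order and responses.
#' @param stim_factory For template observers: a
#'   `function(letter, level)` returning a `stimulus_frame` or
#'   `stimulus_movie`, where `level` is the achieved `acuity_level`.
#' @param letters Response alphabet (default HOTV).
#' @return A list with `estimate` (a [estimate_threshold()] result),
#'   `state` (final `staircase_state`) and `trials` (a data frame with
#'   one row per trial: `trial_index`, `nominal_logmar`,
#'   `achieved_logmar`, `letter`, `response`, `correct`,
#'   `reversal_flag`).
#' @export
#' @examples
#' run <- run_staircase(psychometric_observer(0.3),
#'                      viewing_geometry(4.5, side_quantum = 1),
#'                      staircase_config(), seed = 11)
#' run$estimate$threshold_logmar
run_staircase <- function(observer, geometry, config, seed,
                          stim_factory = NULL, letters = hotv_letters) {
  if (missing(seed)) nl_stop("run_staircase requires an explicit seed")
  is_template <- inherits(observer, "template_observer")
  if (is_template && is.null(stim_factory)) {
    nl_stop("a template observer needs a stim_factory")
  }
  floor_logmar <- geometry_floor(geometry)$logmar
  state <- staircase_new(config, min_level = floor_logmar)
  n_cap <- config$max_trials
  nominal <- numeric(n_cap); achieved <- numeric(n_cap)
  shown <- character(n_cap); resp <- character(n_cap)
  corr <- logical(n_cap); revflag <- logical(n_cap)
  with_seed(seed, {
    while (!state$finished) {
      i <- state$n_trials + 1L
      letter <- letters[sample.int(length(letters), 1)]
      lv <- logmar_to_size(state$level, geometry, clamp = TRUE)
      response <- if (is_template) {
        template_respond(observer, stim_factory(letter, lv))
      } else {
        respond(observer, letter, lv$logmar, letters)
      }
      n_rev_before <- length(state$reversal_levels)
      nominal[i] <- state$level
      achieved[i] <- lv$logmar
      state <- tryCatch(
        staircase_update(state, response == letter, config,
                         achieved_level = lv$logmar),
        error = function(e) {
          nl_stop("staircase update failed at trial ", i, " (letter ",
                  letter, ", level ", format(lv$logmar), "): ",
                  conditionMessage(e))
        }
      )
      shown[i] <- letter; resp[i] <- response
      corr[i] <- response == letter
      revflag[i] <- length(state$reversal_levels) > n_rev_before
    }
  })
  n <- state$n_trials
  trials <- data.frame(
    trial_index = seq_len(n),
    nominal_logmar = nominal[seq_len(n)],
    achieved_logmar = achieved[seq_len(n)],
    letter = shown[seq_len(n)],
    response = resp[seq_len(n)],
    correct = corr[seq_len(n)],
    reversal_flag = revflag[seq_len(n)],
    stringsAsFactors = FALSE
  )
  est <- if (length(state$reversal_levels) == 0) {
    # e.g. a perfect observer rides the geometry floor without reversing
    structure(list(threshold_logmar = NA_real_,
                   reversal_levels_used = numeric(0),
                   n_trials = state$n_trials, converged = FALSE),
              class = "threshold_estimate")
  } else {
    estimate_threshold(state, config)
  }
  list(estimate = est, state = state, trials = trials)
}

#' Average threshold estimates over repeated runs
#'
#' @param estimates A numeric vector of thresholds (logMAR) or a list of
#'   `threshold_estimate` objects (typically 4 runs per condition).
#' @return A list with `mean_logmar`, `se_logmar`, `n`.
#' @export
#' @examples
#' average_runs(c(0.3, 0.5)) # mean 0.4, SE 0.1
average_runs <- function(estimates) {
  if (is.list(estimates)) {
    estimates <- vapply(estimates, function(e) {
      if (inherits(e, "threshold_estimate")) e$threshold_logmar
      else as.numeric(e)
    }, 0)
  }
  if (length(estimates) == 0) nl_stop("no run estimates to average")
  list(mean_logmar = mean(estimates),
       se_logmar = std_error(estimates),
       n = length(estimates))
}

#' Equilibrium percent correct of an n-down/1-up rule (closed form)
#'
#' At equilibrium a downward step (n consecutive corrects) is as likely
#' as an upward one, so p^n = 1/2 and p = 0.5^(1/n): 70.71% for the
#' 2-down/1-up rule, 79.37% for 3-down/1-up.
#'
#' @param n_down Consecutive corrects required per downward step.
#' @return Equilibrium probability correct (not percent).
#' @export
updown_equilibrium_p <- function(n_down) 0.5^(1 / n_down)

#' Monte-Carlo probe of the staircase convergence point
#'
#' Runs the up-down rule without a stopping criterion against a
#' stationary psychometric observer for `n_trials` trials, then measures
#' the observed percent correct at the equilibrium level (the most
#' visited nominal level after burn-in). By default the observer's
#' 70.7% point sits exactly on the staircase level grid (four steps
#' below the start), so the probe estimates the percent correct the
#' track equilibrates at; the analytic value is
#' `100 * 0.5^(1/n_down)`.
#'
#' @param config A [staircase_config()].
#' @param n_trials Number of simulated trials (default 50000).
#' @param seed Integer seed.
#' @param observer Optional [psychometric_observer()]; default anchored
#'   four steps below `start_logmar`.
#' @param burn_in Trials discarded before measuring (default 500).
#' @return A list with `percent_correct` (at the equilibrium level),
#'   `percent_correct_overall`, `equilibrium_level`,
#'   `analytic_percent` and `n_trials_at_equilibrium`.
#' @export
#' @examples
#' probe <- convergence_probe(staircase_config(), n_trials = 5000, seed = 1)
#' probe$percent_correct
convergence_probe <- function(config, n_trials = 50000, seed = 1,
                              observer = NULL, burn_in = 500) {
  if (is.null(observer)) {
    observer <- psychometric_observer(
      alpha_logmar = config$start_logmar - 4 * config$step_logmar
    )
  }
  if (burn_in >= n_trials) nl_stop("burn_in must be smaller than n_trials")
  levels_seen <- numeric(n_trials)
  correct_seen <- logical(n_trials)
  with_seed(seed, {
    level <- config$start_logmar
    cc <- 0L
    p_cache <- new.env(parent = emptyenv())
    for (i in seq_len(n_trials)) {
      key <- sprintf("%.6f", level)
      p <- p_cache[[key]]
      if (is.null(p)) {
        p <- p_correct(observer, level)
        p_cache[[key]] <- p
      }
      ok <- stats::runif(1) < p
      levels_seen[i] <- level
      correct_seen[i] <- ok
      if (ok) {
        cc <- cc + 1L
        if (cc >= config$n_down) {
          level <- level - config$step_logmar
          cc <- 0L
        }
      } else {
        level <- level + config$step_logmar
        cc <- 0L
      }
    }
  })
  keep <- seq.int(burn_in + 1L, n_trials)
  lv <- levels_seen[keep]; ok <- correct_seen[keep]
  tab <- table(sprintf("%.6f", lv))
  eq_key <- names(tab)[which.max(tab)]
  at_eq <- sprintf("%.6f", lv) == eq_key
  list(percent_correct = 100 * mean(ok[at_eq]),
       percent_correct_overall = 100 * mean(ok),
       equilibrium_level = as.numeric(eq_key),
       analytic_percent = 100 * updown_equilibrium_p(config$n_down),
       n_trials_at_equilibrium = sum(at_eq))
}
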