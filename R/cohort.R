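# Cohort simulation emulating a two-group noise-letter acuity study:
# two groups of five participants (older / younger), four conditions
# (LM/CM letters x monocular/binocular viewing), four staircase runs per
# condition, and an optional neutral-density (ND) filter scenario with
# 19% light transmission.

#' Default per-condition true acuity means and standard errors
#'
#' The group-level condition means (logMAR) and their standard errors
#' that the cohort generator reproduces by default, one row per
#' group x stimulus type x viewing cell. Between-subject SDs are derived
#' as `SE * sqrt(n)` with n = 5 participants per group.
#'
#' @return A data frame with columns `group`, `stimulus_type`,
#'   `viewing`, `mean_logmar`, `se_logmar`.
#' @export
default_condition_table <- function() {
  data.frame(
    group = rep(c("older", "younger"), each = 4),
    stimulus_type = rep(c("LM", "LM", "CM", "CM"), 2),
    viewing = rep(c("monocular", "binocular"), 4),
    mean_logmar = c(-0.12, -0.15, 0.44, 0.39,
                    -0.18, -0.24, 0.34, 0.20),
    se_logmar = c(0.06, 0.07, 0.02, 0.03,
                  0.04, 0.04, 0.05, 0.03),
    stringsAsFactors = FALSE
  )
}

#' Default viewing geometries per stimulus type
#'
#' LM letters are viewed at 9 m, CM letters at 4.5 m, both on a display
#' with 0.47 mm pixels. Simulated staircases use a 1-pixel letter-side
#' quantum (fractional-pixel noise checks), which keeps the achievable
#' acuity grid fine near threshold; see the methods vignette.
#'
#' @param side_quantum Letter-side quantum in pixels (default 1).
#' @return Named list of [viewing_geometry()] objects (`LM`, `CM`).
#' @export
default_geometries <- function(side_quantum = 1) {
  list(LM = viewing_geometry(9, side_quantum = side_quantum),
       CM = viewing_geometry(4.5, side_quantum = side_quantum))
}

#' Default staircase start levels per stimulus type
#'
#' Comfortably suprathreshold starting letter sizes: 0.2 logMAR for LM,
#' 0.8 logMAR for CM.
#'
#' @return Named numeric vector.
#' @export
default_start_levels <- function() c(LM = 0.2, CM = 0.8)

#' Specify a simulated study cohort
#'
#' @param n_per_group Participants per group (default 5).
#' @param condition_table Data frame like [default_condition_table()];
#'   `se_logmar` may be replaced by an explicit `between_sd_logmar`
#'   column.
#' @param run_sd Within-participant run-to-run SD of the true threshold
#'   (logMAR, default 0.05).
#' @param n_runs Staircase runs averaged per condition (default 4).
#' @param nd_transmission Light transmission of the ND filter scenario
#'   (0.19 for the 85N6 filter; 1 = no filter).
#' @param nd_coefficient Threshold elevation per log10 unit of light
#'   attenuation (logMAR per log10; default 0: acuity unaffected by the
#'   filter, the empirical outcome this design emulates).
#' @param slope,lapse_rate Psychometric parameters given to every
#'   simulated participant.
#' @return A `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 5,
                        condition_table = default_condition_table(),
                        run_sd = 0.05, n_runs = 4,
                        nd_transmission = 1, nd_coefficient = 0,
                        slope = 0.16, lapse_rate = 0.01) {
  need <- c("group", "stimulus_type", "viewing", "mean_logmar")
  if (!all(need %in% names(condition_table))) {
    nl_stop("condition_table needs columns ", paste(need, collapse = ", "))
  }
  if (is.null(condition_table$between_sd_logmar)) {
    if (is.null(condition_table$se_logmar)) {
      nl_stop("condition_table needs se_logmar or between_sd_logmar")
    }
    condition_table$between_sd_logmar <-
      condition_table$se_logmar * sqrt(n_per_group)
  }
  if (run_sd < 0) nl_stop("run_sd must be >= 0")
  if (any(condition_table$between_sd_logmar < 0)) {
    nl_stop("between-subject SDs must be >= 0")
  }
  if (nd_transmission <= 0 || nd_transmission > 1) {
    nl_stop("nd_transmission must lie in (0, 1]")
  }
  structure(
    list(n_per_group = as.integer(n_per_group),
         condition_table = condition_table,
         run_sd = run_sd,
         n_runs = as.integer(n_runs),
         nd_transmission = nd_transmission,
         nd_coefficient = nd_coefficient,
         slope = slope,
         lapse_rate = lapse_rate),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat("<cohort_spec> ", x$n_per_group, " participants x ",
      length(unique(x$condition_table$group)), " groups, ",
      nrow(x$condition_table) / length(unique(x$condition_table$group)),
      " conditions, ", x$n_runs, " runs/condition\n", sep = "")
  invisible(x)
}

# threshold elevation induced by an ND filter of given transmission
nd_threshold_shift <- function(coefficient, transmission) {
  coefficient * log10(1 / transmission)
}

condition_cell <- function(spec, group, stimulus_type, viewing) {
  ct <- spec$condition_table
  row <- ct[ct$group == group & ct$stimulus_type == stimulus_type &
              ct$viewing == viewing, ]
  if (nrow(row) != 1) {
    nl_stop("condition_table has no (or duplicated) cell for group=",
            group, ", stimulus_type=", stimulus_type, ", viewing=", viewing)
  }
  row
}

# simulate the n_runs staircases of one participant x condition and
# return the averaged threshold
simulate_condition_runs <- function(spec, true_alpha, stimulus_type,
                                    staircase_cfg, geometries,
                                    start_levels, seed) {
  geom <- geometries[[stimulus_type]]
  cfg <- staircase_cfg
  cfg$start_logmar <- unname(start_levels[[stimulus_type]])
  ests <- vapply(seq_len(spec$n_runs), function(r) {
    jitter <- if (spec$run_sd > 0) {
      with_seed(derive_seed(seed, "jitter", r),
                stats::rnorm(1, 0, spec$run_sd))
    } else 0
    obs <- psychometric_observer(true_alpha + jitter,
                                 slope = spec$slope,
                                 lapse_rate = spec$lapse_rate)
    run_staircase(obs, geom, cfg,
                  seed = derive_seed(seed, "run", r))$estimate$threshold_logmar
  }, 0)
  list(threshold = mean(ests), runs = ests)
}

#' Simulate a full study cohort
#'
#' For every participant x condition cell, draws a true threshold from
#' `Normal(cell mean, between-subject SD)`, builds a
#' [psychometric_observer()] around it, runs `n_runs` adaptive
#' staircases (with run-level threshold jitter of SD `run_sd`) through
#' the stimulus-type-specific viewing geometry, and records the averaged
#' threshold. An ND-filter scenario (`nd_transmission < 1`) shifts every
#' true threshold by `nd_coefficient * log10(1/transmission)`.
#'
#' All randomness is driven by sub-seeds derived from `seed`, so the
#' result is bit-reproducible and independent of evaluation order.
#'
#' @param spec A [cohort_spec()].
#' @param staircase_cfg A [staircase_config()]; its start level is
#'   overridden per stimulus type by `start_levels`.
#' @param geometries Named list of [viewing_geometry()] per stimulus
#'   type, default [default_geometries()].
#' @param start_levels Named start levels per stimulus type, default
#'   [default_start_levels()].
#' @param seed Master integer seed.
#' @param keep_trials If `TRUE`, attach per-run trial logs as attribute
#'   `"trial_log"`.
#' @return A data frame (one row per participant x condition) with
#'   columns `participant_id`, `group`, `stimulus_type`, `viewing`,
#'   `nd_filter`, `threshold_logmar`, `n_runs`.
#' @export
#' @examples
#' \donttest{
#' cohort <- simulate_cohort(cohort_spec(n_per_group = 2), seed = 1)
#' }
simulate_cohort <- function(spec, staircase_cfg = staircase_config(),
                            geometries = default_geometries(),
                            start_levels = default_start_levels(),
                            seed, keep_trials = FALSE) {
  if (missing(seed)) nl_stop("simulate_cohort requires an explicit seed")
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- unique(spec$condition_table$group)
  conds <- unique(spec$condition_table[, c("stimulus_type", "viewing")])
  nd_on <- spec$nd_transmission < 1
  shift <- nd_threshold_shift(spec$nd_coefficient, spec$nd_transmission)
  rows <- list()
  logs <- list()
  for (g in groups) {
    for (i in seq_len(spec$n_per_group)) {
      pid <- paste0(substr(g, 1, 1), i)
      for (ci in seq_len(nrow(conds))) {
        st <- conds$stimulus_type[ci]; vw <- conds$viewing[ci]
        cell <- condition_cell(spec, g, st, vw)
        alpha <- with_seed(derive_seed(seed, "alpha", g, i, st, vw),
                           stats::rnorm(1, cell$mean_logmar,
                                        cell$between_sd_logmar)) + shift
        res <- simulate_condition_runs(
          spec, alpha, st, staircase_cfg, geometries, start_levels,
          seed = derive_seed(seed, "cond", g, i, st, vw)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = g, stimulus_type = st,
          viewing = vw, nd_filter = nd_on,
          threshold_logmar = res$threshold, n_runs = spec$n_runs,
          stringsAsFactors = FALSE
        )
        if (keep_trials) {
          logs[[length(logs) + 1L]] <- data.frame(
            participant_id = pid, group = g, stimulus_type = st,
            viewing = vw, run = seq_along(res$runs),
            threshold_logmar = res$runs, stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  out <- do.call(rbind, rows)
  if (keep_trials) attr(out, "trial_log") <- do.call(rbind, logs)
  out
}

#' Simulate the neutral-density filter control experiment
#'
#' Re-tests a subset of younger participants with and without an ND
#' filter (19% transmission by default), holding each participant's true
#' thresholds fixed across the two passes, as in a within-subject
#' control. With the default `nd_coefficient = 0` the two passes differ
#' only by staircase sampling noise.
#'
#' @param spec A [cohort_spec()].
#' @param n_participants Number of younger participants re-tested
#'   (default 3).
#' @param transmission ND filter transmission (default 0.19).
#' @inheritParams simulate_cohort
#' @return A data frame like [simulate_cohort()]'s with an `nd_filter`
#'   logical column distinguishing the two passes.
#' @export
simulate_nd_control <- function(spec, n_participants = 3,
                                transmission = 0.19,
                                staircase_cfg = staircase_config(),
                                geometries = default_geometries(),
                                start_levels = default_start_levels(),
                                seed) {
  if (missing(seed)) nl_stop("simulate_nd_control requires an explicit seed")
  shift <- nd_threshold_shift(spec$nd_coefficient, transmission)
  conds <- unique(spec$condition_table[, c("stimulus_type", "viewing")])
  rows <- list()
  for (i in seq_len(n_participants)) {
    pid <- paste0("y", i)
    for (ci in seq_len(nrow(conds))) {
      st <- conds$stimulus_type[ci]; vw <- conds$viewing[ci]
      cell <- condition_cell(spec, "younger", st, vw)
      alpha <- with_seed(derive_seed(seed, "alpha", "younger", i, st, vw),
                         stats::rnorm(1, cell$mean_logmar,
                                      cell$between_sd_logmar))
      for (nd in c(FALSE, TRUE)) {
        res <- simulate_condition_runs(
          spec, alpha + if (nd) shift else 0, st, staircase_cfg,
          geometries, start_levels,
          seed = derive_seed(seed, "nd", nd, i, st, vw)
        )
        rows[[length(rows) + 1L]] <- data.frame(
          participant_id = pid, group = "younger", stimulus_type = st,
          viewing = vw, nd_filter = nd,
          threshold_logmar = res$threshold, n_runs = spec$n_runs,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  do.call(rbind, rows)
}

#' Write or read a cohort result table as CSV
#'
#' Plain comma-separated UTF-8 with a header row, mirroring the layout
#' of deposited per-participant acuity tables (participant, group,
#' stimulus type, viewing, VA in logMAR), so externally downloaded
#' tables with these columns load interchangeably.
#'
#' @param cohort A cohort result data frame.
#' @param path File path.
#' @return `read_cohort_csv` returns the data frame; `write_cohort_csv`
#'   returns `path` invisibly.
#' @export
write_cohort_csv <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort_csv
#' @export
read_cohort_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("participant_id", "group", "stimulus_type", "viewing",
            "threshold_logmar")
  if (!all(need %in% names(df))) {
    nl_stop("cohort CSV must have columns ", paste(need, collapse = ", "))
  }
  df
}
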