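# Experiment configuration: defaults, YAML/JSON loading, validation.

#' Default end-to-end experiment configuration
#'
#' Nested list with one block per stage. Field names mirror the
#' constructors' arguments ([stimulus_spec()], [viewing_geometry()],
#' [staircase_config()], [cohort_spec()]). Geometry and start levels are
#' per stimulus type: LM letters at 9 m starting at 0.2 logMAR, CM
#' letters at 4.5 m starting at 0.8 logMAR.
#'
#' @return A named list (class `experiment_config`).
#' @export
default_config <- function() {
  structure(list(
    stimulus = list(
      mean_luminance = 1,
      noise_contrast = 0.2,
      luminance_amplitude = 0.3,
      contrast_amplitude = 1.0,
      bipolar_modulation = FALSE
    ),
    geometry = list(
      LM = list(distance_m = 9, pixel_pitch_mm = 0.47,
                checks_per_stroke = 3, side_quantum = 1),
      CM = list(distance_m = 4.5, pixel_pitch_mm = 0.47,
                checks_per_stroke = 3, side_quantum = 1)
    ),
    staircase = list(
      step_logmar = 0.125, n_down = 2, n_up = 1,
      n_reversals_stop = 8, n_reversals_used = 6,
      n_alternatives = 4, max_trials = 200,
      start_logmar = list(LM = 0.2, CM = 0.8)
    ),
    cohort = list(
      n_per_group = 5, n_runs = 4, run_sd = 0.05,
      nd_transmission = 1, nd_coefficient = 0,
      slope = 0.16, lapse_rate = 0.01
    ),
    seed = 1,
    out_dir = "noisyletters-out"
  ), class = "experiment_config")
}

# recursively overlay user values onto defaults, rejecting unknown keys
merge_config <- function(defaults, user, path = character(0)) {
  if (is.null(user)) return(defaults)
  if (!is.list(user)) {
    nl_stop("config key '", paste(path, collapse = "."),
            "' must be a block, got a scalar")
  }
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown)) {
    nl_stop("unknown config key",
            if (length(unknown) > 1) "s" else "", ": ",
            paste(paste(c(path, ""), collapse = "."), unknown,
                  sep = "", collapse = ", "))
  }
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]]))) {
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]], c(path, k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

validate_config <- function(config) {
  # constructing the stage objects runs every invariant check
  cfg_stimulus_spec(config, "LM")
  cfg_stimulus_spec(config, "CM")
  for (st in names(config$geometry)) cfg_geometry(config, st)
  for (st in names(config$staircase$start_logmar)) {
    cfg_staircase(config, st)
  }
  cfg_cohort_spec(config)
  if (!is.numeric(config$seed) || length(config$seed) != 1) {
    nl_stop("config key 'seed' must be a single number")
  }
  invisible(config)
}

#' Load an experiment configuration from YAML or JSON
#'
#' Unspecified keys take their defaults from [default_config()]; unknown
#' keys are rejected with their key path. An empty file yields the full
#' default configuration. Validation constructs every stage object, so
#' any invariant violation (e.g. `noise_contrast` above 1) errors at
#' load time.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A validated `experiment_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) nl_stop("config file not found: ", path)
  user <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  cfg <- merge_config(default_config(), user)
  class(cfg) <- "experiment_config"
  validate_config(cfg)
  cfg
}

#' Save an experiment configuration
#'
#' Writes YAML or JSON (by extension); [load_config()] round-trips the
#' result losslessly.
#'
#' @param config An `experiment_config`.
#' @param path Output path (`.yaml`/`.yml` or `.json`).
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  u <- unclass(config)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(u, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(u, path)
  }
  invisible(path)
}

# stable short hash of a configuration (provenance tag in outputs)
config_hash <- function(config) {
  ser <- paste(deparse(unclass(config)), collapse = "")
  h1 <- 0; h2 <- 0
  for (v in utf8ToInt(ser)) {
    h1 <- (h1 * 131 + v) %% 2147483647
    h2 <- (h2 * 137 + v) %% 2147483629
  }
  sprintf("%08x%08x", as.integer(h1), as.integer(h2))
}

# ---- constructors from config blocks ----

cfg_stimulus_spec <- function(config, stimulus_type) {
  s <- config$stimulus
  stimulus_spec(stimulus_type,
                mean_luminance = s$mean_luminance,
                noise_contrast = s$noise_contrast,
                luminance_amplitude =
                  if (stimulus_type == "LM") s$luminance_amplitude else 0,
                contrast_amplitude =
                  if (stimulus_type == "CM") s$contrast_amplitude else 0,
                bipolar_modulation = s$bipolar_modulation)
}

cfg_geometry <- function(config, stimulus_type) {
  g <- config$geometry[[stimulus_type]]
  if (is.null(g)) nl_stop("no geometry block for stimulus type ", stimulus_type)
  viewing_geometry(g$distance_m, g$pixel_pitch_mm, g$checks_per_stroke,
                   g$side_quantum)
}

cfg_staircase <- function(config, stimulus_type) {
  s <- config$staircase
  staircase_config(step_logmar = s$step_logmar, n_down = s$n_down,
                   n_up = s$n_up, n_reversals_stop = s$n_reversals_stop,
                   n_reversals_used = s$n_reversals_used,
                   start_logmar = s$start_logmar[[stimulus_type]],
                   n_alternatives = s$n_alternatives,
                   max_trials = s$max_trials)
}

cfg_cohort_spec <- function(config) {
  ch <- config$cohort
  cohort_spec(n_per_group = ch$n_per_group, run_sd = ch$run_sd,
              n_runs = ch$n_runs, nd_transmission = ch$nd_transmission,
              nd_coefficient = ch$nd_coefficient, slope = ch$slope,
              lapse_rate = ch$lapse_rate)
}
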