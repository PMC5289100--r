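# Simulated observers.
#
# The parametric observer answers a 4AFC letter-identification trial
# correctly with probability
#
#   p(level) = guess + (1 - guess - lapse) * F((level - alpha) / slope)
#
# where F is a Weibull-type sigmoid on the logMAR axis, rescaled so that
# p(alpha) = sqrt(1/2) = 0.7071 exactly. Anchoring the psychometric
# function at the 70.7%-correct point makes alpha directly comparable to
# the convergence point of a two-down/one-up staircase: an unbiased
# staircase should recover alpha.
#
# The template observer works in the image domain instead: it correlates
# a (possibly noise-perturbed) decision map with the four letter
# templates and picks the best match. A linear (pixel-correlation) rule
# can read LM letters but is blind in expectation to CM letters, whose
# mean luminance equals the background everywhere; a rectified contrast
# map (|luminance - I|) recovers them - the classic filter-rectify-filter
# account of second-order vision.

P_TARGET <- sqrt(0.5)  # 2-down/1-up convergence probability

#' Create a parametric psychometric observer
#'
#' @param alpha_logmar Acuity level (logMAR) at which the observer is
#'   70.71% correct, i.e. the 2-down/1-up convergence point.
#' @param slope Spread of the psychometric function on the logMAR axis
#'   (default 0.16, an equivalent Weibull size exponent of about 6;
#'   smaller is steeper).
#' @param guess_rate Probability correct by guessing; 0.25 for 4AFC.
#' @param lapse_rate Stimulus-independent error rate (default 0.01, max
#'   0.05).
#' @return A `psychometric_observer`.
#' @export
#' @examples
#' obs <- psychometric_observer(0.3)
#' p_correct(obs, 0.3) # 0.7071
psychometric_observer <- function(alpha_logmar, slope = 0.16,
                                  guess_rate = 0.25, lapse_rate = 0.01) {
  if (!is.finite(alpha_logmar)) nl_stop("alpha_logmar must be finite")
  if (slope <= 0) nl_stop("slope must be > 0")
  if (guess_rate <= 0 || guess_rate >= 1) nl_stop("guess_rate must be in (0, 1)")
  if (lapse_rate < 0 || lapse_rate > 0.05) {
    nl_stop("lapse_rate must lie in [0, 0.05]")
  }
  f0 <- (P_TARGET - guess_rate) / (1 - guess_rate - lapse_rate)
  if (f0 <= 0 || f0 >= 1) {
    nl_stop("guess and lapse rates leave no room for the 70.7% anchor")
  }
  structure(
    list(alpha_logmar = alpha_logmar,
         slope = slope,
         guess_rate = guess_rate,
         lapse_rate = lapse_rate,
         # F(z) = 1 - exp(-k * 10^(z / slope)); k makes F(0) hit the anchor
         k = -log(1 - f0)),
    class = "psychometric_observer"
  )
}

#' @export
print.psychometric_observer <- function(x, ...) {
  cat(sprintf(paste0("<psychometric_observer> alpha = %+.3f logMAR, ",
                     "slope = %.3f, guess = %.2f, lapse = %.3f\n"),
              x$alpha_logmar, x$slope, x$guess_rate, x$lapse_rate))
  invisible(x)
}

#' Probability of a correct 4AFC response at a given level
#'
#' Monotone non-decreasing in `level_logmar` (larger letters are easier),
#' with floor `guess_rate`, ceiling `1 - lapse_rate`, and
#' `p(alpha_logmar) = 0.70710678` exactly.
#'
#' @param observer A [psychometric_observer()].
#' @param level_logmar Presented acuity level(s), logMAR.
#' @return Probability vector.
#' @export
p_correct <- function(observer, level_logmar) {
  stopifnot(inherits(observer, "psychometric_observer"))
  z <- (level_logmar - observer$alpha_logmar) / observer$slope
  f <- 1 - exp(-observer$k * 10^z)
  observer$guess_rate +
    (1 - observer$guess_rate - observer$lapse_rate) * f
}

#' Simulate one 4AFC response
#'
#' The observer answers correctly with probability
#' [p_correct()]; otherwise it errs uniformly among the other three
#' letters. Uses the current RNG stream (seed at the run level).
#'
#' @param observer A [psychometric_observer()].
#' @param presented_letter The letter shown.
#' @param level_logmar The achieved (post-quantisation) level shown.
#' @param letters The response alphabet (default HOTV).
#' @return A single response letter.
#' @export
respond <- function(observer, presented_letter, level_logmar,
                    letters = hotv_letters) {
  p <- p_correct(observer, level_logmar)
  if (stats::runif(1) < p) {
    presented_letter
  } else {
    others <- letters[letters != presented_letter]
    others[sample.int(length(others), 1)]
  }
}

#' Create an image-domain template-matching observer
#'
#' @param decision_rule `"pixel_correlation"` (linear pooling of
#'   luminance, suited to LM letters) or
#'   `"rectified_contrast_correlation"` (correlates the rectified local
#'   contrast map `|luminance - I|` with the templates, required for CM
#'   letters).
#' @param internal_noise_sd Gaussian noise added to the decision map, in
#'   luminance units per check (default 0).
#' @return A `template_observer`.
#' @export
template_observer <- function(decision_rule = c("pixel_correlation",
                                                "rectified_contrast_correlation"),
                              internal_noise_sd = 0) {
  decision_rule <- match.arg(decision_rule)
  if (internal_noise_sd < 0) nl_stop("internal_noise_sd must be >= 0")
  structure(list(decision_rule = decision_rule,
                 internal_noise_sd = internal_noise_sd),
            class = "template_observer")
}

# decision map of one frame at check resolution: centred letter-sized
# region of the luminance (linear rule) or rectified contrast (CM rule)
frame_decision_map <- function(frame, rule) {
  v <- frame$noise$values
  spec <- frame$spec
  img <- spec$mean_luminance * (1 +
    spec$noise_contrast * v +
    spec$luminance_amplitude *
      modulation_support(frame$template, nrow(v), ncol(v),
                         spec$bipolar_modulation) +
    spec$contrast_amplitude * spec$noise_contrast *
      modulation_support(frame$template, nrow(v), ncol(v),
                         spec$bipolar_modulation) * v)
  side <- nrow(frame$template$check_grid)
  oy <- floor((nrow(v) - side) / 2)
  ox <- floor((ncol(v) - side) / 2)
  region <- img[oy + seq_len(side), ox + seq_len(side)]
  if (rule == "rectified_contrast_correlation") {
    abs(region - spec$mean_luminance)
  } else {
    region
  }
}

#' Identify the letter in a stimulus with a template observer
#'
#' Computes the observer's decision map (averaged over frames for a
#' movie), adds internal noise, correlates it with the four HOTV templates
#' at the stimulus's check resolution, and returns the best-matching
#' letter. Exact ties are broken in the fixed order H < O < T < V.
#'
#' @param observer A [template_observer()].
#' @param stimulus A `stimulus_frame` or `stimulus_movie`.
#' @return The chosen letter.
#' @export
template_respond <- function(observer, stimulus) {
  stopifnot(inherits(observer, "template_observer"))
  frames <- if (inherits(stimulus, "stimulus_movie")) {
    stimulus$frames
  } else if (inherits(stimulus, "stimulus_frame")) {
    list(stimulus)
  } else {
    nl_stop("stimulus must be a stimulus_frame or stimulus_movie")
  }
  cps <- frames[[1]]$template$checks_per_stroke
  side <- nrow(frames[[1]]$template$check_grid)
  maps <- lapply(frames, frame_decision_map, rule = observer$decision_rule)
  map <- Reduce(`+`, maps) / length(maps)
  if (observer$internal_noise_sd > 0) {
    map <- map + stats::rnorm(length(map), 0, observer$internal_noise_sd)
  }
  scores <- vapply(hotv_letters, function(L) {
    tpl <- make_letter_template(L, cps)$check_grid
    if (nrow(tpl) != side) nl_stop("template/stimulus size mismatch")
    suppressWarnings(stats::cor(as.vector(map), as.vector(tpl)))
  }, 0)
  scores[is.na(scores)] <- -Inf
  hotv_letters[which.max(scores)]  # which.max takes the first -> H<O<T<V
}
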