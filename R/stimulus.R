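# Noise-letter stimulus synthesis.
#
# Every pixel of a stimulus frame obeys
#
#   I(x, y) = I * [1 + n * N(x, y) + l * L(x, y) + m * n * M(x, y) * N(x, y)]
#
# where I is the mean luminance, n the carrier (noise) contrast,
# N(x, y) in {-1, +1} a binary white-noise check, l the luminance
# amplitude, m the contrast amplitude, and L, M square-wave modulation
# supports (1 on letter ink, 0 elsewhere by default). LM letters use
# l > 0, m = 0; CM letters use m > 0, l = 0, so a CM letter differs from
# its background only in local contrast: its expected luminance equals I
# everywhere.

#' Specify a noise-letter stimulus
#'
#' Validates and stores the parameters of the modulation equation. LM
#' (luminance-modulated, first-order) stimuli must have zero contrast
#' amplitude; CM (contrast-modulated, second-order) stimuli must have zero
#' luminance amplitude. Pixel luminances are guaranteed to stay in
#' `[0, 2 * mean_luminance]`, which requires
#' `|l| + n * (1 + |m|) <= 1`.
#'
#' @param stimulus_type `"LM"` or `"CM"`.
#' @param mean_luminance Mean luminance `I` (normalised display units,
#'   default 1).
#' @param noise_contrast Carrier contrast `n` in `[0, 1]` (default 0.2).
#' @param luminance_amplitude Luminance amplitude `l` (default 0.3 for LM,
#'   forced to 0 for CM).
#' @param contrast_amplitude Contrast amplitude `m` (default 1.0 for CM,
#'   forced to 0 for LM).
#' @param bipolar_modulation If `TRUE` the square-wave supports L and M
#'   take values +1 on ink and -1 elsewhere instead of 1/0. Off by
#'   default; see the methods vignette.
#' @return A `stimulus_spec`.
#' @export
#' @examples
#' stimulus_spec("CM")
#' stimulus_spec("LM", luminance_amplitude = 0.4)
stimulus_spec <- function(stimulus_type = c("LM", "CM"),
                          mean_luminance = 1,
                          noise_contrast = 0.2,
                          luminance_amplitude = NULL,
                          contrast_amplitude = NULL,
                          bipolar_modulation = FALSE) {
  stimulus_type <- match.arg(stimulus_type)
  if (is.null(luminance_amplitude)) {
    luminance_amplitude <- if (stimulus_type == "LM") 0.3 else 0
  }
  if (is.null(contrast_amplitude)) {
    contrast_amplitude <- if (stimulus_type == "CM") 1.0 else 0
  }
  I <- mean_luminance; n <- noise_contrast
  l <- luminance_amplitude; m <- contrast_amplitude
  if (!is.numeric(I) || I <= 0) nl_stop("mean_luminance must be > 0")
  if (!is.numeric(n) || n < 0 || n > 1) {
    nl_stop("noise_contrast must lie in [0, 1], got ", n)
  }
  if (stimulus_type == "LM" && m != 0) {
    nl_stop("LM stimuli require contrast_amplitude = 0 (got m = ", m, ")")
  }
  if (stimulus_type == "CM" && l != 0) {
    nl_stop("CM stimuli require luminance_amplitude = 0 (got l = ", l, ")")
  }
  if (abs(l) + n * (1 + abs(m)) > 1 + 1e-12) {
    nl_stop("luminance out of gamut: |l| + n*(1 + |m|) = ",
            abs(l) + n * (1 + abs(m)),
            " > 1 for (l = ", l, ", n = ", n, ", m = ", m, ")")
  }
  structure(
    list(stimulus_type = stimulus_type,
         mean_luminance = I,
         noise_contrast = n,
         luminance_amplitude = l,
         contrast_amplitude = m,
         bipolar_modulation = isTRUE(bipolar_modulation)),
    class = "stimulus_spec"
  )
}

#' @export
print.stimulus_spec <- function(x, ...) {
  cat("<stimulus_spec> ", x$stimulus_type,
      ": I = ", x$mean_luminance,
      ", n = ", x$noise_contrast,
      ", l = ", x$luminance_amplitude,
      ", m = ", x$contrast_amplitude,
      if (x$bipolar_modulation) ", bipolar L/M" else "",
      "\n", sep = "")
  invisible(x)
}

#' Sample a binary white-noise carrier field
#'
#' Draws i.i.d. equiprobable -1/+1 values, one per noise check. The same
#' seed always reproduces the same field.
#'
#' @param n_checks_y,n_checks_x Field size in checks (rows, columns).
#' @param check_size_px Side of a check in screen pixels (default 1); at
#'   pixel resolution each check is a constant square block of this side.
#' @param seed Integer seed (required; reproducibility is part of the
#'   contract).
#' @param frame_index Frame tag carried along in movies.
#' @return A `noise_field` with fields `values` (checks, entries in
#'   -1/+1), `check_size_px`, `seed`, `frame_index`.
#' @export
#' @examples
#' nf <- sample_noise(15, 15, seed = 7)
#' table(nf$values)
sample_noise <- function(n_checks_y, n_checks_x, check_size_px = 1, seed,
                         frame_index = 1L) {
  if (missing(seed)) nl_stop("sample_noise requires an explicit seed")
  if (n_checks_y < 1 || n_checks_x < 1) {
    nl_stop("noise field dimensions must be >= 1 (got ",
            n_checks_y, " x ", n_checks_x, ")")
  }
  if (check_size_px < 1 || check_size_px != round(check_size_px)) {
    nl_stop("check_size_px must be a positive integer")
  }
  values <- with_seed(seed, matrix(
    sample(c(-1, 1), n_checks_y * n_checks_x, replace = TRUE),
    nrow = n_checks_y, ncol = n_checks_x
  ))
  structure(
    list(values = values,
         check_size_px = as.integer(check_size_px),
         seed = as.integer(seed),
         frame_index = as.integer(frame_index)),
    class = "noise_field"
  )
}

# expand a check-resolution matrix to pixel resolution
expand_checks <- function(m, check_size_px) {
  if (check_size_px == 1) return(m)
  kronecker(m, matrix(1, check_size_px, check_size_px))
}

# check-resolution modulation supports (L or M) for a template centred in
# an ny x nx field; unipolar 0/1 or bipolar -1/+1
modulation_support <- function(template, ny, nx, bipolar = FALSE) {
  side <- nrow(template$check_grid)
  if (ny < side || nx < side) {
    nl_stop("noise field (", ny, " x ", nx,
            " checks) is smaller than the letter (", side, " checks)")
  }
  bg <- if (bipolar) -1 else 0
  sup <- matrix(bg, ny, nx)
  oy <- floor((ny - side) / 2)
  ox <- floor((nx - side) / 2)
  ink <- if (bipolar) 2 * template$check_grid - 1 else template$check_grid
  sup[oy + seq_len(side), ox + seq_len(side)] <- ink
  sup
}

#' Render a single noise-letter frame
#'
#' Applies the modulation equation pixelwise, with the letter centred in
#' the noise field. Background checks (outside the letter support) carry
#' only the noise term, so they read `I * (1 + n * N)`.
#'
#' @param spec A [stimulus_spec()].
#' @param template A [make_letter_template()] template.
#' @param noise A [sample_noise()] field at least as large as the letter's
#'   check grid.
#' @return A `stimulus_frame` with fields `image` (pixel luminance
#'   matrix), `spec`, `template`, `noise`.
#' @export
#' @examples
#' fr <- render_frame(stimulus_spec("CM"), make_letter_template("H"),
#'                    sample_noise(30, 30, seed = 1))
#' range(fr$image)
render_frame <- function(spec, template, noise) {
  stopifnot(inherits(spec, "stimulus_spec"),
            inherits(template, "letter_template"),
            inherits(noise, "noise_field"))
  ny <- nrow(noise$values); nx <- ncol(noise$values)
  sup <- modulation_support(template, ny, nx, spec$bipolar_modulation)
  I <- spec$mean_luminance
  checks <- I * (1 +
    spec$noise_contrast * noise$values +
    spec$luminance_amplitude * sup +
    spec$contrast_amplitude * spec$noise_contrast * sup * noise$values)
  if (any(checks < -1e-12) || any(checks > 2 * I + 1e-12)) {
    nl_stop("rendered luminance outside [0, 2I] for (l = ",
            spec$luminance_amplitude, ", n = ", spec$noise_contrast,
            ", m = ", spec$contrast_amplitude, ")")
  }
  structure(
    list(image = expand_checks(checks, noise$check_size_px),
         spec = spec, template = template, noise = noise),
    class = "stimulus_frame"
  )
}

#' Render a dynamic noise-letter movie
#'
#' Frames share the spec and template; the noise carrier is refreshed
#' independently every frame (sub-seeds derived deterministically from
#' `seed`), the standard way to avoid static pixel-clumping luminance
#' artefacts in second-order stimuli.
#'
#' @inheritParams render_frame
#' @param n_frames Number of frames (>= 1).
#' @param frame_rate_hz Nominal frame rate (default 60).
#' @param seed Master seed for the noise sequence.
#' @param n_checks_y,n_checks_x Field size in checks; default twice the
#'   letter side.
#' @param check_size_px Pixels per check (default 1).
#' @return A `stimulus_movie` with fields `frames` (list of
#'   `stimulus_frame`) and `frame_rate_hz`.
#' @export
render_movie <- function(spec, template, n_frames, frame_rate_hz = 60,
                         seed, n_checks_y = NULL, n_checks_x = NULL,
                         check_size_px = 1) {
  if (missing(seed)) nl_stop("render_movie requires an explicit seed")
  if (n_frames < 1) nl_stop("n_frames must be >= 1")
  side <- nrow(template$check_grid)
  if (is.null(n_checks_y)) n_checks_y <- 2 * side
  if (is.null(n_checks_x)) n_checks_x <- 2 * side
  frames <- lapply(seq_len(n_frames), function(k) {
    render_frame(spec, template,
                 sample_noise(n_checks_y, n_checks_x, check_size_px,
                              seed = derive_seed(seed, "frame", k),
                              frame_index = k))
  })
  structure(list(frames = frames, frame_rate_hz = frame_rate_hz),
            class = "stimulus_movie")
}

# indices of letter-support checks within a frame's check grid
letter_check_index <- function(frame) {
  sup <- modulation_support(frame$template,
                            nrow(frame$noise$values),
                            ncol(frame$noise$values), bipolar = FALSE)
  sup == 1
}

#' Mean-luminance artefact check for a movie
#'
#' Computes the spatio-temporal mean luminance inside and outside the
#' letter support, at check resolution (pixels within a check are
#' duplicates, so checks are the independent samples). For CM stimuli both
#' means estimate the background luminance `I`; for LM stimuli the letter
#' region estimates `I * (1 + l)`. The pass flag tests
#' `|mean - expectation| < k * SE` in both regions.
#'
#' @param movie A [render_movie()] movie (>= 1 frame).
#' @param k Tolerance multiplier in standard errors (default 3).
#' @return A list with `letter_region_mean`, `background_mean`, their
#'   standard errors, the expected values under the stimulus equation, and
#'   `tolerance_pass`.
#' @export
check_mean_luminance <- function(movie, k = 3) {
  stopifnot(inherits(movie, "stimulus_movie"), length(movie$frames) >= 1)
  idx <- letter_check_index(movie$frames[[1]])
  spec <- movie$frames[[1]]$spec
  lett <- unlist(lapply(movie$frames, function(f) {
    v <- f$spec$mean_luminance * (1 +
      f$spec$noise_contrast * f$noise$values +
      f$spec$luminance_amplitude * 1 +
      f$spec$contrast_amplitude * f$spec$noise_contrast * f$noise$values)
    v[idx]
  }))
  bg <- unlist(lapply(movie$frames, function(f) {
    v <- f$spec$mean_luminance * (1 + f$spec$noise_contrast * f$noise$values)
    v[!idx]
  }))
  I <- spec$mean_luminance
  exp_letter <- I * (1 + spec$luminance_amplitude)
  exp_bg <- I
  se_l <- std_error(lett); se_b <- std_error(bg)
  # degenerate case (n = 0): zero spread, means are exact
  ok <- function(m, e, s) {
    if (is.na(s) || s == 0) abs(m - e) < 1e-12 else abs(m - e) < k * s
  }
  pass <- ok(mean(lett), exp_letter, se_l) && ok(mean(bg), exp_bg, se_b)
  list(letter_region_mean = mean(lett),
       background_mean = mean(bg),
       letter_region_se = se_l,
       background_se = se_b,
       expected_letter_mean = exp_letter,
       expected_background_mean = exp_bg,
       tolerance_pass = pass)
}

#' Quantise a frame to 8-bit display levels
#'
#' Rounds luminances to the nearest of 256 equally spaced levels on
#' `[0, 2I]`. Off the default rendering path; provided for export.
#'
#' @param frame A `stimulus_frame`.
#' @return The frame with a quantised `image`.
#' @export
quantize_frame <- function(frame) {
  I <- frame$spec$mean_luminance
  lev <- round(frame$image / (2 * I) * 255)
  frame$image <- lev / 255 * 2 * I
  frame
}

#' Write a frame as an 8-bit grayscale PNG with JSON sidecar metadata
#'
#' @param frame A `stimulus_frame`.
#' @param path Output PNG path; metadata is written to `<path>.json`.
#' @param extra Named list merged into the sidecar metadata.
#' @return Invisibly, the PNG path.
#' @export
write_frame_png <- function(frame, path, extra = list()) {
  I <- frame$spec$mean_luminance
  png::writePNG(pmin(pmax(frame$image / (2 * I), 0), 1), target = path)
  meta <- c(list(
    stimulus_type = frame$spec$stimulus_type,
    mean_luminance = frame$spec$mean_luminance,
    noise_contrast = frame$spec$noise_contrast,
    luminance_amplitude = frame$spec$luminance_amplitude,
    contrast_amplitude = frame$spec$contrast_amplitude,
    letter = frame$template$letter,
    checks_per_stroke = frame$template$checks_per_stroke,
    check_size_px = frame$noise$check_size_px,
    noise_seed = frame$noise$seed
  ), extra)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}
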