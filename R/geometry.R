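# Letter size <-> logMAR conversion.
#
# An optotype is "resolved" at the angular size of its stroke (one fifth
# of letter height). For a letter of side s pixels viewed at distance d,
# the stroke subtends atan((s/5) * pitch / (1000 * d)) which, expressed in
# arcminutes, is the minimum angle of resolution (MAR); logMAR is its
# base-10 logarithm. A physical display can only draw letters whose side
# is a whole number of pixels, so only a discrete set of logMAR levels is
# achievable; conversions report the ACHIEVED level after quantisation.

#' Describe the viewing geometry of a noise-letter display
#'
#' @param distance_m Viewing distance in metres (> 0). The study design
#'   this package emulates uses 9 m for LM letters and 4.5 m for CM
#'   letters.
#' @param pixel_pitch_mm Physical size of one screen pixel in mm
#'   (default 0.47).
#' @param checks_per_stroke Noise checks per stroke width (default 3, so a
#'   letter spans 15 checks).
#' @param side_quantum Quantum of achievable letter sides in pixels.
#'   Defaults to `5 * checks_per_stroke` (whole-pixel noise checks, the
#'   strictest rendering grid). Set to 1 to allow any whole-pixel letter
#'   side, the fine grid used for simulated staircases where checks may
#'   take fractional pixel sizes.
#' @return A `viewing_geometry`.
#' @export
#' @examples
#' viewing_geometry(4.5)
viewing_geometry <- function(distance_m, pixel_pitch_mm = 0.47,
                             checks_per_stroke = 3, side_quantum = NULL) {
  if (!is.numeric(distance_m) || distance_m <= 0) {
    nl_stop("distance_m must be > 0")
  }
  if (!is.numeric(pixel_pitch_mm) || pixel_pitch_mm <= 0) {
    nl_stop("pixel_pitch_mm must be > 0")
  }
  checks_per_stroke <- as.integer(checks_per_stroke)
  if (is.na(checks_per_stroke) || checks_per_stroke < 1) {
    nl_stop("checks_per_stroke must be a positive integer")
  }
  if (is.null(side_quantum)) side_quantum <- 5L * checks_per_stroke
  side_quantum <- as.integer(side_quantum)
  if (is.na(side_quantum) || side_quantum < 1) {
    nl_stop("side_quantum must be a positive integer")
  }
  structure(
    list(distance_m = distance_m,
         pixel_pitch_mm = pixel_pitch_mm,
         checks_per_stroke = checks_per_stroke,
         side_quantum = side_quantum),
    class = "viewing_geometry"
  )
}

#' @export
print.viewing_geometry <- function(x, ...) {
  cat("<viewing_geometry> ", x$distance_m, " m, ",
      x$pixel_pitch_mm, " mm/px, ", x$checks_per_stroke,
      " checks/stroke, side quantum ", x$side_quantum, " px (floor ",
      sprintf("%+.3f", geometry_floor(x)$logmar), " logMAR)\n", sep = "")
  invisible(x)
}

# exact angular size of `px` pixels, in arcminutes
pixels_to_arcmin <- function(px, geometry) {
  atan(px * geometry$pixel_pitch_mm / (1000 * geometry$distance_m)) *
    (180 / pi) * 60
}

acuity_level <- function(logmar, letter_side_px, geometry) {
  structure(
    list(logmar = logmar,
         mar_arcmin = 10^logmar,
         letter_side_px = as.integer(letter_side_px),
         stroke_px = letter_side_px / 5,
         geometry = geometry),
    class = "acuity_level"
  )
}

#' @export
print.acuity_level <- function(x, ...) {
  cat(sprintf("<acuity_level> %+.4f logMAR (MAR %.3f arcmin), letter side %d px\n",
              x$logmar, x$mar_arcmin, x$letter_side_px))
  invisible(x)
}

# smallest achievable letter side: at least one whole pixel per stroke,
# rounded up to the side quantum
min_letter_side <- function(geometry) {
  q <- geometry$side_quantum
  as.integer(q * ceiling(max(5, q) / q))
}

#' Smallest achievable acuity level (the geometry floor)
#' @param geometry A [viewing_geometry()].
#' @return The `acuity_level` of the smallest drawable letter.
#' @export
geometry_floor <- function(geometry) {
  s <- min_letter_side(geometry)
  acuity_level(log10(pixels_to_arcmin(s / 5, geometry)), s, geometry)
}

#' Convert a rendered letter size to its logMAR acuity level
#'
#' @param letter_side_px Letter side in pixels; must be a positive
#'   multiple of the geometry's `side_quantum` (15 for the default
#'   whole-check grid).
#' @param geometry A [viewing_geometry()].
#' @return An `acuity_level` with the exact (atan-based) achieved logMAR.
#' @export
#' @examples
#' size_to_logmar(15, viewing_geometry(4.5)) # ~ +0.032 logMAR
size_to_logmar <- function(letter_side_px, geometry) {
  stopifnot(inherits(geometry, "viewing_geometry"))
  q <- geometry$side_quantum
  if (length(letter_side_px) != 1 || letter_side_px < 1 ||
      letter_side_px != round(letter_side_px) ||
      (letter_side_px %% q) != 0) {
    nl_stop("letter_side_px must be a positive multiple of the side ",
            "quantum (", q, " px) so that letters land on the rendering ",
            "grid; got ", letter_side_px)
  }
  acuity_level(log10(pixels_to_arcmin(letter_side_px / 5, geometry)),
               letter_side_px, geometry)
}

# fast numeric core of logmar_to_size: returns achieved logmar only
quantize_logmar <- function(target_logmar, geometry, clamp = FALSE) {
  lv <- logmar_to_size(target_logmar, geometry, clamp = clamp)
  lv$logmar
}

#' Find the achievable letter size closest to a target logMAR
#'
#' Inverts [size_to_logmar()] onto the discrete grid of drawable letter
#' sides. The level minimising `|achieved - target|` is returned; exact
#' ties are broken toward the larger letter (conservative: avoids floor
#' effects in adaptive procedures).
#'
#' @param target_logmar Target acuity level in logMAR.
#' @param geometry A [viewing_geometry()].
#' @param clamp If `TRUE`, targets below the smallest drawable letter
#'   return the floor level instead of erroring.
#' @return An `acuity_level` (achieved, post-quantisation).
#' @export
#' @examples
#' logmar_to_size(0.0, viewing_geometry(4.5))
logmar_to_size <- function(target_logmar, geometry, clamp = FALSE) {
  stopifnot(inherits(geometry, "viewing_geometry"))
  if (!is.finite(target_logmar)) nl_stop("target_logmar must be finite")
  q <- geometry$side_quantum
  floor_lv <- geometry_floor(geometry)
  if (target_logmar < floor_lv$logmar - 1e-12) {
    if (clamp) return(floor_lv)
    nl_stop("target ", format(target_logmar), " logMAR is below the ",
            "smallest drawable letter for this geometry (floor ",
            sprintf("%+.4f", floor_lv$logmar), " logMAR at ",
            floor_lv$letter_side_px, " px)")
  }
  # invert the exact mapping, then snap to the quantum grid
  theta_rad <- 10^target_logmar / 60 * pi / 180
  stroke_px <- tan(theta_rad) * 1000 * geometry$distance_m /
    geometry$pixel_pitch_mm
  side_f <- 5 * stroke_px
  lo <- max(min_letter_side(geometry), q * floor(side_f / q))
  hi <- max(min_letter_side(geometry), q * ceiling(side_f / q))
  cand <- unique(c(lo, hi))
  ach <- vapply(cand, function(s) log10(pixels_to_arcmin(s / 5, geometry)),
                0)
  d <- abs(ach - target_logmar)
  best <- if (length(cand) == 2 && abs(d[1] - d[2]) < 1e-12) {
    which.max(cand)           # tie -> larger letter
  } else {
    which.min(d)
  }
  acuity_level(ach[best], cand[best], geometry)
}
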