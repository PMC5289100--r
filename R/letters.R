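# Canonical HOTV letterforms on the 5x5 stroke grid.
#
# Each optotype is drawn on a 5 x 5 grid of stroke cells (1 = ink), so the
# stroke width is exactly one fifth of the letter height, the classic
# Sloan-style optotype proportion. Rows run top to bottom.
#
# H: full-height verticals in columns 1 and 5, crossbar on row 3.
# O: one-cell-wide ring, hollow 3 x 3 interior.
# T: full-width bar on row 1, central vertical on rows 2-5.
# V: verticals on rows 1-3 that step inward on row 4 and meet at the
#    bottom-centre cell (a square-grid rendering of the converging strokes).
.hotv_strokes <- list(
  H = rbind(c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1),
            c(1, 1, 1, 1, 1),
            c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1)),
  O = rbind(c(1, 1, 1, 1, 1),
            c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1),
            c(1, 1, 1, 1, 1)),
  T = rbind(c(1, 1, 1, 1, 1),
            c(0, 0, 1, 0, 0),
            c(0, 0, 1, 0, 0),
            c(0, 0, 1, 0, 0),
            c(0, 0, 1, 0, 0)),
  V = rbind(c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1),
            c(1, 0, 0, 0, 1),
            c(0, 1, 0, 1, 0),
            c(0, 0, 1, 0, 0))
)

#' The four HOTV optotype letters
#' @export
hotv_letters <- c("H", "O", "T", "V")

#' Build a noise-check resolution letter template
#'
#' Expands the canonical 5x5 stroke grid of an HOTV optotype to noise-check
#' resolution by nearest-neighbour block replication: each stroke cell
#' becomes a `checks_per_stroke` x `checks_per_stroke` block, so with the
#' default of 3 checks per stroke a letter spans 15 x 15 noise checks.
#'
#' @param letter One of `"H"`, `"O"`, `"T"`, `"V"`.
#' @param checks_per_stroke Number of noise checks per stroke width
#'   (default 3).
#' @return A `letter_template` with fields `letter`, `stroke_grid` (5x5
#'   binary), `check_grid` (binary, side `5 * checks_per_stroke`) and
#'   `checks_per_stroke`.
#' @export
#' @examples
#' tpl <- make_letter_template("T")
#' dim(tpl$check_grid) # 15 15
make_letter_template <- function(letter, checks_per_stroke = 3) {
  if (!is.character(letter) || length(letter) != 1 ||
      !letter %in% hotv_letters) {
    nl_stop("unknown letter '", paste(letter, collapse = ","),
            "'; valid letters are H, O, T, V")
  }
  checks_per_stroke <- as.integer(checks_per_stroke)
  if (is.na(checks_per_stroke) || checks_per_stroke < 1) {
    nl_stop("checks_per_stroke must be a positive integer")
  }
  stroke <- .hotv_strokes[[letter]]
  check <- kronecker(stroke, matrix(1, checks_per_stroke, checks_per_stroke))
  structure(
    list(letter = letter,
         stroke_grid = stroke,
         check_grid = check,
         checks_per_stroke = checks_per_stroke),
    class = "letter_template"
  )
}

#' @export
print.letter_template <- function(x, ...) {
  cat("<letter_template> '", x$letter, "', ",
      nrow(x$check_grid), "x", ncol(x$check_grid), " checks (",
      x$checks_per_stroke, " per stroke), ink fraction ",
      signif(mean(x$check_grid), 3), "\n", sep = "")
  invisible(x)
}
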