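#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded to `seed`, then restores the
#' previous RNG state, so library functions never disturb a caller's
#' random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Derive a reproducible sub-seed from a master seed and labels
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) of the master
#' seed and any number of stage / participant / run labels. The same inputs
#' always map to the same sub-seed, independent of evaluation order, which
#' keeps multi-stage simulations reproducible even if stages are reordered
#' or parallelised.
#'
#' @param seed Master integer seed.
#' @param ... Further labels (coerced to character).
#' @return An integer in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "staircase", "older", 3, "run", 2)
derive_seed <- function(seed, ...) {
  key <- paste(c(as.character(seed), vapply(list(...), as.character, "")),
               collapse = "/")
  h <- 0
  for (v in utf8ToInt(key)) h <- (h * 131 + v) %% 2147483647
  as.integer(h)
}

#' Round half away from zero
#'
#' Decimal rounding with ties going away from zero (so 1.125 -> 1.13 at
#' 2 dp), the convention used when reporting acuity tables, as opposed to
#' [round()]'s round-half-even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
#' @examples
#' round_half_up(1.125, 2) # 1.13
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Standard error of the mean
#' @param x Numeric vector.
#' @return `sd(x)/sqrt(length(x))`; `NA` for fewer than 2 values.
#' @export
std_error <- function(x) {
  n <- length(x)
  if (n < 2) return(NA_real_)
  stats::sd(x) / sqrt(n)
}

# shared stop helper: consistent error prefix without a condition class zoo
nl_stop <- function(...) stop(..., call. = FALSE)
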