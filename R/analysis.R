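# Threshold analysis: group summaries, binocular summation ratios,
# fold-differences and a two-way mixed-design ANOVA.
#
# Acuity lives on the logMAR scale; ratios of acuities (MAR) are
# therefore powers of ten of logMAR differences. The binocular summation
# ratio is monocular MAR / binocular MAR = 10^(mono - bino): values
# above 1 mean binocular viewing improved acuity.

#' Binocular summation ratio
#'
#' `monocular MAR / binocular MAR`, computed exactly as
#' `10^(monocular_logmar - binocular_logmar)`. A ratio above 1 means
#' binocular acuity is better.
#'
#' @param monocular_logmar,binocular_logmar Acuities in logMAR
#'   (vectorised).
#' @return Numeric ratio(s).
#' @export
#' @examples
#' summation_ratio(0.44, 0.39) # 1.122...
summation_ratio <- function(monocular_logmar, binocular_logmar) {
  if (!all(is.finite(monocular_logmar)) || !all(is.finite(binocular_logmar))) {
    nl_stop("summation_ratio requires finite logMAR inputs")
  }
  10^(monocular_logmar - binocular_logmar)
}

#' Fold-difference between two acuities
#'
#' How many times better (in MAR) acuity `b` is than acuity `a`:
#' `fold = 10^(a - b)`, together with the raw logMAR difference
#' (0.1 logMAR is one chart line).
#'
#' @param logmar_a,logmar_b Acuities in logMAR.
#' @return List with `fold` and `difference_logmar` (`a - b`).
#' @export
#' @examples
#' group_fold_difference(0.39, 0.20) # 0.19 logMAR, ~1.55-fold
group_fold_difference <- function(logmar_a, logmar_b) {
  if (!all(is.finite(logmar_a)) || !all(is.finite(logmar_b))) {
    nl_stop("group_fold_difference requires finite logMAR inputs")
  }
  list(fold = 10^(logmar_a - logmar_b),
       difference_logmar = logmar_a - logmar_b)
}

#' Per-cell group summaries of a cohort
#'
#' Mean and standard error of the threshold in every
#' group x stimulus type x viewing cell.
#'
#' @param cohort A cohort result data frame (see [simulate_cohort()]).
#' @return Data frame with columns `group`, `stimulus_type`, `viewing`,
#'   `n`, `mean_logmar`, `se_logmar`.
#' @export
summarize_groups <- function(cohort) {
  need <- c("group", "stimulus_type", "viewing", "threshold_logmar")
  if (!all(need %in% names(cohort))) {
    nl_stop("cohort needs columns ", paste(need, collapse = ", "))
  }
  if (nrow(cohort) == 0) nl_stop("cohort is empty: no cells to summarise")
  cells <- unique(cohort[, c("group", "stimulus_type", "viewing")])
  cells <- cells[order(cells$group, cells$stimulus_type, cells$viewing), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- cohort$group == cells$group[i] &
      cohort$stimulus_type == cells$stimulus_type[i] &
      cohort$viewing == cells$viewing[i]
    x <- cohort$threshold_logmar[sel]
    if (length(x) == 0) {
      nl_stop("empty cell: group=", cells$group[i], ", stimulus_type=",
              cells$stimulus_type[i], ", viewing=", cells$viewing[i])
    }
    data.frame(cells[i, , drop = FALSE], n = length(x),
               mean_logmar = mean(x), se_logmar = std_error(x),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Per-participant binocular summation ratios
#'
#' Pairs each participant's monocular and binocular thresholds within a
#' stimulus type and computes the summation ratio.
#'
#' @param cohort A cohort result data frame containing both viewing
#'   conditions.
#' @return Data frame with columns `participant_id`, `group`,
#'   `stimulus_type`, `monocular_logmar`, `binocular_logmar`, `ratio`.
#' @export
summation_by_participant <- function(cohort) {
  mono <- cohort[cohort$viewing == "monocular", ]
  bino <- cohort[cohort$viewing == "binocular", ]
  key <- c("participant_id", "group", "stimulus_type")
  m <- merge(mono[, c(key, "threshold_logmar")],
             bino[, c(key, "threshold_logmar")],
             by = key, suffixes = c("_mono", "_bino"))
  if (nrow(m) == 0) {
    nl_stop("no participant has both monocular and binocular thresholds")
  }
  out <- data.frame(
    participant_id = m$participant_id, group = m$group,
    stimulus_type = m$stimulus_type,
    monocular_logmar = m$threshold_logmar_mono,
    binocular_logmar = m$threshold_logmar_bino,
    ratio = summation_ratio(m$threshold_logmar_mono,
                            m$threshold_logmar_bino),
    stringsAsFactors = FALSE
  )
  out[order(out$group, out$stimulus_type, out$participant_id), ]
}

#' Group-level binocular summation summary
#'
#' Aggregates per-participant ratios (mean +/- SE per
#' group x stimulus type), the aggregation implied by reporting an SE on
#' the ratio itself. The ratio of the group mean acuities
#' (`ratio_of_means`) is also reported; on heterogeneous data the two
#' differ (the mean of ratios is not the ratio of means).
#'
#' @param cohort A cohort result data frame.
#' @return Data frame with columns `group`, `stimulus_type`, `n`,
#'   `mean_ratio`, `se_ratio`, `ratio_of_means`.
#' @export
summarize_summation <- function(cohort) {
  per <- summation_by_participant(cohort)
  cells <- unique(per[, c("group", "stimulus_type")])
  cells <- cells[order(cells$group, cells$stimulus_type), ]
  out <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- per$group == cells$group[i] &
      per$stimulus_type == cells$stimulus_type[i]
    x <- per[sel, ]
    data.frame(cells[i, , drop = FALSE], n = nrow(x),
               mean_ratio = mean(x$ratio),
               se_ratio = std_error(x$ratio),
               ratio_of_means = summation_ratio(mean(x$monocular_logmar),
                                                mean(x$binocular_logmar)),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Two-way mixed-design ANOVA
#'
#' Standard decomposition for one between-subject factor (e.g. age
#' group) and one within-subject factor (e.g. stimulus type), fitted via
#' `aov` with an `Error(subject/within)` stratum. With 2 groups of n
#' participants the between-effect F is reported on
#' (1, 2n - 2) degrees of freedom. The design must be balanced and
#' complete: exactly one value per subject x within-level.
#'
#' @param data Data frame in long format.
#' @param dv Name of the response column (default `"threshold_logmar"`).
#' @param within Name of the within-subject factor column.
#' @param between Name of the between-subject factor column.
#' @param subject Name of the subject identifier column.
#' @return Data frame with columns `effect`, `F`, `df1`, `df2`, `p` for
#'   the between main effect, within main effect and their interaction.
#' @export
#' @examples
#' cohort <- data.frame(
#'   participant_id = rep(paste0("s", 1:4), each = 2),
#'   group = rep(c("a", "b"), each = 4),
#'   stimulus_type = rep(c("LM", "CM"), 4),
#'   threshold_logmar = c(0, .5, .1, .6, .2, .9, .1, .8)
#' )
#' mixed_anova(cohort, within = "stimulus_type", between = "group")
mixed_anova <- function(data, dv = "threshold_logmar",
                        within = "stimulus_type", between = "group",
                        subject = "participant_id") {
  for (col in c(dv, within, between, subject)) {
    if (!col %in% names(data)) nl_stop("column '", col, "' not found")
  }
  d <- data.frame(
    y = data[[dv]],
    w = factor(data[[within]]),
    b = factor(data[[between]]),
    s = factor(data[[subject]]),
    stringsAsFactors = FALSE
  )
  counts <- table(d$s, d$w)
  if (any(counts != 1)) {
    nl_stop("design must be balanced: exactly one value per ",
            subject, " x ", within, " cell (no imputation is done)")
  }
  per_group <- table(unique(d[, c("s", "b")])$b)
  if (length(unique(per_group)) != 1) {
    nl_stop("design must be balanced: unequal group sizes (",
            paste(per_group, collapse = ", "), ")")
  }
  fit <- stats::aov(y ~ b * w + Error(s / w), data = d)
  s <- summary(fit)
  # stratum 1: subjects (between effect), stratum 2: subject x within
  tab_b <- s[["Error: s"]][[1]]
  tab_w <- s[["Error: s:w"]][[1]]
  pick <- function(tab, term) {
    i <- match(term, trimws(rownames(tab)))
    if (is.na(i)) nl_stop("ANOVA term '", term, "' not found")
    res <- grep("Residuals", rownames(tab))
    data.frame(F = tab[i, "F value"], df1 = tab[i, "Df"],
               df2 = tab[res, "Df"], p = tab[i, "Pr(>F)"])
  }
  out <- rbind(
    cbind(effect = between, pick(tab_b, "b")),
    cbind(effect = within, pick(tab_w, "w")),
    cbind(effect = paste0(between, ":", within), pick(tab_w, "b:w"))
  )
  rownames(out) <- NULL
  out
}
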