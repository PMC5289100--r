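# independent textbook oracle: two-way mixed-design sums of squares
# computed from cell/marginal means (between factor b with a levels,
# within factor w with k levels, n subjects per group)
anova_oracle <- function(d) {
  grand <- mean(d$y)
  a <- length(unique(d$b)); k <- length(unique(d$w))
  n <- length(unique(d$s)) / a
  subj_means <- tapply(d$y, d$s, mean)
  subj_group <- tapply(as.character(d$b), d$s, unique)
  grp_means <- tapply(d$y, d$b, mean)
  w_means <- tapply(d$y, d$w, mean)
  cell_means <- tapply(d$y, list(d$b, d$w), mean)
  ss_between_subj <- k * sum((subj_means - grand)^2)
  ss_b <- n * k * sum((grp_means - grand)^2)
  ss_subj_within <- ss_between_subj - ss_b
  ss_w <- n * a * sum((w_means - grand)^2)
  ss_bw <- n * sum((sweep(sweep(cell_means, 1, grp_means - grand),
                          2, w_means - grand) - grand)^2)
  ss_total <- sum((d$y - grand)^2)
  ss_err <- ss_total - ss_between_subj - ss_w - ss_bw
  df_b <- a - 1; df_sw <- a * (n - 1)
  df_w <- k - 1; df_bw <- (a - 1) * (k - 1); df_e <- a * (n - 1) * (k - 1)
  f_b <- (ss_b / df_b) / (ss_subj_within / df_sw)
  f_w <- (ss_w / df_w) / (ss_err / df_e)
  f_bw <- (ss_bw / df_bw) / (ss_err / df_e)
  list(F = c(f_b, f_w, f_bw),
       df1 = c(df_b, df_w, df_bw), df2 = c(df_sw, df_e, df_e),
       p = c(stats::pf(f_b, df_b, df_sw, lower.tail = FALSE),
             stats::pf(f_w, df_w, df_e, lower.tail = FALSE),
             stats::pf(f_bw, df_bw, df_e, lower.tail = FALSE)))
}

toy_cohort <- function(seed = 1, n = 5, shift = 0) {
  set.seed(seed)
  d <- expand.grid(participant_id = paste0("s", 1:(2 * n)),
                   stimulus_type = c("LM", "CM"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(as.integer(sub("s", "", d$participant_id)) <= n,
                    "older", "younger")
  d$viewing <- "binocular"
  d$threshold_logmar <- round(stats::rnorm(nrow(d), 0.2, 0.15), 3) +
    ifelse(d$stimulus_type == "CM", 0.4, 0) +
    ifelse(d$group == "older", 0.1, 0) + shift
  d
}

test_that("binocular summation ratios reproduce the published worked examples", {
  # older-group CM means: 0.44 monocular, 0.39 binocular -> 1.12
  expect_equal(round_half_up(summation_ratio(0.44, 0.39), 2), 1.12)
  # younger-group LM means: -0.18 monocular, -0.24 binocular -> 1.15
  expect_equal(round_half_up(summation_ratio(-0.18, -0.24), 2), 1.15)
  expect_equal(summation_ratio(0.37, 0.37), 1)
  expect_error(summation_ratio(NA, 0.2), "finite")
})

test_that("the ratio/log identity and scale equivariance hold exactly", {
  mono <- c(0.44, -0.18, 0.2, 0.02)
  bino <- c(0.39, -0.24, 0.13, 0.02)
  expect_equal(log10(summation_ratio(mono, bino)), mono - bino)
  expect_equal(summation_ratio(mono + 0.3, bino + 0.3),
               summation_ratio(mono, bino))
  d0 <- toy_cohort(2)
  d1 <- d0; d1$threshold_logmar <- d1$threshold_logmar + 0.25
  a0 <- mixed_anova(d0); a1 <- mixed_anova(d1)
  expect_equal(a0$F, a1$F)
  expect_equal(a0$p, a1$p)
})

test_that("fold-differences report both the ratio and the logMAR gap", {
  fd <- group_fold_difference(0.39, 0.20)
  expect_equal(fd$difference_logmar, 0.19)
  expect_equal(fd$fold, 10^0.19)
  same <- group_fold_difference(0.1, 0.1)
  expect_equal(same$fold, 1)
  expect_equal(same$difference_logmar, 0)
})

test_that("group summaries compute per-cell mean and SE", {
  d <- data.frame(
    participant_id = paste0("p", 1:4),
    group = c("older", "older", "younger", "younger"),
    stimulus_type = "CM", viewing = "binocular",
    threshold_logmar = c(0.3, 0.5, 0.2, 0.2)
  )
  s <- summarize_groups(d)
  older <- s[s$group == "older", ]
  expect_equal(older$mean_logmar, 0.4)
  expect_equal(older$se_logmar, 0.1)
  younger <- s[s$group == "younger", ]
  expect_equal(younger$se_logmar, 0)
  # 5-value cell against hand-computed values
  d5 <- data.frame(participant_id = paste0("p", 1:5), group = "g",
                   stimulus_type = "LM", viewing = "monocular",
                   threshold_logmar = c(0.10, 0.20, 0.15, 0.05, 0.30))
  s5 <- summarize_groups(d5)
  expect_equal(s5$mean_logmar, 0.16)
  expect_equal(s5$se_logmar, 0.0430116263, tolerance = 1e-8)
  expect_error(summarize_groups(d[0, ]), "columns|cell")
})

test_that("per-participant summation aggregation differs from ratio of means", {
  set.seed(11)
  n <- 6
  d <- rbind(
    data.frame(participant_id = paste0("p", 1:n), group = "older",
               stimulus_type = "LM", viewing = "monocular",
               threshold_logmar = stats::rnorm(n, 0.0, 0.25)),
    data.frame(participant_id = paste0("p", 1:n), group = "older",
               stimulus_type = "LM", viewing = "binocular",
               threshold_logmar = stats::rnorm(n, -0.1, 0.25))
  )
  per <- summation_by_participant(d)
  expect_equal(nrow(per), n)
  expect_equal(per$ratio,
               10^(per$monocular_logmar - per$binocular_logmar))
  s <- summarize_summation(d)
  # heterogeneous data: mean of ratios != ratio of mean acuities
  expect_gt(abs(s$mean_ratio - s$ratio_of_means), 1e-3)
  # but both agree when every participant is identical
  flat <- d; flat$threshold_logmar <- ifelse(flat$viewing == "monocular",
                                             0.3, 0.2)
  sf <- summarize_summation(flat)
  expect_equal(sf$mean_ratio, sf$ratio_of_means)
  expect_equal(sf$se_ratio, 0)
})

test_that("the mixed ANOVA matches the textbook sums-of-squares oracle", {
  d <- toy_cohort(7)
  res <- mixed_anova(d)
  orc <- anova_oracle(data.frame(y = d$threshold_logmar,
                                 b = factor(d$group),
                                 w = factor(d$stimulus_type),
                                 s = factor(d$participant_id)))
  expect_equal(res$F, orc$F, tolerance = 1e-10)
  expect_equal(res$df1, orc$df1)
  expect_equal(res$df2, orc$df2)
  expect_equal(res$p, orc$p, tolerance = 1e-10)
  # 2 groups x 5 participants, 2 within levels: every effect on (1, 8) df
  expect_true(all(res$df1 == 1))
  expect_true(all(res$df2 == 8))
})

test_that("the ANOVA returns zero F when all cell means are identical", {
  # subject offsets plus antisymmetric within-subject noise that cancels
  # in every cell mean: all effect sums of squares are exactly zero
  d <- expand.grid(participant_id = paste0("s", 1:6),
                   stimulus_type = c("LM", "CM"),
                   stringsAsFactors = FALSE)
  idx <- as.integer(sub("s", "", d$participant_id))
  d$group <- rep(c("older", "younger"), each = 3)[idx]
  offs <- c(0.1, -0.1, 0, 0.1, -0.1, 0)
  wob <- c(0.02, -0.02, 0, 0.02, -0.02, 0)
  d$threshold_logmar <- 0.3 + offs[idx] +
    wob[idx] * ifelse(d$stimulus_type == "LM", 1, -1)
  res <- mixed_anova(d)
  expect_equal(res$F, c(0, 0, 0), tolerance = 1e-12)
})

test_that("unbalanced designs are rejected", {
  d <- toy_cohort(3)
  expect_error(mixed_anova(d[-1, ]), "balanced")
  d2 <- toy_cohort(3, n = 5)
  d2$group[d2$participant_id == "s1"] <- "younger"
  expect_error(mixed_anova(d2), "balanced")
})
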