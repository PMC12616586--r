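toy_table <- function() {
  # 4 subjects x 3 conditions with a real condition effect
  tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:4), each = 3),
    condition = rep(c("a", "b", "c"), times = 4),
    site = "left_kidney",
    svo2 = c(0.92, 0.84, 0.75,
             0.95, 0.86, 0.78,
             0.90, 0.80, 0.74,
             0.93, 0.85, 0.80)
  )
}

test_that("RM-ANOVA matches a from-scratch sums-of-squares oracle", {
  tab <- toy_table()
  got <- rm_anova(tab, "svo2", "left_kidney")
  oracle <- rm_anova_oracle(
    data.frame(subject_id = tab$subject_id, condition = tab$condition,
               value = tab$svo2)
  )
  expect_equal(got$f_stat, oracle$f, tolerance = 1e-10)
  expect_equal(got$p_value, oracle$p, tolerance = 1e-10)
  expect_equal(got$df_num, oracle$df1)
  expect_equal(got$df_den, oracle$df2)
  expect_equal(got$n_subjects_used, 4)
})

test_that("degrees of freedom follow the within-subject design", {
  set.seed(41)
  n <- 7
  k <- 4
  tab <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:n), each = k),
    condition = rep(letters[1:k], times = n),
    site = "x",
    value = rnorm(n * k)
  )
  got <- rm_anova(tab, "value", "x")
  expect_equal(got$df_num, k - 1)
  expect_equal(got$df_den, (k - 1) * (n - 1))
})

test_that("RM-ANOVA F is invariant to per-subject constant shifts", {
  tab <- toy_table()
  f0 <- rm_anova(tab, "svo2")$f_stat
  shifted <- tab |>
    dplyr::mutate(svo2 = svo2 + rep(c(10, -5, 3, 0.7), each = 3))
  expect_equal(rm_anova(shifted, "svo2")$f_stat, f0, tolerance = 1e-9)
})

test_that("subjects with a missing condition are excluded listwise", {
  tab <- toy_table()
  tab$svo2[tab$subject_id == "S4" & tab$condition == "c"] <- NA
  got <- rm_anova(tab, "svo2")
  expect_equal(got$n_subjects_used, 3)
  oracle <- rm_anova_oracle(
    tab |>
      dplyr::filter(subject_id != "S4") |>
      dplyr::transmute(subject_id, condition, value = svo2) |>
      as.data.frame()
  )
  expect_equal(got$f_stat, oracle$f, tolerance = 1e-10)
})

test_that("null data yields the nominal type-I error rate", {
  # no condition effect, huge subject effects: the within-subject F should
  # reject at ~alpha
  set.seed(42)
  n_sim <- 1000
  rejections <- 0L
  for (i in seq_len(n_sim)) {
    subj <- rnorm(6, 0, 50)
    tab <- tibble::tibble(
      subject_id = rep(sprintf("S%d", 1:6), each = 4),
      condition = rep(letters[1:4], times = 6),
      site = "x",
      value = rep(subj, each = 4) + rnorm(24)
    )
    p <- rm_anova(tab, "value", "x")$p_value
    if (p < 0.05) rejections <- rejections + 1L
  }
  expect_gt(rejections / n_sim, 0.03)
  expect_lt(rejections / n_sim, 0.07)
})

test_that("degenerate zero-variance designs fail rather than return NaN", {
  subj_means <- c(1, 2, 3, 4)
  tab <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:4), each = 3),
    condition = rep(c("a", "b", "c"), times = 4),
    site = "x",
    value = rep(subj_means, each = 3)
  )
  expect_error(rm_anova(tab, "value", "x"), "Degenerate")
})

test_that("too few complete subjects or conditions abort", {
  tab <- toy_table()[1:6, ] # 2 subjects
  expect_error(rm_anova(tab, "svo2"), ">= 3")
  one_cond <- toy_table() |> dplyr::filter(condition == "a")
  expect_error(rm_anova(one_cond, "svo2"), "2 conditions")
})

test_that("Bonferroni adjustment multiplies and caps at one", {
  set.seed(43)
  n <- 8
  tab <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:n), each = 4),
    condition = rep(c("a", "b", "c", "d"), times = n),
    site = "x",
    value = rnorm(4 * n) + rep(c(0, 3, 0.05, 0), times = n)
  )
  pw <- pairwise_bonferroni(tab, "value", "x")
  expect_equal(nrow(pw), 6) # choose(4, 2)
  expect_equal(pw$n_comparisons, rep(6, 6))
  expect_equal(pw$adjusted_p, pmin(1, pw$raw_p * 6), tolerance = 1e-12)
  expect_true(all(pw$adjusted_p <= 1))
  # monotone nondecreasing in the raw p-values (ties at the cap allowed)
  expect_true(all(diff(pw$adjusted_p[order(pw$raw_p)]) >= -1e-15))
  # strong effects get small adjusted p, null contrasts are capped near 1
  strong <- pw$adjusted_p[pw$condition_a == "a" & pw$condition_b == "b"]
  null_p <- pw$adjusted_p[pw$condition_a == "a" & pw$condition_b == "d"]
  expect_lt(strong, 0.05)
  expect_gt(null_p, strong)
})

test_that("identical paired samples are reported incomparable, not p = 1", {
  tab <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:4), each = 2),
    condition = rep(c("a", "b"), times = 4),
    site = "x",
    value = rep(c(1, 1), times = 4) + rep(1:4, each = 2)
  )
  pw <- pairwise_bonferroni(tab, "value", "x")
  expect_true(is.na(pw$raw_p))
  expect_match(pw$note, "incomparable")
})

test_that("cohort summary reports mean +/- SD with reporting rounding", {
  rec <- tibble::tibble(
    subject_id = rep(c("S1", "S2"), each = 2),
    condition = rep(c("baseline", "recovery"), times = 2),
    site_or_scope = "left_kidney",
    svo2 = c(0.921, 0.918, 0.925, 0.926),
    bfr = c(407, 411, 416, 402),
    rmro2 = c(138.2, 141.1, 142.0, 136.0)
  )
  s <- summarize_cohort(rec)
  base_svo2 <- s[s$parameter == "svo2" & s$condition == "baseline", ]
  expect_equal(base_svo2$mean, mean(c(0.921, 0.925)))
  expect_equal(base_svo2$report_mean, 92) # percent, whole number
  base_bfr <- s[s$parameter == "bfr" & s$condition == "baseline", ]
  expect_equal(base_bfr$report_mean, 410) # tens place
  # single record cell has SD zero
  one <- summarize_cohort(rec[1, ])
  expect_true(all(one$sd == 0))
})

test_that("significance stars follow the 0.05 / 0.01 / 0.001 thresholds", {
  expect_equal(significance_stars(c(0.2, 0.04, 0.009, 0.0005, NA)),
               c("", "*", "**", "***", ""))
})
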