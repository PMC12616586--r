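#' One-way repeated-measures ANOVA for a metabolic parameter at one site
#'
#' Tests the effect of breathing condition on a parameter measured
#' repeatedly within subjects, using the standard one-way within-subject
#' decomposition (condition, subject and residual sums of squares;
#' `F = MS_condition / MS_error` on `(k - 1, (k - 1)(n - 1))` degrees of
#' freedom). Subjects missing any condition are excluded entirely
#' (listwise deletion). Fitting goes through `stats::aov()` with a
#' `subject` error stratum.
#'
#' An optional Greenhouse-Geisser sphericity correction is available; by
#' default none is applied and the uncorrected F-test is reported.
#'
#' @param data Tibble of per-subject measurements with columns
#'   `subject_id`, `condition`, a site column (`site` or `site_or_scope`)
#'   and the parameter columns.
#' @param parameter Name of the parameter column to analyze.
#' @param site Site/scope label to filter on (`NULL` to use `data` as-is).
#' @param gg_correction Apply the Greenhouse-Geisser epsilon correction to
#'   the degrees of freedom and p-value.
#' @return A one-row tibble (`parameter`, `site`, `f_stat`, `df_num`,
#'   `df_den`, `p_value`, `n_subjects_used`, and `gg_epsilon` when
#'   requested).
#' @export
rm_anova <- function(data, parameter, site = NULL, gg_correction = FALSE) {
  d <- prepare_rm_data(data, parameter, site)
  n <- length(unique(d$subject_id))
  k <- length(unique(d$condition))
  if (k < 2) abort("At least 2 conditions are required.")
  if (n < 3) {
    abort(sprintf(
      "Only %d complete subject(s) after listwise deletion; >= 3 required.", n
    ))
  }
  fit <- aov(value ~ condition + Error(subject_id), data = d)
  tab <- summary(fit)[["Error: Within"]][[1]]
  rn <- trimws(rownames(tab))
  i_cond <- match("condition", rn)
  i_res <- match("Residuals", rn)
  # residual mean square of zero (up to rounding noise relative to the data
  # scale) makes F a 0/0: report the degeneracy, never NaN
  scale2 <- stats::var(d$value)
  if (!is.finite(tab[i_res, "Mean Sq"]) ||
      tab[i_res, "Mean Sq"] <= 1e-12 * max(scale2, .Machine$double.xmin)) {
    abort(paste0(
      "Degenerate within-subject design: residual mean square is zero, ",
      "the F statistic is undefined."
    ))
  }
  f <- tab[i_cond, "F value"]
  df1 <- tab[i_cond, "Df"]
  df2 <- tab[i_res, "Df"]
  p <- tab[i_cond, "Pr(>F)"]
  out <- tibble(
    parameter = parameter, site = site %||% NA_character_,
    f_stat = f, df_num = df1, df_den = df2, p_value = p,
    n_subjects_used = n
  )
  if (gg_correction) {
    eps <- gg_epsilon(d)
    out$gg_epsilon <- eps
    out$p_value <- pf(f, eps * df1, eps * df2, lower.tail = FALSE)
    out$df_num <- eps * df1
    out$df_den <- eps * df2
  }
  out
}

# Filter to one site, select the parameter column, listwise-delete
# incomplete subjects, coerce factors.
prepare_rm_data <- function(data, parameter, site) {
  site_col <- intersect(c("site", "site_or_scope"), names(data))[1]
  if (!is.null(site)) {
    if (is.na(site_col)) abort("`data` has no site column to filter on.")
    data <- data[data[[site_col]] == site, , drop = FALSE]
    if (nrow(data) == 0) abort(sprintf("No rows for site '%s'.", site))
  }
  if (!parameter %in% names(data)) {
    abort(sprintf("No column named '%s' in `data`.", parameter))
  }
  d <- tibble(
    subject_id = as.character(data$subject_id),
    condition = as.character(data$condition),
    value = as.numeric(data[[parameter]])
  )
  conds <- unique(d$condition)
  complete <- d |>
    dplyr::filter(!is.na(.data$value)) |>
    dplyr::count(.data$subject_id) |>
    dplyr::filter(.data$n == length(conds))
  d <- d[d$subject_id %in% complete$subject_id & !is.na(d$value), ]
  d$subject_id <- factor(d$subject_id)
  d$condition <- factor(d$condition, levels = conds)
  d
}

# Greenhouse-Geisser epsilon from the within-subject covariance matrix.
gg_epsilon <- function(d) {
  wide <- tidyr::pivot_wider(d, names_from = "condition",
                             values_from = "value")
  m <- as.matrix(wide[, -1])
  s <- stats::cov(m)
  k <- ncol(s)
  # double-centered covariance
  dc <- s - outer(rowMeans(s), rep(1, k)) - outer(rep(1, k), colMeans(s)) +
    mean(s)
  sum(diag(dc))^2 / ((k - 1) * sum(dc^2))
}

#' Bonferroni-adjusted pairwise comparisons between conditions
#'
#' Paired two-sided t-tests for every pair of conditions (k = 4 stages
#' gives 6 comparisons), on the same listwise-complete subjects as
#' [rm_anova()]. Each raw p-value is multiplied by the number of
#' comparisons and capped at 1. A pair whose within-subject differences
#' are all zero has no defined t statistic and is reported as
#' incomparable (`NA` p-values with a note), not as p = 1.
#'
#' @inheritParams rm_anova
#' @return A tibble with one row per condition pair: `parameter`, `site`,
#'   `condition_a`, `condition_b`, `t_stat`, `raw_p`, `adjusted_p`,
#'   `n_comparisons`, `note`.
#' @export
pairwise_bonferroni <- function(data, parameter, site = NULL) {
  d <- prepare_rm_data(data, parameter, site)
  conds <- levels(d$condition)
  pairs <- utils::combn(conds, 2)
  n_comp <- ncol(pairs)
  wide <- tidyr::pivot_wider(d, names_from = "condition",
                             values_from = "value")
  res <- purrr::map(seq_len(n_comp), function(i) {
    a <- pairs[1, i]
    b <- pairs[2, i]
    x <- wide[[a]]
    y <- wide[[b]]
    tt <- tryCatch(t.test(x, y, paired = TRUE), error = function(e) NULL)
    if (!is.null(tt) &&
        (!is.finite(tt$statistic) || is.na(tt$p.value))) {
      tt <- NULL # all-zero differences: no defined t statistic
    }
    if (is.null(tt)) {
      tibble(
        parameter = parameter, site = site %||% NA_character_,
        condition_a = a, condition_b = b,
        t_stat = NA_real_, raw_p = NA_real_, adjusted_p = NA_real_,
        n_comparisons = n_comp,
        note = "incomparable: zero within-subject variance"
      )
    } else {
      tibble(
        parameter = parameter, site = site %||% NA_character_,
        condition_a = a, condition_b = b,
        t_stat = unname(tt$statistic), raw_p = tt$p.value,
        adjusted_p = min(1, tt$p.value * n_comp),
        n_comparisons = n_comp, note = ""
      )
    }
  })
  dplyr::bind_rows(res)
}

#' Cohort summary table (mean +/- SD per parameter, site and condition)
#'
#' Summarizes a metabolic-record table into the conventional cohort
#' report: mean and SD of each parameter per site and breathing condition,
#' with reporting-convention rounding ([round_for_report()]) applied to a
#' separate pair of columns -- saturations and arteriovenous differences
#' rendered in percent, flows and metabolic rates rounded to the tens
#' place, T2 to the nearest ms. Metabolic rates are averaged
#' per-subject-then-across-subjects (each record row is one subject), not
#' recomputed from parameter means.
#'
#' @param records Tibble with columns `subject_id`, `condition`, a site
#'   column (`site` or `site_or_scope`), and any of the parameter columns
#'   `sao2`, `svo2`, `avdo2`, `t2`, `bfr`, `delta_bfr`, `rmro2`.
#' @return A tibble with columns `site`, `parameter`, `condition`, `mean`,
#'   `sd`, `n`, `report_mean`, `report_sd` (reporting scale/rounding).
#' @export
summarize_cohort <- function(records) {
  site_col <- intersect(c("site", "site_or_scope"), names(records))[1]
  if (is.na(site_col)) abort("`records` needs a site column.")
  params <- intersect(
    c("sao2", "svo2", "avdo2", "t2", "bfr", "delta_bfr", "rmro2"),
    names(records)
  )
  if (length(params) == 0) abort("No parameter columns found.")
  long <- records |>
    dplyr::select(dplyr::all_of(c("subject_id", "condition", site_col,
                                  params))) |>
    tidyr::pivot_longer(dplyr::all_of(params), names_to = "parameter",
                        values_to = "value") |>
    dplyr::filter(!is.na(.data$value))
  percent_kinds <- c("sao2", "svo2", "avdo2")
  long |>
    dplyr::group_by(
      site = .data[[site_col]], .data$parameter, .data$condition
    ) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = if (dplyr::n() > 1) sd(.data$value) else 0,
      n = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      report_scale = ifelse(.data$parameter %in% percent_kinds, 100, 1),
      report_mean = purrr::map2_dbl(
        .data$mean * .data$report_scale, .data$parameter,
        round_for_report
      ),
      report_sd = purrr::map2_dbl(
        .data$sd * .data$report_scale, .data$parameter,
        round_for_report
      )
    ) |>
    dplyr::select(-"report_scale")
}

#' Significance stars for report tables
#'
#' Thresholds 0.05, 0.01, 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of `""`, `"*"`, `"**"`, `"***"`.
#' @export
significance_stars <- function(p) {
  dplyr::case_when(
    is.na(p) ~ "",
    p < 0.001 ~ "***",
    p < 0.01 ~ "**",
    p < 0.05 ~ "*",
    TRUE ~ ""
  )
}

#' Boxplot panel of cohort metabolic parameters across conditions
#'
#' @param records As for [summarize_cohort()].
#' @param parameter Parameter column to plot.
#' @param site Optional site filter.
#' @return A ggplot: per-condition boxplots with subject trajectories.
#' @export
plot_condition_profiles <- function(records, parameter, site = NULL) {
  site_col <- intersect(c("site", "site_or_scope"), names(records))[1]
  if (!is.null(site) && !is.na(site_col)) {
    records <- records[records[[site_col]] == site, , drop = FALSE]
  }
  ggplot2::ggplot(
    records,
    ggplot2::aes(x = .data$condition, y = .data[[parameter]])
  ) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey92") +
    ggplot2::geom_line(
      ggplot2::aes(group = .data$subject_id), colour = "grey55",
      alpha = 0.6
    ) +
    ggplot2::geom_point(colour = "grey40", alpha = 0.7) +
    ggplot2::stat_summary(fun = mean, geom = "point", shape = 18,
                          size = 3, colour = "black") +
    ggplot2::labs(x = "Breathing condition", y = parameter,
                  title = site %||% "") +
    ggplot2::theme_minimal()
}
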