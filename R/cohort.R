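#' Default cohort demography specification
#'
#' Marginal distributions for a healthy-adult renal imaging cohort:
#' truncated normals `(mean, sd, min, max)` for age, height, weight,
#' hemoglobin and the two kidney masses, plus the male fraction. Hemoglobin
#' is the measured quantity (finger-prick); hematocrit is derived from it by
#' the conversion `Hct(%) = Hb (g/dL) / 0.34`, so its spec is expressed on
#' the hemoglobin scale (mean 14.28 g/dL and SD 1.36 g/dL correspond to
#' Hct 42% +/- 4%, range 34%-46%).
#'
#' @return A named list of distribution specs, each
#'   `c(mean, sd, min, max)`, plus `male_fraction`.
#' @export
default_demography <- function() {
  list(
    age = c(mean = 30, sd = 9, min = 23, max = 53), # years
    height = c(mean = 1.71, sd = 0.12, min = 1.50, max = 1.91), # m
    weight = c(mean = 71, sd = 14, min = 55, max = 100), # kg
    hb = c(mean = 0.34 * 42, sd = 0.34 * 4,
           min = 0.34 * 34, max = 0.34 * 46), # g/dL
    left_kidney_mass = c(mean = 172, sd = 29, min = 124, max = 226), # g
    right_kidney_mass = c(mean = 159, sd = 26, min = 117, max = 221), # g
    male_fraction = 0.5
  )
}

#' Generate a synthetic subject cohort
#'
#' Draws subject attributes independently from the truncated normal
#' distributions in `demography` and derives hematocrit from hemoglobin by
#' the `Hb / 0.34` rule ([hb_to_hct()]).
#'
#' @param n_subjects Number of subjects (>= 1).
#' @param seed Integer seed; the cohort is a pure function of
#'   `(n_subjects, seed, demography)`.
#' @param demography Distribution spec as from [default_demography()].
#' @return A tibble with one row per subject: `subject_id`, `sex`, `age`,
#'   `height`, `weight`, `hb`, `hct`, `left_kidney_mass`,
#'   `right_kidney_mass`.
#' @examples
#' cohort <- generate_cohort(10, seed = 7)
#' mean(cohort$hct)
#' @export
generate_cohort <- function(n_subjects = 10, seed = 1,
                            demography = default_demography()) {
  if (!is.numeric(n_subjects) || n_subjects < 1) {
    abort("`n_subjects` must be >= 1.")
  }
  n_subjects <- as.integer(n_subjects)
  specs <- demography[setdiff(names(demography), "male_fraction")]
  for (nm in names(specs)) {
    s <- specs[[nm]]
    if (s["sd"] < 0) abort(sprintf("SD for `%s` must be >= 0.", nm))
    if (s["mean"] < s["min"] || s["mean"] > s["max"]) {
      abort(sprintf("Truncation bounds for `%s` exclude the mean.", nm))
    }
  }
  with_local_seed(seed, {
    draws <- lapply(specs, function(s) {
      rnorm_trunc(n_subjects, s["mean"], s["sd"], s["min"], s["max"])
    })
    n_male <- round(demography$male_fraction * n_subjects)
    sex <- sample(c(rep("M", n_male), rep("F", n_subjects - n_male)))
    tibble(
      subject_id = sprintf("S%02d", seq_len(n_subjects)),
      sex = sex,
      age = draws$age,
      height = draws$height,
      weight = draws$weight,
      hb = draws$hb,
      hct = hb_to_hct(draws$hb),
      left_kidney_mass = draws$left_kidney_mass,
      right_kidney_mass = draws$right_kidney_mass
    )
  })
}

#' Default per-condition physiological truth specification
#'
#' Marginal means and SDs of arterial saturation, site-wise venous
#' saturation (fractions) and site-wise blood flow rate (mL/min) for the
#' four stages of a graded isocapnic hypoxia protocol: baseline room air,
#' mild hypoxia (end-tidal O2 target 62 mmHg, arterial saturation ~90%),
#' moderate hypoxia (52 mmHg, ~85%), and recovery room air.
#'
#' @return A list with elements `conditions` (ordered stage labels),
#'   `target_peto2` (mmHg per stage), `sao2`, `svo2`, `bfr` (per-stage and,
#'   for the latter two, per-site mean/sd tables) and
#'   `subject_effect_frac`, the fraction of each between-subject SD
#'   attributed to a subject-level offset shared across conditions (making
#'   repeated measures within a subject correlated).
#' @export
default_physiology <- function() {
  conditions <- c("baseline", "mild_hypoxia", "moderate_hypoxia", "recovery")
  sites <- c("left_renal_vein", "suprarenal_ivc", "infrarenal_ivc")
  m <- function(...) {
    x <- matrix(c(...), nrow = 3, byrow = TRUE,
                dimnames = list(sites, conditions))
    x
  }
  list(
    conditions = conditions,
    sites = sites,
    target_peto2 = c(baseline = 100, mild_hypoxia = 62,
                     moderate_hypoxia = 52, recovery = 100),
    sao2_mean = c(baseline = 0.99, mild_hypoxia = 0.90,
                  moderate_hypoxia = 0.84, recovery = 0.98),
    sao2_sd = c(baseline = 0.01, mild_hypoxia = 0.01,
                moderate_hypoxia = 0.02, recovery = 0.01),
    svo2_mean = m(
      0.92, 0.83, 0.76, 0.92,
      0.83, 0.71, 0.68, 0.80,
      0.71, 0.67, 0.62, 0.75
    ),
    svo2_sd = m(
      0.03, 0.04, 0.05, 0.03,
      0.04, 0.05, 0.06, 0.03,
      0.10, 0.04, 0.10, 0.05
    ),
    bfr_mean = m(
      410, 430, 440, 410,
      2420, 2750, 2970, 2510,
      1390, 1580, 1760, 1510
    ),
    bfr_sd = m(
      65, 56, 48, 56,
      650, 560, 590, 380,
      530, 420, 380, 240
    ),
    svo2_floor = 0.30,
    subject_effect_frac = 0.5
  )
}

# Draw one parameter for all subjects x conditions with a subject-level
# random offset shared across conditions. The marginal per-condition SD is
# preserved: var = (f * sd)^2 from the subject offset + (1 - f^2) * sd^2
# residual. Returns an n_subjects x n_conditions matrix.
draw_correlated <- function(n, means, sds, frac) {
  k <- length(means)
  subj_scale <- frac * mean(sds)
  u <- rnorm(n, 0, 1)
  resid_sd <- sqrt(pmax(sds^2 - subj_scale^2, 0))
  out <- matrix(NA_real_, n, k)
  for (j in seq_len(k)) {
    out[, j] <- means[j] + u * subj_scale + rnorm(n, 0, resid_sd[j])
  }
  out
}

#' Generate per-condition physiological ground truth for a cohort
#'
#' For each subject and breathing condition, draws arterial saturation,
#' site-wise venous saturation and site-wise blood flow rate from the
#' marginal distributions in `physiology`, with a subject-level random
#' offset shared across conditions so that repeated measures within a
#' subject are correlated. Physiological constraints are enforced by
#' redrawing: venous saturation strictly below arterial at every site (and
#' above a physiological floor, default 30% saturation), all flows
#' positive, and suprarenal IVC flow strictly above infrarenal.
#'
#' @param cohort Tibble from [generate_cohort()].
#' @param seed Integer seed.
#' @param physiology Spec as from [default_physiology()].
#' @param conditions Subset/order of stages to generate.
#' @return A long tibble with columns `subject_id`, `condition`,
#'   `target_peto2`, `sao2`, `site`, `svo2`, `bfr`.
#' @examples
#' cohort <- generate_cohort(2, seed = 1)
#' truth <- generate_condition_truth(cohort, seed = 2)
#' @export
generate_condition_truth <- function(cohort, seed = 1,
                                     physiology = default_physiology(),
                                     conditions = physiology$conditions) {
  bad <- setdiff(conditions, physiology$conditions)
  if (length(bad) > 0) {
    abort(sprintf("Unknown condition(s): %s.", paste(bad, collapse = ", ")))
  }
  n <- nrow(cohort)
  sites <- physiology$sites
  frac <- physiology$subject_effect_frac
  with_local_seed(seed, {
    redraw_until <- function(x, ok_fun, draw_fun) {
      bad <- which(!ok_fun(x))
      tries <- 0L
      while (length(bad) > 0L) {
        tries <- tries + 1L
        if (tries > 10000L) abort("Constraint redraw failed to converge.")
        x[bad] <- draw_fun(length(bad), bad)
        bad <- bad[!ok_fun(x[bad])]
      }
      x
    }

    sao2 <- draw_correlated(n, physiology$sao2_mean[conditions],
                            physiology$sao2_sd[conditions], frac)
    sao2 <- pmin(sao2, 1) # saturation cannot exceed 100%

    out <- vector("list", length(sites))
    for (s in seq_along(sites)) {
      site <- sites[s]
      svo2 <- draw_correlated(n, physiology$svo2_mean[site, conditions],
                              physiology$svo2_sd[site, conditions], frac)
      # venous strictly between the floor and arterial, per subject x
      # condition
      floor_y <- physiology$svo2_floor %||% 0
      for (j in seq_along(conditions)) {
        mj <- physiology$svo2_mean[site, conditions[j]]
        sj <- physiology$svo2_sd[site, conditions[j]]
        ok <- function(v, sa) v < sa & v > floor_y
        idx <- which(!ok(svo2[, j], sao2[, j]))
        tries <- 0L
        while (length(idx) > 0L) {
          tries <- tries + 1L
          if (tries > 10000L) abort("SvO2 < SaO2 redraw failed to converge.")
          svo2[idx, j] <- rnorm(length(idx), mj, sj)
          idx <- idx[!ok(svo2[idx, j], sao2[idx, j])]
        }
      }
      bfr <- draw_correlated(n, physiology$bfr_mean[site, conditions],
                             physiology$bfr_sd[site, conditions], frac)
      for (j in seq_along(conditions)) {
        mj <- physiology$bfr_mean[site, conditions[j]]
        sj <- physiology$bfr_sd[site, conditions[j]]
        bfr[, j] <- redraw_until(
          bfr[, j], function(x) x > 0,
          function(m, i) rnorm(m, mj, sj)
        )
      }
      out[[s]] <- tibble(
        subject_id = rep(cohort$subject_id, times = length(conditions)),
        condition = rep(conditions, each = n),
        site = site,
        sao2 = as.vector(sao2),
        svo2 = as.vector(svo2),
        bfr = as.vector(bfr)
      )
    }
    truth <- dplyr::bind_rows(out)

    # suprarenal IVC flow must exceed infrarenal: resolve violations by
    # redrawing the infrarenal value below the paired suprarenal one
    wide <- tidyr::pivot_wider(
      dplyr::select(truth, "subject_id", "condition", "site", "bfr"),
      names_from = "site", values_from = "bfr"
    )
    viol <- which(wide$suprarenal_ivc <= wide$infrarenal_ivc)
    for (i in viol) {
      mj <- physiology$bfr_mean["infrarenal_ivc", wide$condition[i]]
      sj <- physiology$bfr_sd["infrarenal_ivc", wide$condition[i]]
      repeat {
        cand <- rnorm(1, mj, sj)
        if (cand > 0 && cand < wide$suprarenal_ivc[i]) break
      }
      wide$infrarenal_ivc[i] <- cand
    }
    truth <- dplyr::rows_update(
      truth,
      tidyr::pivot_longer(wide, cols = dplyr::all_of(sites),
                          names_to = "site", values_to = "bfr"),
      by = c("subject_id", "condition", "site")
    )

    truth$target_peto2 <- physiology$target_peto2[truth$condition]
    truth$condition <- factor(truth$condition, levels = physiology$conditions)
    dplyr::arrange(
      dplyr::select(truth, "subject_id", "condition", "target_peto2",
                    "site", "sao2", "svo2", "bfr"),
      .data$subject_id, .data$condition, .data$site
    )
  })
}
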