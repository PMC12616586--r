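#' Pipeline run configuration
#'
#' Bundles every knob of the simulate - fit - quantify - analyze workflow
#' into one serializable object. All randomness derives from the single
#' root `seed` through fixed per-stage offsets, so a run is a pure function
#' of its configuration.
#'
#' @param seed Root integer seed.
#' @param n_subjects Cohort size.
#' @param conditions Ordered breathing-stage labels.
#' @param sites Vessel sites to image.
#' @param acquisitions_per_condition Repeated acquisitions per subject,
#'   condition and site; derived parameters are averaged across them.
#' @param matrix_size Image matrix (pixels).
#' @param effective_tes Five effective echo times, ms.
#' @param s0 Fully-relaxed vessel signal, a.u.
#' @param noise_sigma Per-pixel complex-noise SD of the magnitude images,
#'   in signal units (default `s0 / 50`, i.e. vessel SNR 50 at TE 0).
#' @param velocity_noise_sd Gaussian velocity-map noise SD, cm/s.
#' @param subject_effect_frac Fraction of between-subject SD shared across
#'   conditions (within-subject correlation of the truth).
#' @param calibration Name of the calibration config (`"renal-3T-v1"`).
#' @param sd_scale Multiplier on every physiological SD (0 gives the
#'   deterministic cohort at the specification means).
#' @param output_dir Where [run_pipeline()] writes artifacts.
#' @param write_images Also write every rendered series as NIfTI (off by
#'   default; tables are always written).
#' @return A `run_config` list.
#' @export
run_config <- function(seed = 1, n_subjects = 10,
                       conditions = c("baseline", "mild_hypoxia",
                                      "moderate_hypoxia", "recovery"),
                       sites = c("left_renal_vein", "suprarenal_ivc",
                                 "infrarenal_ivc"),
                       acquisitions_per_condition = 5,
                       matrix_size = c(64, 64),
                       effective_tes = c(0, 40, 80, 160, 240),
                       s0 = 1000, noise_sigma = s0 / 50,
                       velocity_noise_sd = 0.5,
                       subject_effect_frac = 0.5,
                       calibration = "renal-3T-v1",
                       sd_scale = 1,
                       output_dir = tempfile("renoxi-run-"),
                       write_images = FALSE) {
  structure(
    list(
      seed = as.integer(seed), n_subjects = as.integer(n_subjects),
      conditions = conditions, sites = sites,
      acquisitions_per_condition = as.integer(acquisitions_per_condition),
      matrix_size = as.integer(matrix_size),
      effective_tes = as.numeric(effective_tes),
      s0 = s0, noise_sigma = noise_sigma,
      velocity_noise_sd = velocity_noise_sd,
      subject_effect_frac = subject_effect_frac,
      calibration = calibration, sd_scale = sd_scale,
      output_dir = output_dir, write_images = isTRUE(write_images)
    ),
    class = "run_config"
  )
}

#' @rdname run_config
#' @param path YAML file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15)
  invisible(path)
}

#' @rdname run_config
#' @param config A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(run_config, y)
}

# Resolve the named calibration of a config.
config_calibration <- function(config) {
  if (identical(config$calibration, "renal-3T-v1")) {
    default_calibration()
  } else if (file.exists(config$calibration)) {
    read_calibration_yaml(config$calibration)
  } else {
    abort(sprintf("Unknown calibration '%s'.", config$calibration))
  }
}

# Scale every SD of a physiology/demography spec by `s` (0 = deterministic).
scale_physiology_sds <- function(phys, s) {
  phys$sao2_sd <- phys$sao2_sd * s
  phys$svo2_sd <- phys$svo2_sd * s
  phys$bfr_sd <- phys$bfr_sd * s
  phys
}

scale_demography_sds <- function(demo, s) {
  for (nm in setdiff(names(demo), "male_fraction")) {
    demo[[nm]]["sd"] <- demo[[nm]]["sd"] * s
    if (s == 0) {
      demo[[nm]]["min"] <- -Inf
      demo[[nm]]["max"] <- Inf
    }
  }
  demo
}

#' Simulate and measure every acquisition of a cohort experiment
#'
#' For each subject, condition, site and repeat acquisition: renders the
#' T2-prepared and velocity series from the ground truth, fits the
#' ROI-mean T2 decay, inverts the oxygenation calibration, and quantifies
#' flow. Derived parameters are then averaged across the repeat
#' acquisitions.
#'
#' @param cohort From [generate_cohort()].
#' @param truth From [generate_condition_truth()].
#' @param config A [run_config()].
#' @return A list with `per_acquisition` (one row per rendered
#'   acquisition: `t2`, `svo2`, `bfr`) and `measurements` (averaged across
#'   acquisitions, one row per subject x condition x site).
#' @export
simulate_measurements <- function(cohort, truth, config = run_config()) {
  calib <- config_calibration(config)
  hct_by_subject <- setNames(cohort$hct, cohort$subject_id)
  rows <- vector("list", nrow(truth) * config$acquisitions_per_condition)
  ix <- 0L
  img_dir <- file.path(config$output_dir, "images")
  if (config$write_images) {
    dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  }
  for (r in seq_len(nrow(truth))) {
    tr <- truth[r, ]
    hct <- hct_by_subject[[tr$subject_id]]
    geom <- site_geometry(
      tr$site,
      matrix_size = config$matrix_size,
      vessel_center = round(config$matrix_size / 2),
      effective_tes = config$effective_tes,
      noise_sigma = config$noise_sigma
    )
    for (a in seq_len(config$acquisitions_per_condition)) {
      ix <- ix + 1L
      acq_id <- sprintf("%s_%s_%s_a%d", tr$subject_id,
                        as.character(tr$condition), tr$site, a)
      seed_t2 <- derive_seed(config$seed, 100000L + ix)
      seed_pc <- derive_seed(config$seed, 200000L + ix)
      ser_t2 <- render_t2prep_series(
        svo2 = tr$svo2, hct = hct, geom = geom, calib = calib,
        seed = seed_t2, s0 = config$s0, acquisition_id = acq_id
      )
      ser_pc <- render_velocity_series(
        bfr = tr$bfr, geom = geom, seed = seed_pc,
        velocity_noise_sd = config$velocity_noise_sd,
        acquisition_id = acq_id
      )
      if (config$write_images) {
        write_t2prep_nifti(
          ser_t2,
          file.path(img_dir, paste0(acq_id, "_t2prep.nii.gz")),
          file.path(img_dir, paste0(acq_id, "_t2prep_mask.nii.gz"))
        )
        write_velocity_nifti(
          ser_pc,
          file.path(img_dir, paste0(acq_id, "_velocity.nii.gz")),
          file.path(img_dir, paste0(acq_id, "_velocity_mask.nii.gz"))
        )
      }
      fit <- fit_t2(roi_mean_signal(ser_t2))
      # noise can push a fitted T2 slightly past the oxygenated maximum;
      # a 5% band maps such fits to the boundary saturation
      svo2_hat <- t2_to_svo2(fit$t2, hct, calib, boundary_tol = 0.05)$svo2
      flow <- compute_bfr(ser_pc, tr$site)
      rows[[ix]] <- tibble(
        subject_id = tr$subject_id, condition = as.character(tr$condition),
        site = tr$site, acquisition = a,
        t2 = fit$t2, r_squared = fit$r_squared,
        svo2 = svo2_hat, bfr = flow$bfr
      )
    }
  }
  per_acq <- dplyr::bind_rows(rows)
  measurements <- per_acq |>
    dplyr::group_by(.data$subject_id, .data$condition, .data$site) |>
    dplyr::summarise(
      t2 = mean(.data$t2), svo2 = mean(.data$svo2), bfr = mean(.data$bfr),
      n_acquisitions = dplyr::n(), .groups = "drop"
    ) |>
    dplyr::left_join(
      dplyr::distinct(truth, .data$subject_id,
                      condition = as.character(.data$condition),
                      .data$sao2),
      by = c("subject_id", "condition")
    )
  list(per_acquisition = per_acq, measurements = measurements)
}

#' Derive per-subject metabolic records from site measurements
#'
#' Builds the analysis table: one row per subject x condition x scope.
#' The left-kidney scope carries the renal-vein measurements plus the
#' unilateral metabolic rate; the two IVC scopes carry their measured
#' parameters; the bilateral scope carries the IVC flow difference, the
#' flow-weighted mixed venous saturation and the bilateral metabolic rate
#' normalized by total kidney mass. Metabolic rates are computed per
#' subject first; cohort averaging happens only in [summarize_cohort()].
#'
#' @param measurements One row per subject x condition x site with
#'   columns `sao2`, `svo2`, `bfr`, `t2` (as from
#'   [simulate_measurements()], or real tabular data).
#' @param cohort Subject table with `hct` and kidney masses.
#' @param constants From [physiological_constants()].
#' @return A tibble with columns `subject_id`, `condition`,
#'   `site_or_scope`, `sao2`, `svo2`, `avdo2`, `t2`, `bfr`, `delta_bfr`,
#'   `rmro2`, `flag`.
#' @export
derive_metabolic_records <- function(measurements, cohort,
                                     constants = physiological_constants()) {
  m <- dplyr::left_join(
    measurements,
    dplyr::select(cohort, "subject_id", "hct", "left_kidney_mass",
                  "right_kidney_mass"),
    by = "subject_id"
  )
  site_rec <- m |>
    dplyr::mutate(
      site_or_scope = ifelse(.data$site == "left_renal_vein",
                             "left_kidney", .data$site),
      avdo2 = .data$sao2 - .data$svo2,
      delta_bfr = NA_real_,
      rmro2 = ifelse(
        .data$site == "left_renal_vein",
        constants$crbc * .data$hct * .data$bfr *
          (.data$sao2 - .data$svo2) / .data$left_kidney_mass * 100,
        NA_real_
      )
    )
  wide <- m |>
    dplyr::filter(.data$site %in% c("suprarenal_ivc", "infrarenal_ivc")) |>
    dplyr::select("subject_id", "condition", "site", "sao2", "svo2",
                  "bfr", "hct", "left_kidney_mass", "right_kidney_mass") |>
    tidyr::pivot_wider(names_from = "site",
                       values_from = c("svo2", "bfr"))
  bilateral <- NULL
  if (nrow(wide) > 0 &&
      all(c("svo2_suprarenal_ivc", "svo2_infrarenal_ivc",
            "bfr_suprarenal_ivc", "bfr_infrarenal_ivc") %in% names(wide))) {
    total_mass <- wide$left_kidney_mass + wide$right_kidney_mass
    mixed <- (wide$bfr_suprarenal_ivc * wide$svo2_suprarenal_ivc -
                wide$bfr_infrarenal_ivc * wide$svo2_infrarenal_ivc) /
      (wide$bfr_suprarenal_ivc - wide$bfr_infrarenal_ivc)
    rmro2_bil <- constants$crbc * wide$hct / total_mass * 100 *
      (wide$bfr_suprarenal_ivc * (wide$sao2 - wide$svo2_suprarenal_ivc) -
         wide$bfr_infrarenal_ivc * (wide$sao2 - wide$svo2_infrarenal_ivc))
    bilateral <- tibble(
      subject_id = wide$subject_id, condition = wide$condition,
      site_or_scope = "bilateral",
      sao2 = wide$sao2, svo2 = mixed, avdo2 = wide$sao2 - mixed,
      t2 = NA_real_,
      bfr = NA_real_,
      delta_bfr = wide$bfr_suprarenal_ivc - wide$bfr_infrarenal_ivc,
      rmro2 = rmro2_bil,
      flag = dplyr::case_when(
        mixed < 0 | mixed > 1 ~ "mixed SvO2 outside [0, 1]",
        rmro2_bil < 0 ~ "negative bilateral rMRO2",
        TRUE ~ ""
      )
    )
  }
  site_rec <- site_rec |>
    dplyr::mutate(
      flag = dplyr::case_when(
        .data$avdo2 < 0 ~ "negative AVDO2 (SvO2 > SaO2)",
        TRUE ~ ""
      )
    ) |>
    dplyr::select("subject_id", "condition", "site_or_scope", "sao2",
                  "svo2", "avdo2", "t2", "bfr", "delta_bfr", "rmro2",
                  "flag")
  dplyr::bind_rows(site_rec, bilateral) |>
    dplyr::arrange(.data$subject_id, .data$condition, .data$site_or_scope)
}

#' Run the full simulate - fit - quantify - analyze pipeline
#'
#' Generates a cohort and its condition truth, renders and measures every
#' acquisition, derives per-subject metabolic records, and produces the
#' cohort summary plus repeated-measures ANOVA and Bonferroni-adjusted
#' pairwise tables. All tables are written as CSV under
#' `config$output_dir` together with the config as YAML and a manifest
#' (package version, seed, config hash); rendered image stacks are written
#' as NIfTI when `config$write_images` is set. Re-running with the same
#' config reproduces every numeric output exactly.
#'
#' @param config A [run_config()].
#' @param stages Subset of `c("simulate", "fit", "quantify", "analyze")`
#'   to run (earlier stages are always implied).
#' @return A list with `cohort`, `truth`, `per_acquisition`,
#'   `measurements`, `records`, `summary`, `anova`, `pairwise`,
#'   `output_dir`, invisibly-written artifact paths in `files`.
#' @export
run_pipeline <- function(config = run_config(),
                         stages = c("simulate", "fit", "quantify",
                                    "analyze")) {
  stages <- match.arg(stages, several.ok = TRUE)
  run_stage <- function(s) {
    s %in% stages ||
      match(s, c("simulate", "fit", "quantify", "analyze")) <=
        max(match(stages, c("simulate", "fit", "quantify", "analyze")))
  }
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  emit <- function(x, name) {
    p <- file.path(config$output_dir, name)
    utils::write.csv(x, p, row.names = FALSE)
    files <<- c(files, p)
    p
  }
  log_lines <- character(0)
  log_msg <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", format(Sys.time()),
                                       sprintf(fmt, ...)))
  }

  # -- simulate ------------------------------------------------------------
  log_msg("simulate: n_subjects = %d, seed = %d", config$n_subjects,
          config$seed)
  demo <- scale_demography_sds(default_demography(), config$sd_scale)
  phys <- scale_physiology_sds(default_physiology(), config$sd_scale)
  phys$subject_effect_frac <- config$subject_effect_frac
  cohort <- generate_cohort(config$n_subjects,
                            seed = derive_seed(config$seed, 1L),
                            demography = demo)
  truth <- generate_condition_truth(
    cohort, seed = derive_seed(config$seed, 2L), physiology = phys,
    conditions = config$conditions
  )
  truth <- truth[truth$site %in% config$sites, , drop = FALSE]
  emit(cohort, "cohort.csv")
  emit(truth, "condition_truth.csv")
  out <- list(cohort = cohort, truth = truth, output_dir = config$output_dir)

  # -- fit (render + measure) ---------------------------------------------
  if (run_stage("fit")) {
    log_msg("fit: %d acquisitions",
            nrow(truth) * config$acquisitions_per_condition)
    meas <- simulate_measurements(cohort, truth, config)
    emit(meas$per_acquisition, "acquisition_fits.csv")
    emit(meas$measurements, "measurements.csv")
    out$per_acquisition <- meas$per_acquisition
    out$measurements <- meas$measurements
  }

  # -- quantify ------------------------------------------------------------
  if (run_stage("quantify")) {
    records <- derive_metabolic_records(out$measurements, cohort)
    emit(records, "metabolic_records.csv")
    out$records <- records
  }

  # -- analyze -------------------------------------------------------------
  if (run_stage("analyze")) {
    out$summary <- summarize_cohort(out$records)
    emit(out$summary, "cohort_summary.csv")
    grid <- dplyr::distinct(
      tidyr::pivot_longer(
        out$records,
        cols = dplyr::any_of(c("t2", "svo2", "avdo2", "bfr", "delta_bfr",
                               "rmro2")),
        names_to = "parameter", values_to = "value"
      ) |> dplyr::filter(!is.na(.data$value)),
      .data$site_or_scope, .data$parameter
    )
    safe_stats <- function(fun) {
      function(p, s) {
        tryCatch(fun(out$records, p, s), error = function(e) NULL)
      }
    }
    out$anova <- dplyr::bind_rows(purrr::map2(
      grid$parameter, grid$site_or_scope, safe_stats(rm_anova)
    ))
    out$pairwise <- dplyr::bind_rows(purrr::map2(
      grid$parameter, grid$site_or_scope, safe_stats(pairwise_bonferroni)
    ))
    if (nrow(out$pairwise) > 0) {
      out$pairwise$stars <- significance_stars(out$pairwise$adjusted_p)
    }
    emit(out$anova, "rm_anova.csv")
    emit(out$pairwise, "pairwise_bonferroni.csv")
  }

  # -- manifest ------------------------------------------------------------
  manifest <- list(
    package = "renoxi",
    version = as.character(utils::packageVersion("renoxi")),
    seed = config$seed,
    config_hash = rlang::hash(unclass(config)),
    stages = stages,
    n_acquisitions = nrow(truth) * config$acquisitions_per_condition
  )
  yaml::write_yaml(manifest, file.path(config$output_dir, "manifest.yaml"))
  write_run_config(config, file.path(config$output_dir, "config.yaml"))
  writeLines(log_lines, file.path(config$output_dir, "run.log"))
  out$files <- files
  out$manifest <- manifest
  invisible(out)
}
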