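test_that("cohort generation is reproducible and respects the demography spec", {
  c1 <- generate_cohort(10, seed = 42)
  c2 <- generate_cohort(10, seed = 42)
  expect_identical(c1, c2)
  c3 <- generate_cohort(10, seed = 43)
  expect_false(identical(c1, c3))

  demo <- default_demography()
  expect_true(all(c1$left_kidney_mass >= demo$left_kidney_mass["min"]))
  expect_true(all(c1$left_kidney_mass <= demo$left_kidney_mass["max"]))
  expect_true(all(c1$hct > 0.15 & c1$hct < 0.60))
  # hematocrit derived from hemoglobin by the 0.34 rule
  expect_equal(c1$hct, c1$hb / 0.34 / 100, tolerance = 1e-12)
  expect_equal(sort(table(c1$sex)), sort(table(c(rep("M", 5), rep("F", 5)))),
               ignore_attr = TRUE)
})

test_that("degenerate SD-zero cohort sits exactly at the specification means", {
  demo <- default_demography()
  for (nm in setdiff(names(demo), "male_fraction")) demo[[nm]]["sd"] <- 0
  one <- generate_cohort(1, seed = 5, demography = demo)
  expect_equal(one$left_kidney_mass, 172)
  expect_equal(one$right_kidney_mass, 159)
  expect_equal(one$hct, 0.42, tolerance = 1e-12)
  expect_equal(one$height, 1.71)
})

test_that("distribution specs whose bounds exclude the mean are rejected", {
  demo <- default_demography()
  demo$age["min"] <- 40 # mean is 30
  expect_error(generate_cohort(5, seed = 1, demography = demo),
               "exclude the mean")
})

test_that("sample means of generated parameters concentrate on the generator mean", {
  # analytic mean of a normal truncated to [lo, hi]
  trunc_mean <- function(spec) {
    a <- (spec["min"] - spec["mean"]) / spec["sd"]
    b <- (spec["max"] - spec["mean"]) / spec["sd"]
    unname(spec["mean"] + spec["sd"] * (dnorm(a) - dnorm(b)) /
             (pnorm(b) - pnorm(a)))
  }
  # 200 replicate cohorts at n = 10: each empirical grand mean within
  # 4 standard errors of the truncated-normal mean (truncation at the
  # asymmetric observed ranges shifts the mean slightly off the nominal
  # center; the nominal SD is a conservative SE bound)
  demo <- default_demography()
  reps <- 200
  means <- purrr::map(seq_len(reps), function(i) {
    co <- generate_cohort(10, seed = 1000 + i)
    c(left = mean(co$left_kidney_mass), right = mean(co$right_kidney_mass),
      hb = mean(co$hb), weight = mean(co$weight))
  })
  m <- do.call(rbind, means)
  grand <- colMeans(m)
  target <- c(left = trunc_mean(demo$left_kidney_mass),
              right = trunc_mean(demo$right_kidney_mass),
              hb = trunc_mean(demo$hb),
              weight = trunc_mean(demo$weight))
  se <- c(left = 29, right = 26, hb = 0.34 * 4, weight = 14) / sqrt(2000)
  expect_true(all(abs(grand - target) < 4 * se))
  # and a single cohort's left-mass mean lies within 3 nominal SEs
  one <- generate_cohort(10, seed = 77)
  expect_lt(abs(mean(one$left_kidney_mass) - target["left"]),
            3 * 29 / sqrt(10))
})

test_that("condition truth hits the spec means when SDs are zero", {
  demo <- default_demography()
  for (nm in setdiff(names(demo), "male_fraction")) demo[[nm]]["sd"] <- 0
  cohort <- generate_cohort(2, seed = 1, demography = demo)
  phys <- default_physiology()
  phys$sao2_sd[] <- 0
  phys$svo2_sd[] <- 0
  phys$bfr_sd[] <- 0
  truth <- generate_condition_truth(cohort, seed = 1, physiology = phys)

  base_lrv <- truth[truth$condition == "baseline" &
                      truth$site == "left_renal_vein", ]
  expect_equal(base_lrv$sao2, rep(0.99, 2))
  expect_equal(base_lrv$svo2, rep(0.92, 2))
  expect_equal(base_lrv$bfr, rep(410, 2))

  mod_lrv <- truth[truth$condition == "moderate_hypoxia" &
                     truth$site == "left_renal_vein", ]
  expect_equal(mod_lrv$sao2, rep(0.84, 2))
  expect_equal(mod_lrv$svo2, rep(0.76, 2))
})

test_that("condition truth enforces physiological ordering constraints", {
  cohort <- generate_cohort(10, seed = 2)
  # many draws: venous strictly below arterial at every site, positive
  # flows, suprarenal above infrarenal
  for (s in 1:25) {
    truth <- generate_condition_truth(cohort, seed = s)
    expect_true(all(truth$svo2 < truth$sao2))
    expect_true(all(truth$svo2 > 0))
    expect_true(all(truth$bfr > 0))
    wide <- tidyr::pivot_wider(truth[, c("subject_id", "condition", "site",
                                         "bfr")],
                               names_from = "site", values_from = "bfr")
    expect_true(all(wide$suprarenal_ivc > wide$infrarenal_ivc))
  }
})

test_that("within-subject correlation is induced by the subject effect", {
  cohort <- generate_cohort(200, seed = 3)
  truth <- generate_condition_truth(cohort, seed = 4)
  wide <- tidyr::pivot_wider(
    truth[truth$site == "left_renal_vein", c("subject_id", "condition", "bfr")],
    names_from = "condition", values_from = "bfr"
  )
  r <- cor(wide$baseline, wide$recovery)
  # subject effect at 50% of between-subject SD implies correlation ~0.25
  expect_gt(r, 0.05)
})
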