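test_that("hemoglobin-to-hematocrit conversion follows the 0.34 rule", {
  expect_equal(hb_to_hct(14.28), 0.42, tolerance = 1e-12)
  expect_equal(hb_to_hct(0.34), 0.01, tolerance = 1e-12)
  expect_equal(hb_to_hct(11.56), 0.34, tolerance = 1e-12)
  expect_error(hb_to_hct(0), "> 0")
  expect_error(hb_to_hct(-3), "> 0")
})

test_that("kidney mass is volume times tissue density", {
  expect_equal(kidney_mass_from_volume(162.26), 171.9956, tolerance = 1e-9)
  expect_equal(kidney_mass_from_volume(100), 106)
  expect_error(kidney_mass_from_volume(0), "> 0")
})

test_that("unilateral rMRO2 reproduces the plug-in operating points", {
  # baseline cohort means -> 139.7, reported 140 after tens rounding
  base <- unilateral_rmro2(410, 0.99, 0.92, 0.42, 172)
  expect_equal(as.numeric(base), 19.93 * 0.42 * 410 * 0.07 / 172 * 100,
               tolerance = 1e-12)
  expect_equal(round_for_report(as.numeric(base), "rmro2"), 140)
  # moderate hypoxia means -> 171.3, reported 170
  mod <- unilateral_rmro2(440, 0.84, 0.76, 0.42, 172)
  expect_equal(round_for_report(as.numeric(mod), "rmro2"), 170)
  # zero extraction gives exactly zero
  expect_equal(as.numeric(unilateral_rmro2(410, 0.9, 0.9, 0.42, 172)), 0)
})

test_that("unilateral rMRO2 is homogeneous in its factors", {
  set.seed(31)
  for (i in 1:20) {
    bfr <- runif(1, 200, 600)
    sa <- runif(1, 0.9, 1)
    sv <- runif(1, 0.6, 0.85)
    h <- runif(1, 0.34, 0.5)
    m <- runif(1, 120, 220)
    base <- as.numeric(unilateral_rmro2(bfr, sa, sv, h, m))
    expect_equal(as.numeric(unilateral_rmro2(2 * bfr, sa, sv, h, m)),
                 2 * base, tolerance = 1e-12)
    expect_equal(as.numeric(unilateral_rmro2(bfr, sa, sv, 2 * h, m)),
                 2 * base, tolerance = 1e-12)
    expect_equal(as.numeric(unilateral_rmro2(bfr, sa, sv, h, 2 * m)),
                 base / 2, tolerance = 1e-12)
  }
})

test_that("negative extraction is flagged, not clipped", {
  out <- unilateral_rmro2(410, 0.90, 0.95, 0.42, 172)
  expect_lt(as.numeric(out), 0)
  expect_match(attr(out, "flag"), "negative")
})

test_that("flow-weighted mixing obeys its identities", {
  # equal saturations mix to themselves for any flows
  expect_equal(as.numeric(bilateral_svo2(2400, 0.8, 1300, 0.8)), 0.8,
               tolerance = 1e-12)
  # constructed identity: qvs = 2 qvi, svo2s = (Y + svo2i) / 2 mixes to Y
  set.seed(32)
  for (i in 1:20) {
    y <- runif(1, 0.5, 0.95)
    svi <- runif(1, 0.5, 0.95)
    qvi <- runif(1, 800, 1500)
    mix <- bilateral_svo2(2 * qvi, (y + svi) / 2, qvi, svi)
    expect_equal(as.numeric(mix), y, tolerance = 1e-10)
  }
  # characteristic IVC operating point mixes to ~0.99 (flagged near-boundary
  # values outside [0, 1] are possible and preserved)
  mix <- bilateral_svo2(2420, 0.83, 1390, 0.71)
  expect_equal(as.numeric(mix), 0.9919417, tolerance = 1e-6)
  out <- bilateral_svo2(2000, 0.9, 1500, 0.6)
  expect_gt(as.numeric(out), 1)
  expect_match(attr(out, "flag"), "inconsistent")
  expect_error(bilateral_svo2(1500, 0.8, 1500, 0.7), "zero")
})

test_that("direct and mixed bilateral forms agree to machine precision", {
  set.seed(33)
  n <- 10000
  qvi <- runif(n, 800, 2000)
  qvs <- qvi + runif(n, 100, 1500)
  svs <- runif(n, 0.6, 0.95)
  svi <- runif(n, 0.5, 0.95)
  sa <- runif(n, 0.85, 1)
  h <- runif(n, 0.34, 0.5)
  m <- runif(n, 250, 420)
  d <- as.numeric(bilateral_rmro2(qvs, svs, qvi, svi, sa, h, m,
                                  form = "direct"))
  x <- as.numeric(bilateral_rmro2(qvs, svs, qvi, svi, sa, h, m,
                                  form = "mixed"))
  expect_equal(d, x, tolerance = 1e-12)
})

test_that("equal-saturation bilateral collapses to the unilateral equation", {
  y <- 0.82
  out <- bilateral_rmro2(2400, y, 1400, y, 0.98, 0.42, 331)
  uni <- unilateral_rmro2(1000, 0.98, y, 0.42, 331)
  expect_equal(as.numeric(out), as.numeric(uni), tolerance = 1e-12)
})

test_that("a consistent two-kidney phantom conserves oxygen mass", {
  # equal kidneys each drained at flow q with venous saturation yv; the
  # IVC difference carries 2q at mixed saturation yv, so the bilateral
  # rate equals either kidney's unilateral rate
  q <- 420
  yv <- 0.90
  sa <- 0.99
  h <- 0.44
  mass <- 165
  qvi <- 1300
  svi <- 0.72
  qvs <- qvi + 2 * q
  svs <- (qvi * svi + 2 * q * yv) / qvs
  bil <- bilateral_rmro2(qvs, svs, qvi, svi, sa, h, 2 * mass)
  uni <- unilateral_rmro2(q, sa, yv, h, mass)
  expect_equal(as.numeric(bil), as.numeric(uni), tolerance = 1e-9)
})

test_that("extraction inconsistency yields a flagged negative bilateral rate", {
  out <- bilateral_rmro2(2000, 0.95, 1500, 0.60, 0.97, 0.42, 330)
  expect_lt(as.numeric(out), 0)
  expect_match(attr(out, "flag"), "negative")
})

test_that("reporting rounds by parameter convention", {
  expect_equal(round_for_report(139.7, "rmro2"), 140)
  expect_equal(round_for_report(171.3, "rmro2"), 170)
  expect_equal(round_for_report(92.4, "svo2"), 92)
  expect_equal(round_for_report(1025, "delta_bfr"), 1030) # half away from zero
  expect_equal(round_for_report(-135, "rmro2"), -140)
  expect_equal(round_for_report(158.5, "t2"), 159)
  expect_error(round_for_report(1, "unknown_kind"), "Unknown")
})
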