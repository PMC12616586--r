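tes5 <- c(0, 40, 80, 160, 240)

test_that("roi_mean_signal averages exactly over the mask", {
  # constant field: mean is the constant at every TE
  ser <- manual_t2prep_series(rep(7, 5), tes5)
  expect_equal(roi_mean_signal(ser)$signal, rep(7, 5))
  expect_equal(roi_mean_signal(ser)$te, tes5)

  # checkerboard of 0/2 under a full even-sized mask: mean 1
  ser2 <- manual_t2prep_series(rep(1, 5), tes5)
  chk <- outer(1:16, 1:16, function(i, j) 2 * ((i + j) %% 2))
  for (i in 1:5) ser2$images[, , i] <- chk
  ser2$roi_mask <- matrix(TRUE, 16, 16)
  expect_equal(roi_mean_signal(ser2)$signal, rep(1, 5))

  # singleton mask returns that pixel's trajectory
  ser3 <- manual_t2prep_series(c(5, 4, 3, 2, 1), tes5)
  mask1 <- matrix(FALSE, 16, 16)
  mask1[6, 6] <- TRUE
  ser3$roi_mask <- mask1
  expect_equal(roi_mean_signal(ser3)$signal, c(5, 4, 3, 2, 1))
})

test_that("roi_mean_signal rejects empty or mismatched masks", {
  ser <- manual_t2prep_series(rep(1, 5), tes5)
  ser$roi_mask <- matrix(FALSE, 16, 16)
  expect_error(roi_mean_signal(ser), "empty")
  ser$roi_mask <- matrix(TRUE, 8, 8)
  expect_error(roi_mean_signal(ser), "shape")
})

test_that("noiseless mono-exponential decay is recovered exactly", {
  for (t2_true in c(71, 100, 159)) {
    pts <- tibble::tibble(te = tes5, signal = 1000 * exp(-tes5 / t2_true))
    for (m in c("nls", "log_linear")) {
      fit <- fit_t2(pts, method = m)
      expect_equal(fit$t2, t2_true, tolerance = 1e-6)
      expect_equal(fit$s0, 1000, tolerance = 1e-6)
      expect_equal(fit$r_squared, 1, tolerance = 1e-9)
    }
  }
  # e-folding: points at (0, s0), (t, s0/e), (2t, s0/e^2) give T2 = t
  t <- 85
  pts <- tibble::tibble(te = c(0, t, 2 * t), signal = exp(-c(0, 1, 2)))
  expect_equal(fit_t2(pts)$t2, t, tolerance = 1e-9)
})

test_that("log-linear and nls agree to 1e-9 on noiseless data", {
  pts <- tibble::tibble(te = tes5, signal = 321 * exp(-tes5 / 127))
  f1 <- fit_t2(pts, method = "nls")
  f2 <- fit_t2(pts, method = "log_linear")
  expect_equal(f1$t2, f2$t2, tolerance = 1e-9)
})

test_that("fit is scale-equivariant and TE-shift covariant", {
  set.seed(11)
  sig <- 500 * exp(-tes5 / 140) * exp(rnorm(5, 0, 0.01))
  base <- fit_t2(tibble::tibble(te = tes5, signal = sig))
  # scaling signals by k scales S0 by k, leaves T2 unchanged
  k <- 3.7
  scaled <- fit_t2(tibble::tibble(te = tes5, signal = k * sig))
  expect_equal(scaled$t2, base$t2, tolerance = 1e-8)
  expect_equal(scaled$s0, k * base$s0, tolerance = 1e-8)
  # shifting TEs by delta leaves T2, scales S0 by exp(delta / T2)
  delta <- 30
  shifted <- fit_t2(tibble::tibble(te = tes5 + delta, signal = sig))
  expect_equal(shifted$t2, base$t2, tolerance = 1e-6)
  expect_equal(shifted$s0, base$s0 * exp(delta / base$t2), tolerance = 1e-6)
})

test_that("nls beats a 200x200 grid-search oracle on noisy series", {
  set.seed(21)
  for (rep in 1:3) {
    sig <- 1000 * exp(-tes5 / 120) + rnorm(5, 0, 25)
    fit <- fit_t2(tibble::tibble(te = tes5, signal = sig))
    ss_fit <- sum((sig - fit$s0 * exp(-tes5 / fit$t2))^2)
    oracle <- grid_search_t2(tes5, sig, s0_range = c(500, 1500),
                             t2_range = c(50, 250))
    expect_lte(ss_fit, oracle$ss + 1e-9)
  }
})

test_that("degenerate and invalid inputs fail loudly", {
  # non-decaying series: growing signal
  grow <- tibble::tibble(te = tes5, signal = exp(tes5 / 100))
  expect_error(fit_t2(grow, method = "log_linear"), "does not decay")
  expect_error(fit_t2(grow, method = "nls"), "does not decay")
  # non-positive signal under log_linear points the caller to nls
  neg <- tibble::tibble(te = tes5, signal = c(10, 5, 2, 1, -0.5))
  expect_error(fit_t2(neg, method = "log_linear"), "nls")
  # too few points
  expect_error(fit_t2(tibble::tibble(te = c(0, 50), signal = c(2, 1))),
               "3")
})

test_that("S0 can be fixed to the first-image signal", {
  pts <- tibble::tibble(te = tes5, signal = 800 * exp(-tes5 / 110))
  fit <- fit_t2(pts, s0_fixed = 800)
  expect_equal(fit$s0, 800)
  expect_equal(fit$t2, 110, tolerance = 1e-6)
})

test_that("tidy and glance return the broom-style frames", {
  pts <- tibble::tibble(te = tes5, signal = 1000 * exp(-tes5 / 159))
  fit <- fit_t2(pts)
  td <- tidy(fit)
  expect_equal(td$term, c("t2", "s0"))
  gl <- glance(fit)
  expect_equal(gl$n_points, 5)
  expect_s3_class(autoplot(fit), "ggplot")
})
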