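# Shared fixture builders. All synthetic, generated at test time.

# A small geometry that keeps rendering cheap.
tiny_geometry <- function(...) {
  acquisition_geometry(
    matrix_size = c(32, 32), vessel_center = c(16, 16),
    vessel_radii = c(5, 5), ...
  )
}

# Hand-built velocity series with exact known flow:
# uniform velocity v in a mask of n pixels, pixel_area chosen so the ROI
# area is exactly `area_cm2`.
uniform_velocity_series <- function(v = 10, area_cm2 = 1, n_maps = 5,
                                    matrix_size = c(16, 16)) {
  mask <- matrix(FALSE, matrix_size[1], matrix_size[2])
  mask[4:9, 4:9] <- TRUE
  n_pix <- sum(mask)
  maps <- array(0, dim = c(matrix_size, n_maps))
  for (i in seq_len(n_maps)) {
    frame <- matrix(0, matrix_size[1], matrix_size[2])
    frame[mask] <- v
    maps[, , i] <- frame
  }
  structure(
    list(velocity_maps = maps, pixel_area = area_cm2 / n_pix,
         roi_mask = mask, venc = Inf, acquisition_id = "manual"),
    class = "velocity_series"
  )
}

# Hand-built T2-prepared series from explicit per-TE vessel signals.
manual_t2prep_series <- function(vessel_signals, tes,
                                 matrix_size = c(16, 16),
                                 background = 0) {
  mask <- matrix(FALSE, matrix_size[1], matrix_size[2])
  mask[5:10, 5:10] <- TRUE
  imgs <- array(background, dim = c(matrix_size, length(tes)))
  for (i in seq_along(tes)) {
    frame <- matrix(background, matrix_size[1], matrix_size[2])
    frame[mask] <- vessel_signals[i]
    imgs[, , i] <- frame
  }
  structure(
    list(images = imgs, effective_tes = tes, roi_mask = mask,
         pixel_area = 0.0144, acquisition_id = "manual",
         t2_blood = NA_real_),
    class = "t2prep_series"
  )
}

# Brute-force grid search for the mono-exponential least-squares fit.
grid_search_t2 <- function(te, signal, s0_range, t2_range, n = 200) {
  s0s <- seq(s0_range[1], s0_range[2], length.out = n)
  t2s <- seq(t2_range[1], t2_range[2], length.out = n)
  best <- list(ss = Inf)
  for (s0 in s0s) {
    # vectorize over t2 for speed
    pred <- outer(te, t2s, function(x, t2) exp(-x / t2)) * s0
    ss <- colSums((signal - pred)^2)
    i <- which.min(ss)
    if (ss[i] < best$ss) best <- list(ss = ss[i], s0 = s0, t2 = t2s[i])
  }
  best
}

# From-scratch one-way within-subject ANOVA decomposition.
rm_anova_oracle <- function(d) {
  # d: subject_id, condition, value; complete balanced
  gm <- mean(d$value)
  subj_means <- tapply(d$value, d$subject_id, mean)
  cond_means <- tapply(d$value, d$condition, mean)
  n <- length(subj_means)
  k <- length(cond_means)
  ss_cond <- n * sum((cond_means - gm)^2)
  ss_subj <- k * sum((subj_means - gm)^2)
  ss_tot <- sum((d$value - gm)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  df1 <- k - 1
  df2 <- (k - 1) * (n - 1)
  f <- (ss_cond / df1) / (ss_err / df2)
  list(f = f, df1 = df1, df2 = df2,
       p = pf(f, df1, df2, lower.tail = FALSE))
}

# Invert the calibration by bisection on the forward map.
bisect_svo2 <- function(t2, hct, calib, tol = 1e-12) {
  lo <- calib$valid_svo2[1]
  hi <- calib$valid_svo2[2]
  f <- function(y) forward_t2(y, hct, calib) - t2
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (hi - lo < tol) break
  }
  (lo + hi) / 2
}
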