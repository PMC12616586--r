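#' Acquisition geometry for synthetic image series
#'
#' Describes the pixel grid, the elliptical vessel cross-section, the
#' velocity-encoding limit and the T2-preparation echo times used by the
#' forward renderers. Defaults model a small through-plane slice at 1.2 mm
#' in-plane resolution.
#'
#' @param matrix_size `c(rows, cols)` in pixels.
#' @param pixel_area Pixel area, cm^2 (1.2 mm isotropic = 0.0144 cm^2).
#' @param vessel_center `c(row, col)` of the vessel center, pixels.
#' @param vessel_radii `c(r_row, r_col)` ellipse semi-axes, pixels.
#' @param venc Velocity-encoding limit, cm/s; any rendered velocity above
#'   this would alias and is refused.
#' @param effective_tes Five effective echo times, ms, strictly increasing,
#'   first >= 0. The default `c(0, 40, 80, 160, 240)` spans blood-water T2
#'   from deeply desaturated (~70 ms) to fully oxygenated (~170 ms) venous
#'   blood.
#' @param noise_sigma Noise scale in signal units (per-pixel complex-noise
#'   SD for magnitude images; velocity-map noise SD in cm/s is set
#'   separately at render time).
#' @return An `acquisition_geometry` object (a validated list).
#' @export
acquisition_geometry <- function(matrix_size = c(64, 64),
                                 pixel_area = 0.0144,
                                 vessel_center = c(32, 32),
                                 vessel_radii = c(5, 5),
                                 venc = 60,
                                 effective_tes = c(0, 40, 80, 160, 240),
                                 noise_sigma = 0) {
  if (length(effective_tes) != 5L || any(diff(effective_tes) <= 0) ||
      effective_tes[1] < 0) {
    abort("`effective_tes` must be 5 strictly increasing values, first >= 0.")
  }
  if (venc <= 0) abort("`venc` must be > 0.")
  if (pixel_area <= 0) abort("`pixel_area` must be > 0.")
  if (any(vessel_center - vessel_radii < 1) ||
      any(vessel_center + vessel_radii > matrix_size)) {
    abort("Vessel ellipse must lie fully inside the image matrix.")
  }
  structure(
    list(
      matrix_size = as.integer(matrix_size), pixel_area = pixel_area,
      vessel_center = vessel_center, vessel_radii = vessel_radii,
      venc = venc, effective_tes = as.numeric(effective_tes),
      noise_sigma = noise_sigma
    ),
    class = "acquisition_geometry"
  )
}

#' Per-site default geometries
#'
#' Vessel sizes approximate typical adult cross-sections: left renal vein
#' ~1.1 cm^2, suprarenal IVC ~2.9 cm^2, infrarenal IVC ~2.2 cm^2.
#'
#' @param site One of `"left_renal_vein"`, `"suprarenal_ivc"`,
#'   `"infrarenal_ivc"`.
#' @param ... Overrides passed to [acquisition_geometry()].
#' @return An `acquisition_geometry`.
#' @export
site_geometry <- function(site, ...) {
  radii <- switch(site,
    left_renal_vein = c(5, 5),
    suprarenal_ivc = c(8, 8),
    infrarenal_ivc = c(7, 7),
    abort(sprintf("Unknown site '%s'.", site))
  )
  acquisition_geometry(vessel_radii = radii, ...)
}

# Boolean mask of the vessel ellipse. Pixel centers at integer coordinates;
# a pixel belongs to the vessel if its center lies inside the ellipse
# (partial-volume edge pixels are in or out wholesale; no sub-pixel
# rendering).
vessel_mask <- function(geom) {
  r <- seq_len(geom$matrix_size[1])
  c_ <- seq_len(geom$matrix_size[2])
  dr <- outer((r - geom$vessel_center[1]) / geom$vessel_radii[1],
              rep(1, length(c_)))
  dc <- outer(rep(1, length(r)),
              (c_ - geom$vessel_center[2]) / geom$vessel_radii[2])
  dr^2 + dc^2 <= 1
}

# Normalized squared elliptical radius (dr^2 + dc^2), used for the
# parabolic velocity profile.
vessel_rho2 <- function(geom) {
  r <- seq_len(geom$matrix_size[1])
  c_ <- seq_len(geom$matrix_size[2])
  dr <- outer((r - geom$vessel_center[1]) / geom$vessel_radii[1],
              rep(1, length(c_)))
  dc <- outer(rep(1, length(r)),
              (c_ - geom$vessel_center[2]) / geom$vessel_radii[2])
  dr^2 + dc^2
}

# Rician-distributed magnitude: |signal + complex Gaussian noise|.
add_rician <- function(x, sigma) {
  if (sigma == 0) return(x)
  sqrt((x + rnorm(length(x), 0, sigma))^2 + rnorm(length(x), 0, sigma)^2)
}

#' Render a background-suppressed T2-prepared image series
#'
#' Forward model inverted by the relaxometry module: vessel pixels decay
#' mono-exponentially, `S(TE) = S0 exp(-TE / T2_blood)`, with the blood T2
#' given by the oxygenation calibration at the subject's hematocrit;
#' background pixels carry a small residual signal (imperfect suppression);
#' Rician noise of scale `geom$noise_sigma` is applied to every pixel of
#' every image.
#'
#' @param svo2 True venous oxygen saturation in the vessel, fraction.
#' @param hct Subject hematocrit, fraction.
#' @param geom An [acquisition_geometry()].
#' @param calib A `blood_t2_calibration`.
#' @param seed Integer seed (noise only).
#' @param s0 Fully-relaxed vessel signal, arbitrary units.
#' @param background_frac Residual background signal as a fraction of `s0`.
#' @param acquisition_id Identifier carried through to results.
#' @return A `t2prep_series`: list with `images` (rows x cols x 5 array),
#'   `effective_tes`, `roi_mask`, `pixel_area`, `acquisition_id`, and the
#'   generating `t2_blood` (ground truth, for closed-loop testing).
#' @export
render_t2prep_series <- function(svo2, hct, geom = acquisition_geometry(),
                                 calib = default_calibration(), seed = 1,
                                 s0 = 1000, background_frac = 0.02,
                                 acquisition_id = "acq") {
  t2_blood <- forward_t2(svo2, hct, calib)
  if (!is.finite(t2_blood) || t2_blood <= 0) {
    abort("Calibration produced a non-positive blood T2.")
  }
  mask <- vessel_mask(geom)
  tes <- geom$effective_tes
  imgs <- array(0, dim = c(geom$matrix_size, length(tes)))
  with_local_seed(seed, {
    for (i in seq_along(tes)) {
      frame <- matrix(background_frac * s0, geom$matrix_size[1],
                      geom$matrix_size[2])
      frame[mask] <- s0 * exp(-tes[i] / t2_blood)
      imgs[, , i] <- add_rician(frame, geom$noise_sigma)
    }
  })
  structure(
    list(
      images = imgs, effective_tes = tes, roi_mask = mask,
      pixel_area = geom$pixel_area, acquisition_id = acquisition_id,
      t2_blood = t2_blood
    ),
    class = "t2prep_series"
  )
}

#' Render a phase-contrast velocity-map series
#'
#' Five velocity maps sharing one ground truth with independent noise.
#' Vessel pixels follow a parabolic (Poiseuille) through-plane profile
#' `v = v_max (1 - rho^2)` over the elliptical cross-section, scaled so
#' that (discrete ROI mean velocity) x (ROI area) x 60 equals the requested
#' flow exactly; a uniform plug profile is available as an override.
#' Zero-mean Gaussian velocity noise is added everywhere (phase noise maps
#' to additive velocity noise inside the VENC limit).
#'
#' @param bfr True blood flow rate through the vessel, mL/min.
#' @param geom An [acquisition_geometry()].
#' @param seed Integer seed (noise only).
#' @param profile `"parabolic"` or `"uniform"`.
#' @param velocity_noise_sd Gaussian velocity noise SD, cm/s.
#' @param n_maps Number of interleaves (maps).
#' @param acquisition_id Identifier carried through to results.
#' @return A `velocity_series`: list with `velocity_maps`
#'   (rows x cols x n_maps array, cm/s, signed; toward-the-heart flow
#'   positive), `pixel_area`, `roi_mask`, `venc`, `acquisition_id`.
#' @export
render_velocity_series <- function(bfr, geom = acquisition_geometry(),
                                   seed = 1, profile = c("parabolic", "uniform"),
                                   velocity_noise_sd = 0, n_maps = 5,
                                   acquisition_id = "acq") {
  profile <- match.arg(profile)
  assert_scalar_number(bfr, "bfr", positive = TRUE)
  mask <- vessel_mask(geom)
  n_pix <- sum(mask)
  area <- n_pix * geom$pixel_area # cm^2
  mean_v <- bfr / (area * 60) # cm/s needed so mean * area * 60 = bfr
  if (profile == "uniform") {
    shape <- matrix(0, geom$matrix_size[1], geom$matrix_size[2])
    shape[mask] <- 1
  } else {
    rho2 <- vessel_rho2(geom)
    shape <- matrix(0, geom$matrix_size[1], geom$matrix_size[2])
    shape[mask] <- 1 - rho2[mask]
  }
  # scale the profile so the discrete ROI mean equals mean_v exactly
  shape_mean <- mean(shape[mask])
  field <- shape * (mean_v / shape_mean)
  v_max <- max(field)
  if (v_max > geom$venc) {
    abort(sprintf(
      "Peak velocity %.3g cm/s exceeds VENC %.3g cm/s (would alias).",
      v_max, geom$venc
    ))
  }
  maps <- array(0, dim = c(geom$matrix_size, n_maps))
  with_local_seed(seed, {
    for (i in seq_len(n_maps)) {
      maps[, , i] <- field + if (velocity_noise_sd > 0) {
        matrix(rnorm(length(field), 0, velocity_noise_sd),
               nrow = nrow(field))
      } else {
        0
      }
    }
  })
  structure(
    list(
      velocity_maps = maps, pixel_area = geom$pixel_area, roi_mask = mask,
      venc = geom$venc, acquisition_id = acquisition_id
    ),
    class = "velocity_series"
  )
}

#' @export
print.t2prep_series <- function(x, ...) {
  cat(sprintf(
    "<t2prep_series '%s'> %d x %d x %d, TEs {%s} ms, ROI %d px\n",
    x$acquisition_id, dim(x$images)[1], dim(x$images)[2], dim(x$images)[3],
    paste(x$effective_tes, collapse = ", "), sum(x$roi_mask)
  ))
  invisible(x)
}

#' @export
print.velocity_series <- function(x, ...) {
  cat(sprintf(
    "<velocity_series '%s'> %d x %d x %d maps, ROI %d px, VENC %g cm/s\n",
    x$acquisition_id, dim(x$velocity_maps)[1], dim(x$velocity_maps)[2],
    dim(x$velocity_maps)[3], sum(x$roi_mask), x$venc
  ))
  invisible(x)
}
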