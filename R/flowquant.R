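#' Blood flow rate from a phase-contrast velocity series
#'
#' For each velocity map, the flow is (mean signed velocity over the ROI,
#' cm/s) x (ROI area = mask pixels x pixel area, cm^2) x 60, giving mL/min;
#' the final flow is the mean over the maps. Velocities are averaged within
#' a map before flow computation; flows (not velocities) are averaged
#' across maps. Venous flow toward the heart is the positive direction; for
#' sites where the through-plane positive axis points away from the heart,
#' set `flip_sign = TRUE` so the reported flow is positive for normal flow.
#'
#' @param series A `velocity_series`.
#' @param site Site label carried into the result.
#' @param flip_sign Negate velocities before averaging (expected-direction
#'   flag for the site).
#' @return A one-row tibble: `site`, `bfr` (mL/min), `mean_velocity`
#'   (cm/s), `roi_area` (cm^2), `n_maps`, and `per_interleave_bfr` (list
#'   column of per-map flows). Real-data velocities exceeding the VENC
#'   limit trigger a warning (possible aliasing), never silent unwrapping.
#' @examples
#' geom <- acquisition_geometry()
#' ser <- render_velocity_series(410, geom, seed = 1)
#' compute_bfr(ser, "left_renal_vein")$bfr
#' @export
compute_bfr <- function(series, site = "unspecified", flip_sign = FALSE) {
  if (!inherits(series, "velocity_series")) {
    abort("`series` must be a velocity_series.")
  }
  mask <- series$roi_mask
  if (sum(mask) == 0) abort("ROI mask is empty.")
  d <- dim(series$velocity_maps)
  if (!identical(dim(mask), d[1:2])) {
    abort("ROI mask shape does not match the velocity maps.")
  }
  if (!is.null(series$venc) &&
      any(abs(series$velocity_maps[rep(mask, d[3])]) > series$venc)) {
    warn("Velocities exceed the VENC limit inside the ROI: possible aliasing.")
  }
  area <- sum(mask) * series$pixel_area
  sgn <- if (flip_sign) -1 else 1
  per_map <- vapply(seq_len(d[3]), function(i) {
    sgn * mean(series$velocity_maps[, , i][mask]) * area * 60
  }, numeric(1))
  tibble(
    site = site,
    bfr = mean(per_map),
    mean_velocity = mean(per_map) / (area * 60),
    roi_area = area,
    n_maps = d[3],
    per_interleave_bfr = list(per_map)
  )
}

#' Suprarenal minus infrarenal IVC flow difference
#'
#' The flow difference between the IVC above and below the renal-vein
#' confluence equals total renal venous outflow, the flow term of the
#' bilateral metabolic-rate computation. A negative difference on noisy
#' input is returned as-is with a warning flag, never clipped.
#'
#' @param supra,infra One-row [compute_bfr()] results (or any objects with
#'   a `bfr` field) for the suprarenal and infrarenal IVC of the same
#'   subject and condition.
#' @return A one-row tibble: `delta_bfr` (mL/min) and `flag`
#'   (`"ok"`/`"negative"`).
#' @export
delta_bfr <- function(supra, infra) {
  check_site <- function(x, expected) {
    has_site <- (is.list(x) || is.data.frame(x)) && "site" %in% names(x)
    if (has_site && !x$site[1] %in% c("unspecified", expected)) {
      abort(sprintf("Expected a %s result, got site '%s'.", expected,
                    x$site[1]))
    }
  }
  check_site(supra, "suprarenal_ivc")
  check_site(infra, "infrarenal_ivc")
  d <- supra$bfr[1] - infra$bfr[1]
  tibble(delta_bfr = d, flag = if (d < 0) "negative" else "ok")
}
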