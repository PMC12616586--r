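#' Physiological constants for Fick-principle oxygen metabolism
#'
#' @param crbc Oxygen-carrying capacity of red blood cells,
#'   micromol O2 per mL RBC (default 19.93).
#' @param tissue_density Kidney tissue density, g/mL (default 1.06).
#' @param hb_to_hct_divisor Divisor converting hemoglobin (g/dL) to
#'   hematocrit percent (default 0.34).
#' @return A named list of constants.
#' @export
physiological_constants <- function(crbc = 19.93, tissue_density = 1.06,
                                    hb_to_hct_divisor = 0.34) {
  for (nm in c("crbc", "tissue_density", "hb_to_hct_divisor")) {
    assert_scalar_number(get(nm), nm, positive = TRUE)
  }
  list(crbc = crbc, tissue_density = tissue_density,
       hb_to_hct_divisor = hb_to_hct_divisor)
}

#' Convert hemoglobin concentration to hematocrit
#'
#' `Hct(%) = Hb (g/dL) / 0.34`, returned as a fraction.
#'
#' @param hb Hemoglobin, g/dL. Vectorized.
#' @param constants From [physiological_constants()].
#' @return Hematocrit as a fraction.
#' @examples
#' hb_to_hct(14.28) # 0.42
#' @export
hb_to_hct <- function(hb, constants = physiological_constants()) {
  if (any(!is.finite(hb)) || any(hb <= 0)) abort("`hb` must be > 0.")
  hb / constants$hb_to_hct_divisor / 100
}

#' Kidney mass from segmented volume
#'
#' Multiplies a segmented kidney volume by tissue density (1.06 g/mL).
#'
#' @param volume Kidney volume, mL. Vectorized.
#' @param constants From [physiological_constants()].
#' @return Mass in g.
#' @export
kidney_mass_from_volume <- function(volume,
                                    constants = physiological_constants()) {
  if (any(!is.finite(volume)) || any(volume <= 0)) {
    abort("`volume` must be > 0.")
  }
  volume * constants$tissue_density
}

#' Unilateral whole-organ renal metabolic rate of oxygen
#'
#' Fick's Principle applied at the draining vein of one kidney:
#' \deqn{rMRO_2 = \frac{C_{RBC} \times Hct}{\mathrm{mass}} \times BFR
#'   \times (SaO_2 - SvO_2) \times 100}
#' in (micromol O2/min)/100 g. A negative result (possible on noisy input
#' when measured venous saturation exceeds arterial) is returned as-is and
#' flagged via attribute `"flag"`, never clipped.
#'
#' @param bfr Venous blood flow rate, mL/min.
#' @param sao2,svo2 Arterial and venous oxygen saturation, fractions.
#' @param hct Hematocrit, fraction.
#' @param kidney_mass Mass of the drained kidney, g.
#' @param constants From [physiological_constants()].
#' @return rMRO2 in (micromol O2/min)/100 g. Vectorized over all numeric
#'   arguments.
#' @examples
#' unilateral_rmro2(410, 0.99, 0.92, 0.42, 172) # ~139.7
#' @export
unilateral_rmro2 <- function(bfr, sao2, svo2, hct, kidney_mass,
                             constants = physiological_constants()) {
  if (any(!is.finite(kidney_mass)) || any(kidney_mass <= 0)) {
    abort("`kidney_mass` must be > 0.")
  }
  if (any(bfr <= 0)) abort("`bfr` must be > 0.")
  assert_fraction(sao2, "sao2")
  assert_fraction(svo2, "svo2")
  assert_fraction(hct, "hct")
  out <- constants$crbc * hct * bfr * (sao2 - svo2) / kidney_mass * 100
  if (any(out < 0)) {
    attr(out, "flag") <- "negative extraction (SvO2 > SaO2)"
  }
  out
}

#' Flow-weighted bilateral venous oxygen saturation
#'
#' The venous saturation of the combined renal outflow inferred from
#' measurements above and below the renal-vein confluence of the IVC:
#' \deqn{SvO_2^{bil} = \frac{Q_{Vs}\,SvO_2^{s} - Q_{Vi}\,SvO_2^{i}}
#'   {Q_{Vs} - Q_{Vi}}}
#' Values outside \[0, 1\] indicate a physically inconsistent measurement
#' set and are returned with attribute `"flag"`, not clipped.
#'
#' @param qvs,qvi Suprarenal and infrarenal IVC flow, mL/min (`qvs > qvi`).
#' @param svo2s,svo2i Corresponding venous saturations, fractions.
#' @return The mixed venous saturation as a fraction.
#' @export
bilateral_svo2 <- function(qvs, svo2s, qvi, svo2i) {
  if (any(abs(qvs - qvi) < .Machine$double.eps * pmax(qvs, 1))) {
    abort("`qvs` equals `qvi`: the flow difference is zero.")
  }
  if (any(qvi <= 0) || any(qvs <= 0)) abort("Flows must be > 0.")
  out <- (qvs * svo2s - qvi * svo2i) / (qvs - qvi)
  if (any(out < 0 | out > 1)) {
    attr(out, "flag") <- "outside [0, 1]: physically inconsistent measurements"
  }
  out
}

#' Bilateral whole-organ renal metabolic rate of oxygen
#'
#' Total metabolism of both kidneys normalized by total kidney mass,
#' computed from IVC measurements bracketing the renal-vein confluence:
#' \deqn{rMRO_2^{bil} = \frac{C_{RBC} \times Hct}{\mathrm{total\ mass}}
#'   \left[ Q_{Vs}(SaO_2 - SvO_2^{s}) - Q_{Vi}(SaO_2 - SvO_2^{i}) \right]
#'   \times 100}
#' Two algebraically identical forms are implemented: `form = "direct"`
#' evaluates the expression above; `form = "mixed"` evaluates
#' `(QVs - QVi) * (SaO2 - SvO2_bilateral)` with the flow-weighted mixed
#' saturation from [bilateral_svo2()]. They agree to machine precision and
#' the default is the direct form. A negative result (extraction
#' inconsistency between the two IVC sites) is flagged, not clipped.
#'
#' @param qvs,qvi Suprarenal / infrarenal IVC flow, mL/min.
#' @param svo2s,svo2i Venous saturations at those sites, fractions.
#' @param sao2 Arterial saturation, fraction.
#' @param hct Hematocrit, fraction.
#' @param total_mass Left + right kidney mass, g.
#' @param constants From [physiological_constants()].
#' @param form `"direct"` or `"mixed"`.
#' @return rMRO2 in (micromol O2/min)/100 g.
#' @export
bilateral_rmro2 <- function(qvs, svo2s, qvi, svo2i, sao2, hct, total_mass,
                            constants = physiological_constants(),
                            form = c("direct", "mixed")) {
  form <- match.arg(form)
  if (any(!is.finite(total_mass)) || any(total_mass <= 0)) {
    abort("`total_mass` must be > 0.")
  }
  if (any(qvs <= qvi)) {
    abort("`qvs` must exceed `qvi` (net renal outflow must be positive).")
  }
  assert_fraction(sao2, "sao2")
  assert_fraction(svo2s, "svo2s")
  assert_fraction(svo2i, "svo2i")
  assert_fraction(hct, "hct")
  scale <- constants$crbc * hct / total_mass * 100
  out <- if (form == "direct") {
    scale * (qvs * (sao2 - svo2s) - qvi * (sao2 - svo2i))
  } else {
    mixed <- bilateral_svo2(qvs, svo2s, qvi, svo2i)
    scale * (qvs - qvi) * (sao2 - as.numeric(mixed))
  }
  if (any(out < 0)) {
    attr(out, "flag") <- "negative: IVC extraction inconsistency"
  }
  out
}

#' Round a value for reporting
#'
#' Reporting conventions for cohort tables: flow and metabolic-rate values
#' to the nearest ten (half away from zero); saturations and arteriovenous
#' differences to the nearest whole percent; T2 to the nearest ms. All
#' internal computation is full precision; rounding is applied only at the
#' reporting layer.
#'
#' @param value Numeric vector. Saturations are expected in percent.
#' @param parameter_kind One of `"bfr"`, `"rmro2"`, `"delta_bfr"`,
#'   `"svo2"`, `"sao2"`, `"avdo2"`, `"t2"`.
#' @return Rounded values.
#' @examples
#' round_for_report(139.7, "rmro2") # 140
#' round_for_report(92.4, "svo2") # 92
#' @export
round_for_report <- function(value, parameter_kind) {
  if (any(!is.finite(value))) abort("`value` must be finite.")
  unit <- switch(parameter_kind,
    bfr = , rmro2 = , delta_bfr = 10,
    svo2 = , sao2 = , avdo2 = , t2 = 1,
    abort(sprintf("Unknown parameter kind '%s'.", parameter_kind))
  )
  round_half_away(value, unit)
}
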