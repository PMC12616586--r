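#' Desk-check the metabolic arithmetic against reference cohort values
#'
#' Evaluates the package's core formulas at the cohort-mean operating
#' points of the default physiology specification and compares each result
#' with the corresponding frozen reference value on the reporting scale
#' (tens-rounded metabolic rates and flows, whole-percent saturations).
#' These are pure plug-in-of-means checks of the arithmetic -- the cohort
#' analysis itself always computes per-subject values first and averages
#' afterwards.
#'
#' @param verbose Print the table.
#' @return A tibble with columns `check`, `computed`, `reference`, `pass`.
#' @examples
#' worked_examples(verbose = FALSE)
#' @export
worked_examples <- function(verbose = TRUE) {
  phys <- default_physiology()
  sao2 <- phys$sao2_mean
  svo2 <- phys$svo2_mean
  bfr <- phys$bfr_mean
  hct <- 0.42
  left_mass <- 172

  checks <- list(
    list(
      check = "unilateral rMRO2, baseline means (tens-rounded)",
      computed = round_for_report(
        as.numeric(unilateral_rmro2(
          bfr["left_renal_vein", "baseline"], sao2[["baseline"]],
          svo2["left_renal_vein", "baseline"], hct, left_mass
        )), "rmro2"
      ),
      reference = 140
    ),
    list(
      check = "unilateral rMRO2, moderate-hypoxia means (tens-rounded)",
      computed = round_for_report(
        as.numeric(unilateral_rmro2(
          bfr["left_renal_vein", "moderate_hypoxia"],
          sao2[["moderate_hypoxia"]],
          svo2["left_renal_vein", "moderate_hypoxia"], hct, left_mass
        )), "rmro2"
      ),
      reference = 170
    ),
    list(
      check = "baseline IVC flow difference (mL/min)",
      computed = bfr["suprarenal_ivc", "baseline"] -
        bfr["infrarenal_ivc", "baseline"],
      reference = 1030
    ),
    list(
      check = "baseline AVDO2, left kidney (%)",
      computed = round_for_report(
        100 * (sao2[["baseline"]] - svo2["left_renal_vein", "baseline"]),
        "avdo2"
      ),
      reference = 7
    ),
    list(
      check = "baseline AVDO2, suprarenal IVC (%)",
      computed = round_for_report(
        100 * (sao2[["baseline"]] - svo2["suprarenal_ivc", "baseline"]),
        "avdo2"
      ),
      reference = 16
    ),
    list(
      check = "baseline AVDO2, infrarenal IVC (%)",
      computed = round_for_report(
        100 * (sao2[["baseline"]] - svo2["infrarenal_ivc", "baseline"]),
        "avdo2"
      ),
      reference = 28
    ),
    list(
      check = "flow-weighted mixed venous SvO2 at baseline IVC means",
      computed = round(as.numeric(bilateral_svo2(
        bfr["suprarenal_ivc", "baseline"],
        svo2["suprarenal_ivc", "baseline"],
        bfr["infrarenal_ivc", "baseline"],
        svo2["infrarenal_ivc", "baseline"]
      )), 2),
      reference = 0.99
    )
  )
  out <- dplyr::bind_rows(lapply(checks, function(x) {
    tibble(check = x$check, computed = as.numeric(x$computed),
           reference = x$reference,
           pass = isTRUE(all.equal(as.numeric(x$computed), x$reference,
                                   tolerance = 1e-9)))
  }))
  if (verbose) print(out, width = Inf)
  invisible(out)
}
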