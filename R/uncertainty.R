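#' Measurement-uncertainty propagation for unilateral rMRO2
#'
#' Propagates independent measurement uncertainty in venous/arterial
#' saturation, flow, hematocrit and kidney mass into the Fick-principle
#' metabolic rate, either to first order (analytic partial derivatives of
#' the unilateral equation) or by Monte-Carlo simulation over independent
#' Gaussian draws. Because rMRO2 depends on saturation only through the
#' arteriovenous difference, its relative error from an SvO2 error of SD s
#' is `s / (SaO2 - SvO2)` -- the small normoxic arteriovenous difference of
#' the kidney makes the equation far more sensitive to SvO2 than to a
#' comparable relative error in flow.
#'
#' @param bfr,sao2,svo2,hct,kidney_mass Operating point (same meaning and
#'   units as [unilateral_rmro2()]).
#' @param input_sds Named list/vector of SDs on the measurement scale of
#'   each input; any of `bfr`, `sao2`, `svo2`, `hct`, `kidney_mass` (absent
#'   entries are treated as 0).
#' @param method `"linear"` (first-order) or `"monte_carlo"`.
#' @param n_draws Monte-Carlo draws (>= 1000).
#' @param seed Seed for the Monte-Carlo method.
#' @param constants From [physiological_constants()].
#' @return A list of class `rmro2_uncertainty`: `rmro2` (point value),
#'   `rmro2_sd`, `method`, `sensitivity` (tibble of partial derivatives and
#'   per-input SD contributions), `input_sds`.
#' @examples
#' propagate_uncertainty(410, 0.99, 0.92, 0.42, 172,
#'                       input_sds = list(svo2 = 0.02))
#' @export
propagate_uncertainty <- function(bfr, sao2, svo2, hct, kidney_mass,
                                  input_sds = list(),
                                  method = c("linear", "monte_carlo"),
                                  n_draws = 10000, seed = 1,
                                  constants = physiological_constants()) {
  method <- match.arg(method)
  params <- c("bfr", "sao2", "svo2", "hct", "kidney_mass")
  sds <- setNames(rep(0, length(params)), params)
  sds[names(input_sds)] <- unlist(input_sds)
  if (any(sds < 0)) abort("Input SDs must be >= 0.")
  extra <- setdiff(names(input_sds), params)
  if (length(extra) > 0) {
    abort(sprintf("Unknown input(s): %s.", paste(extra, collapse = ", ")))
  }
  point <- unilateral_rmro2(bfr, sao2, svo2, hct, kidney_mass, constants)
  point <- as.numeric(point)

  # analytic partials of rMRO2 = k * hct * bfr * (sao2 - svo2) / mass,
  # k = 100 * CRBC
  k <- 100 * constants$crbc
  grad <- c(
    bfr = k * hct * (sao2 - svo2) / kidney_mass,
    sao2 = k * hct * bfr / kidney_mass,
    svo2 = -k * hct * bfr / kidney_mass,
    hct = k * bfr * (sao2 - svo2) / kidney_mass,
    kidney_mass = -k * hct * bfr * (sao2 - svo2) / kidney_mass^2
  )

  if (method == "linear") {
    sd_out <- sqrt(sum((grad * sds)^2))
  } else {
    if (n_draws < 1000) abort("`n_draws` must be >= 1000 for Monte Carlo.")
    sd_out <- with_local_seed(seed, {
      draws <- vapply(params, function(p) {
        base <- c(bfr = bfr, sao2 = sao2, svo2 = svo2, hct = hct,
                  kidney_mass = kidney_mass)[[p]]
        rnorm(n_draws, base, sds[[p]])
      }, numeric(n_draws))
      vals <- constants$crbc * draws[, "hct"] * draws[, "bfr"] *
        (draws[, "sao2"] - draws[, "svo2"]) / draws[, "kidney_mass"] * 100
      sd(vals)
    })
  }

  structure(
    list(
      rmro2 = point,
      rmro2_sd = sd_out,
      method = method,
      sensitivity = tibble(
        parameter = params,
        partial = as.numeric(grad[params]),
        input_sd = as.numeric(sds[params]),
        sd_contribution = abs(as.numeric(grad[params])) *
          as.numeric(sds[params])
      ),
      input_sds = as.list(sds)
    ),
    class = "rmro2_uncertainty"
  )
}

#' @export
print.rmro2_uncertainty <- function(x, ...) {
  cat(sprintf(
    "<rmro2_uncertainty> rMRO2 = %.4g +/- %.3g (umol O2/min)/100 g [%s]\n",
    x$rmro2, x$rmro2_sd, x$method
  ))
  print(x$sensitivity)
  invisible(x)
}

#' @method tidy rmro2_uncertainty
#' @export
tidy.rmro2_uncertainty <- function(x, ...) x$sensitivity

#' @method glance rmro2_uncertainty
#' @export
glance.rmro2_uncertainty <- function(x, ...) {
  tibble(rmro2 = x$rmro2, rmro2_sd = x$rmro2_sd,
         rel_sd = x$rmro2_sd / abs(x$rmro2), method = x$method)
}
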