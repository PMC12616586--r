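#' ROI-mean signal decay from a T2-prepared series
#'
#' Averages signal intensity over the ROI mask for each of the five
#' T2-prepared images, yielding the decay curve that [fit_t2()] consumes.
#'
#' @param series A `t2prep_series` (from [render_t2prep_series()] or
#'   [read_t2prep_nifti()]).
#' @return A tibble with columns `te` (ms) and `signal`, in TE order.
#' @export
roi_mean_signal <- function(series) {
  if (!inherits(series, "t2prep_series")) {
    abort("`series` must be a t2prep_series.")
  }
  mask <- series$roi_mask
  if (sum(mask) == 0) abort("ROI mask is empty.")
  d <- dim(series$images)
  if (!identical(dim(mask), d[1:2])) {
    abort("ROI mask shape does not match the images.")
  }
  if (d[3] != length(series$effective_tes)) {
    abort("Number of images does not match the number of effective TEs.")
  }
  sig <- vapply(seq_len(d[3]),
                function(i) mean(series$images[, , i][mask]),
                numeric(1))
  tibble(te = series$effective_tes, signal = sig)
}

#' Fit a mono-exponential T2 decay
#'
#' Fits `S(TE) = S0 exp(-TE / T2)` to ROI-mean signals. The default method
#' is nonlinear least squares (Levenberg-Marquardt) initialized from the
#' closed-form log-linear solution; `method = "log_linear"` returns the
#' log-domain ordinary least-squares fit itself (which requires strictly
#' positive signals). An optional constant `offset` can be subtracted
#' before fitting to compensate a known noise floor (default 0).
#'
#' A non-decaying series (non-positive fitted rate) is an explicit error:
#' a negative or unbounded T2 is reported as a failure rather than clamped.
#'
#' @param points Tibble/data frame with columns `te` (ms) and `signal`, or
#'   a `t2prep_series` (ROI means are taken first).
#' @param method `"nls"` (default) or `"log_linear"`.
#' @param s0_fixed Optional: fix S0 to this value and fit only T2.
#' @param offset Constant subtracted from all signals before fitting.
#' @return A `t2_fit` object; see [tidy.t2_fit()] and [glance.t2_fit()].
#'   Fields: `t2` (ms), `s0`, `residual_rms`, `r_squared`, `n_points`,
#'   `method`.
#' @examples
#' pts <- tibble::tibble(te = c(0, 40, 80, 160, 240),
#'                       signal = 1000 * exp(-c(0, 40, 80, 160, 240) / 159))
#' fit_t2(pts)$t2
#' @export
fit_t2 <- function(points, method = c("nls", "log_linear"),
                   s0_fixed = NULL, offset = 0) {
  method <- match.arg(method)
  if (inherits(points, "t2prep_series")) points <- roi_mean_signal(points)
  te <- points$te
  signal <- points$signal - offset
  if (length(te) < 3L) abort("At least 3 (TE, signal) points are required.")
  if (anyNA(te) || anyNA(signal)) abort("Missing values in decay points.")

  loglin <- function() {
    if (any(signal <= 0)) {
      abort(paste0(
        "Non-positive signal: the log-linear method requires all signals ",
        "> 0; use method = \"nls\"."
      ))
    }
    if (is.null(s0_fixed)) {
      fit <- lm(log(signal) ~ te)
      rate <- -coef(fit)[[2]]
      s0 <- exp(coef(fit)[[1]])
    } else {
      # log S - log S0 = -TE/T2, least squares through the origin
      rate <- -sum(te * (log(signal) - log(s0_fixed))) / sum(te^2)
      s0 <- s0_fixed
    }
    list(t2 = 1 / rate, s0 = s0, rate = rate)
  }

  if (method == "log_linear") {
    est <- loglin()
    if (!is.finite(est$t2) || est$rate <= 0) {
      abort("Series does not decay: fitted T2 would be negative or unbounded.")
    }
  } else {
    if (coef(lm(signal ~ te))[[2]] >= 0) {
      abort("Series does not decay: fitted T2 would be negative or unbounded.")
    }
    ss_of <- function(s0, t2) sum((signal - s0 * exp(-te / t2))^2)
    # Profile S0 in closed form over a coarse log-spaced T2 grid: a
    # well-placed start keeps Levenberg-Marquardt out of the flat
    # small-T2 region where the gradient vanishes.
    te_span <- max(diff(range(te)), 1)
    t2_grid <- exp(seq(log(te_span / 50), log(te_span * 20),
                       length.out = 80))
    prof <- vapply(t2_grid, function(t2) {
      w <- exp(-te / t2)
      s0 <- if (is.null(s0_fixed)) sum(w * signal) / sum(w^2) else s0_fixed
      c(s0, ss_of(s0, t2))
    }, numeric(2))
    i_best <- which.min(prof[2, ])
    start <- list(t2 = t2_grid[i_best], s0 = max(prof[1, i_best], 1e-9))
    ll <- tryCatch(loglin(), error = function(e) NULL)
    if (!is.null(ll) && is.finite(ll$t2) && ll$rate > 0 &&
        ss_of(ll$s0, ll$t2) < prof[2, i_best]) {
      start <- ll
    }
    if (is.null(s0_fixed)) {
      fit <- minpack.lm::nlsLM(
        signal ~ s0 * exp(-te / t2),
        start = list(s0 = start$s0, t2 = start$t2),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      est <- list(t2 = coef(fit)[["t2"]], s0 = coef(fit)[["s0"]])
    } else {
      fit <- minpack.lm::nlsLM(
        signal ~ s0_fixed * exp(-te / t2),
        start = list(t2 = start$t2),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      )
      est <- list(t2 = coef(fit)[["t2"]], s0 = s0_fixed)
    }
    # keep the refined solution only if it actually improves the start
    if (!is.finite(est$t2) || est$t2 <= 0 ||
        ss_of(est$s0, est$t2) > ss_of(start$s0, start$t2)) {
      est <- start
    }
    if (!is.finite(est$t2) || est$t2 <= 0) {
      abort("Series does not decay: fitted T2 would be negative or unbounded.")
    }
  }

  pred <- est$s0 * exp(-te / est$t2)
  res <- signal - pred
  ss_tot <- sum((signal - mean(signal))^2)
  r2 <- if (ss_tot > 0) max(0, min(1, 1 - sum(res^2) / ss_tot)) else NA_real_
  structure(
    list(
      t2 = est$t2, s0 = est$s0,
      residual_rms = sqrt(mean(res^2)), r_squared = r2,
      n_points = length(te), method = method,
      data = tibble(te = te, signal = signal, fitted = pred)
    ),
    class = "t2_fit"
  )
}

#' @export
print.t2_fit <- function(x, ...) {
  cat(sprintf(
    "<t2_fit> T2 = %.4g ms, S0 = %.4g (%s, %d points, RMS resid %.3g, R^2 %.4f)\n",
    x$t2, x$s0, x$method, x$n_points, x$residual_rms,
    if (is.na(x$r_squared)) NA else x$r_squared
  ))
  invisible(x)
}

#' Tidy a T2 fit
#'
#' @param x A `t2_fit`.
#' @param ... Unused.
#' @return One row per parameter with `term` and `estimate`.
#' @method tidy t2_fit
#' @export
tidy.t2_fit <- function(x, ...) {
  tibble(term = c("t2", "s0"), estimate = c(x$t2, x$s0))
}

#' One-row fit summary
#'
#' @param x A `t2_fit`.
#' @param ... Unused.
#' @return A one-row tibble with `t2`, `s0`, `residual_rms`, `r_squared`,
#'   `n_points`, `method`.
#' @method glance t2_fit
#' @export
glance.t2_fit <- function(x, ...) {
  tibble(
    t2 = x$t2, s0 = x$s0, residual_rms = x$residual_rms,
    r_squared = x$r_squared, n_points = x$n_points, method = x$method
  )
}

#' Plot a T2 decay fit
#'
#' @param object A `t2_fit`.
#' @param ... Unused.
#' @return A ggplot showing the ROI-mean signals and the fitted curve.
#' @method autoplot t2_fit
#' @export
autoplot.t2_fit <- function(object, ...) {
  curve <- tibble(
    te = seq(min(object$data$te), max(object$data$te), length.out = 200)
  )
  curve$signal <- object$s0 * exp(-curve$te / object$t2)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$te, y = .data$signal)) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Effective TE (ms)", y = "ROI-mean signal (a.u.)",
      title = sprintf("Mono-exponential T2 fit: T2 = %.0f ms", object$t2)
    ) +
    ggplot2::theme_minimal()
}
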