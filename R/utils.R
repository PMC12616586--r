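# Internal helpers shared across modules.

# Scalar numeric check with a readable error.
assert_scalar_number <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (finite && !is.finite(x)) {
    abort(sprintf("`%s` must be finite.", name))
  }
  if (positive && x <= 0) {
    abort(sprintf("`%s` must be > 0 (got %g).", name, x))
  }
  invisible(x)
}

assert_fraction <- function(x, name, lo = 0, hi = 1, open_lo = TRUE) {
  if (any(!is.finite(x)) || any(x > hi) || any(if (open_lo) x <= lo else x < lo)) {
    abort(sprintf(
      "`%s` must lie in %s%g, %g] (got %s).",
      name, if (open_lo) "(" else "[", lo, hi,
      paste(signif(x, 4), collapse = ", ")
    ))
  }
  invisible(x)
}

# Round half away from zero to the nearest `unit`, matching the reporting
# convention for flow and metabolic-rate values (base round() is half-to-even).
round_half_away <- function(x, unit = 1) {
  sign(x) * floor(abs(x) / unit + 0.5) * unit
}

# Draw from a normal truncated to [lo, hi] by rejection. Degenerate sd = 0
# returns the mean (which must then lie inside the bounds).
rnorm_trunc <- function(n, mean, sd, lo = -Inf, hi = Inf, max_tries = 10000L) {
  mean <- unname(mean)
  sd <- unname(sd)
  lo <- unname(lo)
  hi <- unname(hi)
  if (sd < 0) abort("Standard deviation must be >= 0.")
  if (mean < lo || mean > hi) {
    abort(sprintf(
      "Truncation bounds [%g, %g] exclude the mean %g.", lo, hi, mean
    ))
  }
  if (sd == 0) return(rep(mean, n))
  out <- rnorm(n, mean, sd)
  bad <- which(out < lo | out > hi)
  tries <- 0L
  while (length(bad) > 0L) {
    tries <- tries + 1L
    if (tries > max_tries) {
      abort("Truncated-normal rejection sampling failed to converge.")
    }
    out[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[out[bad] < lo | out[bad] > hi]
  }
  out
}

# Run code under a locally-seeded RNG without disturbing the caller's stream.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Deterministic per-stage seed derivation from one root seed, kept inside
# 32-bit integer range.
derive_seed <- function(seed, stage_offset) {
  as.integer((as.numeric(seed) * 1003L + stage_offset) %% 2147483629)
}
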