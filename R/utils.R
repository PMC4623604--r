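# Internal helpers shared across modules.

# 15N/1H gyromagnetic-ratio quotient: converts a spectrometer's nominal 1H
# frequency (MHz) to the 15N Larmor frequency for ppm -> Hz conversion.
GAMMA_N_OVER_H <- 0.10136767

#' @noRd
assert_number <- function(x, name, lower = -Inf, strict = FALSE, allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    abort(sprintf("`%s` must be a single number.", name))
  }
  if (!is.na(x)) {
    ok <- if (strict) x > lower else x >= lower
    if (!ok) {
      abort(sprintf(
        "`%s` must be %s %s (got %s).", name,
        if (strict) "greater than" else "at least", format(lower), format(x)
      ))
    }
  }
  invisible(x)
}

#' @noRd
assert_flag <- function(x, name) {
  if (!is.logical(x) || length(x) != 1L || is.na(x)) {
    abort(sprintf("`%s` must be TRUE or FALSE.", name))
  }
  invisible(x)
}

# Sample standard deviation with defined degenerate-sample behaviour:
# a singleton has no dispersion information, report 0 with a warning.
#' @noRd
sample_sd <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) <= 1L) {
    warn("standard deviation of a single observation reported as 0")
    return(0)
  }
  stats::sd(x)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG state. All simulate_*() generators funnel through this.
#' @noRd
with_sim_seed <- function(seed, expr) {
  if (is.null(seed)) abort("a `seed` is required for reproducible simulation")
  assert_number(seed, "seed")
  withr::with_seed(as.integer(seed), expr)
}

#' @noRd
`%ifna%` <- function(x, y) ifelse(is.na(x), y, x)
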