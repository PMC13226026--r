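#' Clamp values into a closed interval, warning when anything is clipped
#'
#' Structural invariants of simulated records (fractions in \[0, 1\],
#' EDV <= PSV, non-negative weights) are enforced by clipping with a logged
#' warning rather than silent resampling, so that invariant violations remain
#' auditable.
#'
#' @param x numeric vector.
#' @param lo,hi interval bounds.
#' @param what label used in the warning message.
#' @param warn emit a warning when values are clipped?
#' @return `x` with out-of-range values clipped to the interval.
#' @keywords internal
clamp <- function(x, lo = -Inf, hi = Inf, what = "value", warn = TRUE) {
  n_out <- sum(x < lo | x > hi, na.rm = TRUE)
  if (n_out > 0L && warn) {
    warning(sprintf("%d %s value(s) clipped to [%g, %g]", n_out, what, lo, hi),
            call. = FALSE)
  }
  pmin(pmax(x, lo), hi)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Set the RNG seed only when one is supplied
#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' @noRd
assert_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lo || x > hi) {
    stop(sprintf("configuration error: `%s` must be a single finite number in [%g, %g]",
                 name, lo, hi), call. = FALSE)
  }
  invisible(x)
}
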