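#' Logistic time-course specification for ligand internalization
#'
#' Describes the fraction of ligand internalized as a function of time at
#' 37 degrees C with the four-parameter power logistic
#' \deqn{f(t) = a_2 + \frac{a_1 - a_2}{1 + (t/x_0)^p},}
#' with \eqn{f(0) = a_1} by convention. `a1` is the baseline internalized
#' fraction at the end of labeling washes (time zero), `a2` the plateau at
#' long incubation, `x0` the center time in minutes and `p` the power
#' exponent controlling steepness. The same parameterization is used both to
#' drive the synthetic-data generator and as one of the models offered by
#' [fit_logistic()].
#'
#' @param a1 Baseline internalized fraction at t = 0 (dimensionless).
#' @param a2 Plateau internalized fraction (dimensionless).
#' @param x0 Center time, minutes; must be positive.
#' @param p Power exponent, dimensionless; must be positive.
#'
#' @return An object of class `kinetics_spec` (a named list).
#' @examples
#' sp <- kinetics_spec(a1 = 0.1, a2 = 0.9, x0 = 20, p = 2)
#' interior_fraction_timecourse(sp, c(0, 10, 20, 60))
#' @export
kinetics_spec <- function(a1, a2, x0, p) {
  stopifnot(is.numeric(a1), is.numeric(a2), is.numeric(x0), is.numeric(p))
  if (!(a1 >= 0 && a1 < a2 && a2 <= 1)) {
    abort("invalid kinetics spec: need 0 <= a1 < a2 <= 1")
  }
  if (x0 <= 0) abort("invalid kinetics spec: x0 must be > 0")
  if (p <= 0) abort("invalid kinetics spec: p must be > 0")
  structure(list(a1 = a1, a2 = a2, x0 = x0, p = p), class = "kinetics_spec")
}

#' @export
print.kinetics_spec <- function(x, ...) {
  cat(sprintf(
    "<kinetics_spec> a1 = %.3g, a2 = %.3g, x0 = %.3g min, p = %.3g\n",
    x$a1, x$a2, x$x0, x$p
  ))
  invisible(x)
}

#' Evaluate an internalization time course
#'
#' Evaluates the power-logistic interior fraction \eqn{f(t)} of a
#' [kinetics_spec()] at the requested times. \eqn{f(0)} is defined as `a1`
#' (the analytic limit for all `p > 0`).
#'
#' @param spec A [kinetics_spec()].
#' @param times Numeric vector of times in minutes, all `>= 0`.
#' @return Numeric vector of fractions in `[0, 1]`, non-decreasing in `t`.
#' @export
interior_fraction_timecourse <- function(spec, times) {
  stopifnot(inherits(spec, "kinetics_spec"), is.numeric(times))
  if (any(times < 0)) abort("times must be >= 0")
  f <- spec$a2 + (spec$a1 - spec$a2) / (1 + (times / spec$x0)^spec$p)
  f[times == 0] <- spec$a1
  f
}
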