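# Closed-form evaluation of the logistic / Richards / Gompertz family.
#
# All evaluators work in log space internally: the term nu * exp(-k(x - x_i))
# is handled as log1pexp(log(nu) - k(x - x_i)) so that points far to the left
# of the inflection do not overflow. For nu below NU_GOMPERTZ_SWITCH the
# Gompertz limit form is used, since (1 + nu t)^(-1/nu) loses all precision as
# nu -> 0.

#' Evaluate the logistic curve
#'
#' \eqn{L(x) = c_0 + A / (1 + b e^{-kx})}, strictly increasing in `x` with
#' limits `c0` at \eqn{-\infty} and `c0 + A` at \eqn{+\infty}; the curve is
#' symmetric about its inflection point `x_c`, where it equals `c0 + A/2`.
#'
#' @param x Numeric vector of log-concentrations.
#' @param p A [logistic_params()] object.
#' @return Numeric vector of signal values.
#' @export
logistic_value <- function(x, p) {
  stopifnot(inherits(p, "logistic_params"))
  p$c0 + p$A * exp(-log1pexp(-p$k * (x - p$x_c)))
}

#' Evaluate the Richards curve
#'
#' The \eqn{\nu}-form generalized logistic
#' \deqn{R(x) = c_0 + A (1 + \nu e^{-k(x - x_i)})^{-1/\nu},}
#' strictly increasing with limits `c0` and `c0 + A` and inflection at `x_i`.
#' For \eqn{\nu} below `1e-6` the Gompertz limit
#' \eqn{A \exp(-e^{-k(x - x_i)})} is evaluated instead for numerical
#' stability. `richards_value_d()` is the d-form entry point of the same
#' curve, with `d = nu + 1`.
#'
#' @param x Numeric vector of log-concentrations.
#' @param p A [richards_params()] object.
#' @return Numeric vector of signal values.
#' @export
richards_value <- function(x, p) {
  stopifnot(inherits(p, "richards_params"))
  if (p$nu < NU_GOMPERTZ_SWITCH)
    return(p$c0 + gompertz_value(x, A = p$A, k = p$k, x_i = p$x_i))
  p$c0 + p$A * exp(-log1pexp(log(p$nu) - p$k * (x - p$x_i)) / p$nu)
}

#' @rdname richards_value
#' @param A,k,x_i Scalar curve parameters as in [richards_params()].
#' @param d Asymmetry parameter of the d-form (> 1).
#' @export
richards_value_d <- function(x, A, d, k, x_i) {
  if (!is.numeric(d) || length(d) != 1L || !is.finite(d) || d <= 1)
    stop_domain("'d' must exceed 1 (the 0 < d < 1 branch is not modelled)")
  richards_value(x, richards_params(A = A, d = d, k = k, x_i = x_i))
}

#' Evaluate the log Richards curve
#'
#' \eqn{\ln R(x) = \ln A - (1/\nu)\ln(1 + \nu e^{-k(x - x_i)})}: a concave
#' function with upper asymptote \eqn{\ln A} and a leftmost asymptote of slope
#' \eqn{k/\nu}. Any baseline `c0` must be zero, since the log form is defined
#' for the pure Richards curve.
#'
#' @inheritParams richards_value
#' @return Numeric vector of log-signal values.
#' @export
log_richards_value <- function(x, p) {
  stopifnot(inherits(p, "richards_params"))
  if (p$c0 != 0)
    stop_domain("log_richards_value is defined for c0 = 0; evaluate log(richards_value(...)) instead")
  if (p$nu < NU_GOMPERTZ_SWITCH)
    return(log(p$A) - exp(-p$k * (x - p$x_i)))
  log(p$A) - log1pexp(log(p$nu) - p$k * (x - p$x_i)) / p$nu
}

#' Evaluate the inflection-normalized Richards curve
#'
#' The Richards factor rescaled by the constant multiplier
#' \eqn{(1+\nu)^{1/\nu}/A} so that it equals 1 at the inflection point:
#' \deqn{R_\nu(x) = \left(\frac{1+\nu}{1+\nu e^{-k(x - x_i)}}\right)^{1/\nu}.}
#' Its upper limit is \eqn{(1+\nu)^{1/\nu}}.
#'
#' @inheritParams richards_value
#' @return Numeric vector of dimensionless ratios.
#' @export
normalized_richards_value <- function(x, p) {
  stopifnot(inherits(p, "richards_params"))
  if (p$nu < NU_GOMPERTZ_SWITCH)
    return(exp(1 - exp(-p$k * (x - p$x_i))))
  exp((log1p(p$nu) - log1pexp(log(p$nu) - p$k * (x - p$x_i))) / p$nu)
}

#' Inflection rate value of the d-form Richards curve
#'
#' The ratio of the curve's value at its inflection point to its upper limit,
#' \eqn{d^{1/(1-d)}}. It depends on the asymmetry parameter alone, is strictly
#' increasing on \eqn{d > 1}, and ranges over \eqn{(1/e, 1)}: the lower limit
#' is attained as \eqn{d \to 1} (the Gompertz limit) and the upper as
#' \eqn{d \to \infty}. `d = 2` gives 1/2, the symmetric logistic case.
#'
#' @param d Numeric vector of asymmetry parameters, all > 1.
#' @return Numeric vector of ratios in (1/e, 1).
#' @export
inflection_ratio <- function(d) {
  if (!is.numeric(d) || any(!is.finite(d)) || any(d <= 1))
    stop_domain("'d' must be finite and exceed 1")
  exp(log(d) / (1 - d))
}

#' Evaluate the Gompertz curve
#'
#' \eqn{G(x) = A \exp(-e^{-k(x - x_i)})}, the \eqn{d \to 1} (equivalently
#' \eqn{\nu \to 0}) limit of the Richards family; its value at the inflection
#' point is \eqn{A/e}.
#'
#' @param x Numeric vector of log-concentrations.
#' @param A Upper limit (> 0).
#' @param k Rate (> 0).
#' @param x_i Inflection abscissa.
#' @return Numeric vector of signal values.
#' @export
gompertz_value <- function(x, A, k, x_i) {
  check_positive(A, "A")
  check_positive(k, "k")
  check_real(x_i, "x_i")
  A * exp(-exp(-k * (x - x_i)))
}

#' Absolute and relative growth rates of a Richards curve
#'
#' The Richards curve solves \eqn{dR/dx = (k/\nu) R (1 - (R/A)^\nu)}, so its
#' relative growth rate (the derivative of its logarithm) is
#' \eqn{(k/\nu)(1 - (R/A)^\nu)} — a strictly decreasing function of `x` that
#' approaches \eqn{k/\nu} at the far left and 0 at the far right — and its
#' absolute rate is the product of the curve value and the relative rate,
#' maximal at the inflection point. In the titration reading the relative rate
#' plays the role of an activity coefficient: the fraction of the titrated
#' chemical energy still available to drive binding.
#'
#' @inheritParams richards_value
#' @return A list with numeric vectors `absolute` (signal per unit `x`) and
#'   `relative` (per unit `x`).
#' @export
growth_rates <- function(x, p) {
  stopifnot(inherits(p, "richards_params"))
  if (p$c0 != 0)
    stop_domain("growth rates are defined for the pure Richards curve (c0 = 0)")
  # (R/A)^nu = 1 / (1 + nu e^{-k(x - x_i)}) exactly, so
  # relative = k / (e^{k(x - x_i)} + nu), stable on both tails.
  relative <- p$k / (exp(p$k * (x - p$x_i)) + p$nu)
  list(absolute = richards_value(x, p) * relative, relative = relative)
}

#' Residual of the Richards differential equation
#'
#' Central-finite-difference check that the closed-form Richards curve solves
#' its defining ordinary differential equation: returns
#' \eqn{[R(x+h) - R(x-h)]/(2h) - (k/\nu) R(x) (1 - (R(x)/A)^\nu)}. The
#' magnitude is bounded by the \eqn{O(h^2)} discretization error of the
#' central difference.
#'
#' @inheritParams richards_value
#' @param step Finite-difference step `h`.
#' @return Numeric vector of residuals (signal per unit `x`).
#' @export
ode_residual <- function(x, p, step = 1e-4) {
  stopifnot(inherits(p, "richards_params"))
  check_positive(step, "step")
  fd <- (richards_value(x + step, p) - richards_value(x - step, p)) / (2 * step)
  fd - growth_rates(x, p)$absolute
}
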