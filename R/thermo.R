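# Thermodynamic interpretation of fitted asymmetry parameters.
#
# In a dual titration the antigen-axis asymmetry nu_Ag measures the ratio of
# apparent to true equilibrium dissociation constant, so ln(nu_Ag) is the
# enthalpic part of the excess Gibbs free energy in RT units; the serum-axis
# asymmetry nu_Ab equals [Ab]_s / K_D — the thermodynamic titer — and
# ln(nu_Ab) is the entropic part in R units. All outputs are kept
# dimensionless (ratios to RT and R), so no unit system is imposed.

#' Excess enthalpy and entropy from asymmetry parameters
#'
#' Converts the two fitted asymmetries into the enthalpic and entropic parts
#' of the excess Gibbs free energy:
#' \deqn{\ln \nu_{Ag} = \ln(K_D'/K_D) = \Delta\Delta H / RT, \qquad
#'       \ln \nu_{Ab} = \ln([Ab]_s/K_D) = \Delta\Delta S / R.}
#' Under mass-independent (microspot) measurement conditions apparent affinity
#' exceeds true affinity (\eqn{K_D' < K_D}), so \eqn{\ln \nu_{Ag} > 0} is
#' reported with a warning rather than an error; \eqn{\ln \nu_{Ab}} may take
#' either sign.
#'
#' @param nu_ag Antigen-axis asymmetry (> 0).
#' @param nu_ab Serum-axis asymmetry (> 0).
#' @return An object of class `thermo_summary` with fields `nu_ag`, `nu_ab`,
#'   `ddH_over_RT`, `ddS_over_R`, `kd_ratio` (\eqn{K_D'/K_D}), `thermo_titer`
#'   and `occupancy`.
#' @export
excess_energies <- function(nu_ag, nu_ab) {
  check_positive(nu_ag, "nu_ag")
  check_positive(nu_ab, "nu_ab")
  if (nu_ag > 1)
    warning("nu_ag > 1: apparent affinity weaker than true affinity; ",
            "ln(nu_Ag) is expected to be negative under mass-independent conditions",
            call. = FALSE)
  structure(list(nu_ag = nu_ag, nu_ab = nu_ab,
                 ddH_over_RT = log(nu_ag), ddS_over_R = log(nu_ab),
                 kd_ratio = nu_ag,
                 thermo_titer = thermodynamic_titer(nu_ab),
                 occupancy = occupancy_at_titer(nu_ab)),
            class = "thermo_summary")
}

#' Thermodynamic titer
#'
#' The serum-axis asymmetry parameter read as \eqn{[Ab]_s / K_D}: the ratio of
#' total serum antibody concentration to the equilibrium dissociation
#' constant, a dilution-free, affinity-independent measure of the ability of
#' the serum to saturate antigen. A value of 1 corresponds to half-saturated
#' antigen. It round-trips with the excess entropy:
#' `exp(ddS_over_R)` equals the titer.
#'
#' @param nu_ab Serum-axis asymmetry (> 0).
#' @return The thermodynamic titer (dimensionless).
#' @export
thermodynamic_titer <- function(nu_ab) {
  check_positive(nu_ab, "nu_ab")
  nu_ab
}

#' Antigen saturation at a thermodynamic titer
#'
#' Equilibrium antigen binding-site occupancy under the excess-antibody
#' single-site binding relation \eqn{t / (1 + t)}: one half at titer 1,
#' strictly increasing, with limits 0 and 1. The hyperbolic form is the
#' single-site equilibrium isotherm consistent with the \eqn{[Ab]_s/K_D}
#' reading of the titer.
#'
#' @param t Thermodynamic titer(s), all > 0.
#' @return Saturation fraction(s) in (0, 1).
#' @export
occupancy_at_titer <- function(t) {
  if (!is.numeric(t) || any(!is.finite(t)) || any(t <= 0))
    stop_domain("titer 't' must be finite and positive")
  t / (1 + t)
}

#' Normalized Richards titration factor
#'
#' The dimensionless factor
#' \deqn{\left(\frac{1+\nu}{1+\nu e^{-k(z - z_0)}}\right)^{1/\nu}}
#' used for both the antigen titration curve (in \eqn{\ln[Ag]}) and the
#' antibody titration curve (in \eqn{\ln[Ab]}); it equals 1 at the reference
#' point \eqn{z_0} and is identical to [normalized_richards_value()] with
#' `x_i = z0`.
#'
#' @param z Numeric vector of log-concentrations.
#' @param z0 Reference (inflection) log-concentration.
#' @param nu Asymmetry (> 0).
#' @param k Rate (> 0).
#' @return Numeric vector of dimensionless ratios.
#' @export
titration_factor <- function(z, z0, nu, k) {
  check_real(z0, "z0")
  check_positive(nu, "nu")
  check_positive(k, "k")
  if (nu < NU_GOMPERTZ_SWITCH) return(exp(1 - exp(-k * (z - z0))))
  exp((log1p(nu) - log1pexp(log(nu) - k * (z - z0))) / nu)
}

#' Calibrated signal model
#'
#' `signal_model()` holds the calibration constants that convert bound
#' antibody to fluorescence: the conversion factor `fi_ab` (fluorescence per
#' unit concentration) and the standard binding-site occupancy `ab_bound_std`
#' (bound-antibody concentration at the reference point). `predicted_signal()`
#' evaluates the calibrated dual-titration signal
#' \deqn{FI = FI_{Ab} \cdot [Ab]_{bound}^\circ \cdot R_{1,\nu}(\ln[Ag])
#'       \cdot R_{2,\nu}(\ln[Ab]),}
#' which is linear in both calibration constants and coincides with the
#' normalized double Richards surface under the amplitude identification
#' \eqn{\ln C_n = \ln(FI_{Ab} [Ab]_{bound}^\circ)}.
#'
#' @param fi_ab Fluorescence per unit bound-antibody concentration (> 0).
#' @param ab_bound_std Standard binding-site occupancy (concentration
#'   units, > 0).
#' @return `signal_model()`: an object of class `signal_model`.
#' @export
signal_model <- function(fi_ab, ab_bound_std) {
  check_positive(fi_ab, "fi_ab")
  check_positive(ab_bound_std, "ab_bound_std")
  structure(list(fi_ab = fi_ab, ab_bound_std = ab_bound_std),
            class = "signal_model")
}

#' @rdname signal_model
#' @param x,y Log antigen concentration and log antibody concentration (or
#'   dilution).
#' @param p A [double_richards_params()].
#' @param cal A `signal_model`.
#' @export
predicted_signal <- function(x, y, p, cal) {
  stopifnot(inherits(p, "double_richards_params"), inherits(cal, "signal_model"))
  cal$fi_ab * cal$ab_bound_std *
    titration_factor(x, p$x_i, p$nu1, p$k) *
    titration_factor(y, p$y_i, p$nu2, p$k2)
}

#' Thermodynamic assay report from a converged fit
#'
#' Interprets a converged fit thermodynamically. For a two-dimensional fit,
#' the antigen-axis asymmetry `nu1` maps to \eqn{\nu_{Ag}} and the serum-axis
#' asymmetry `nu2` to \eqn{\nu_{Ab}}, yielding excess enthalpy and entropy,
#' the apparent-to-true \eqn{K_D} ratio, the thermodynamic titer and the
#' antigen occupancy. A one-dimensional (serum-only) fit yields only the
#' \eqn{\nu_{Ab}}-derived quantities — affinity cannot be addressed without
#' antigen titration. With a calibrated [signal_model()] the standard
#' binding-site occupancy is reported in concentration units as
#' \eqn{\exp(\ln C_n) / FI_{Ab}}.
#'
#' @param fit A converged `richards_fit`.
#' @param cal Optional [signal_model()] calibration.
#' @param titer_grid Titer values for the accompanying occupancy table.
#' @return A list of class `assay_report` with elements `thermo` (a
#'   [excess_energies()] summary, or the partial serum-only version),
#'   `axis_mapping`, `occupancy_table` (data.frame `titer`, `occupancy`) and
#'   optionally `ab_bound_std`.
#' @export
assay_report <- function(fit, cal = NULL,
                         titer_grid = c(0.1, 0.25, 0.5, 1, 2, 4, 10)) {
  stopifnot(inherits(fit, "richards_fit"))
  if (!isTRUE(fit$converged))
    stop_domain("no interpretable parameters: the fit did not converge")
  two_d <- inherits(fit$params, "double_richards_params")
  if (two_d) {
    thermo <- excess_energies(nu_ag = fit$params$nu1, nu_ab = fit$params$nu2)
    mapping <- c(nu_ag = "nu1 (antigen axis, x)", nu_ab = "nu2 (serum axis, y)")
  } else {
    nu_ab <- fit$params$nu
    thermo <- structure(list(nu_ag = NA_real_, nu_ab = nu_ab,
                             ddH_over_RT = NA_real_, ddS_over_R = log(nu_ab),
                             kd_ratio = NA_real_,
                             thermo_titer = thermodynamic_titer(nu_ab),
                             occupancy = occupancy_at_titer(nu_ab)),
                        class = "thermo_summary")
    mapping <- c(nu_ab = "nu (single titrated axis)")
  }
  out <- list(thermo = thermo, axis_mapping = mapping,
              occupancy_table = data.frame(titer = titer_grid,
                                           occupancy = occupancy_at_titer(titer_grid)))
  if (!is.null(cal)) {
    stopifnot(inherits(cal, "signal_model"))
    if (two_d) out$ab_bound_std <- exp(fit$params$lnC) / cal$fi_ab
    else out$ab_bound_std <- fit$params$A / cal$fi_ab
  }
  class(out) <- "assay_report"
  out
}

#' @export
print.thermo_summary <- function(x, ...) {
  cat("Thermodynamic summary\n")
  if (is.finite(x$ddH_over_RT %||% NA)) {
    cat(sprintf("  nu_Ag = %g  ->  ddH/RT = %g, K_D'/K_D = %g\n",
                x$nu_ag, x$ddH_over_RT, x$kd_ratio))
  } else cat("  nu_Ag: not available (no antigen titration)\n")
  cat(sprintf("  nu_Ab = %g  ->  ddS/R = %g\n", x$nu_ab, x$ddS_over_R))
  cat(sprintf("  thermodynamic titer [Ab]_s/K_D = %g; antigen occupancy = %.4g\n",
              x$thermo_titer, x$occupancy))
  invisible(x)
}

#' @export
print.assay_report <- function(x, ...) {
  print(x$thermo)
  cat("  axis mapping:", paste(sprintf("%s <- %s", names(x$axis_mapping),
                                       x$axis_mapping), collapse = "; "), "\n")
  if (!is.null(x$ab_bound_std))
    cat(sprintf("  standard binding-site occupancy [Ab]_bound_std = %g (calibrated units)\n",
                x$ab_bound_std))
  invisible(x)
}

#' Serialize a thermodynamic summary
#'
#' Writes a `thermo_summary` to JSON or a one-row CSV, and an occupancy table
#' to CSV.
#'
#' @param x A `thermo_summary` or `assay_report`.
#' @param path Output path.
#' @param format `"json"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_thermo <- function(x, path, format = c("json", "csv")) {
  format <- match.arg(format)
  th <- if (inherits(x, "assay_report")) x$thermo else x
  stopifnot(inherits(th, "thermo_summary"))
  row <- th[c("nu_ag", "nu_ab", "ddH_over_RT", "ddS_over_R", "kd_ratio",
              "thermo_titer", "occupancy")]
  if (format == "json")
    jsonlite::write_json(row, path, auto_unbox = TRUE, digits = NA, na = "null")
  else utils::write.csv(as.data.frame(row), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
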