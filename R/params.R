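#' Logistic curve parameters
#'
#' Container for the three-parameter logistic curve
#' \deqn{L(x) = A / (1 + b e^{-kx}) = A / (1 + e^{-k(x - x_c)})}
#' where \code{A > 0} is the upper limit, \code{k > 0} the rate and \code{x_c}
#' the inflection abscissa. The shift parameter \code{b} is redundant with
#' \code{x_c} through \code{b = exp(k * x_c)} and is stored for the classical
#' parametrization.
#'
#' @param A Upper limit (signal units, > 0).
#' @param k Rate per unit of `x` (> 0).
#' @param x_c Inflection abscissa (log-concentration units). Supply either
#'   `x_c` or `b`.
#' @param b Shift parameter (> 0); converted to `x_c` when given.
#' @param c0 Optional additive baseline (>= 0), turning the curve into the
#'   four-parameter logistic (4PL).
#' @return An object of class `logistic_params`.
#' @export
logistic_params <- function(A, k, x_c = NULL, b = NULL, c0 = 0) {
  check_positive(A, "A")
  check_positive(k, "k")
  if (is.null(x_c) && is.null(b))
    stop_domain("one of 'x_c' or 'b' must be supplied")
  if (!is.null(b)) {
    check_positive(b, "b")
    x_c_from_b <- log(b) / k
    if (!is.null(x_c)) {
      check_real(x_c, "x_c")
      if (abs(x_c - x_c_from_b) > 1e-8 * max(1, abs(x_c)))
        stop_domain("inconsistent 'x_c' and 'b': b = exp(k * x_c) must hold")
    }
    x_c <- x_c_from_b
  } else {
    check_real(x_c, "x_c")
    b <- exp(k * x_c)
  }
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    stop_domain("parameter 'c0' must be a single finite number >= 0")
  structure(list(A = A, k = k, x_c = x_c, b = b, c0 = c0),
            class = "logistic_params")
}

#' Richards curve parameters
#'
#' Container for the Richards (generalized logistic) curve in the
#' \eqn{\nu}-parametrization
#' \deqn{R(x) = A (1 + \nu e^{-k(x - x_i)})^{-1/\nu}}
#' with upper limit \code{A > 0}, asymmetry \eqn{\nu > 0}, rate \code{k > 0}
#' and inflection abscissa \code{x_i}. The alternative asymmetry parameter of
#' the d-form is related by \code{d = nu + 1}; \eqn{\nu = 1} (d = 2) gives the
#' symmetric logistic curve and \eqn{\nu \to 0} (d \to 1) the Gompertz limit.
#'
#' @param A Upper limit (signal units, > 0).
#' @param nu Asymmetry parameter \eqn{\nu} (> 0). Supply either `nu` or `d`.
#' @param k Rate per unit of `x` (> 0).
#' @param x_i Inflection abscissa (log-concentration units).
#' @param d Alternative asymmetry parameter (> 1); converted via `nu = d - 1`.
#' @param c0 Optional additive baseline (>= 0), giving the five-parameter
#'   logistic (5PL) form.
#' @return An object of class `richards_params`.
#' @export
richards_params <- function(A, nu = NULL, k, x_i, d = NULL, c0 = 0) {
  check_positive(A, "A")
  check_positive(k, "k")
  check_real(x_i, "x_i")
  if (is.null(nu) && is.null(d))
    stop_domain("one of 'nu' or 'd' must be supplied")
  if (!is.null(d)) {
    check_real(d, "d")
    if (d <= 1) stop_domain("'d' must exceed 1 (the 0 < d < 1 branch is not modelled)")
    nu_from_d <- d - 1
    if (!is.null(nu) && abs(nu - nu_from_d) > 1e-12 * max(1, nu))
      stop_domain("inconsistent 'nu' and 'd': d = nu + 1 must hold")
    nu <- nu_from_d
  }
  check_positive(nu, "nu")
  if (!is.numeric(c0) || length(c0) != 1L || !is.finite(c0) || c0 < 0)
    stop_domain("parameter 'c0' must be a single finite number >= 0")
  structure(list(A = A, nu = nu, k = k, x_i = x_i, d = nu + 1, c0 = c0),
            class = "richards_params")
}

#' Double Richards surface parameters
#'
#' Parameters of the separable two-variable model for dual titration surfaces,
#' the product of one Richards factor in the log antigen concentration `x` and
#' one in the log serum dilution `y`. Two amplitude conventions exist: the raw
#' product with amplitude \code{C} and the inflection-normalized form in which
#' both factors equal one at their inflection points and the amplitude is
#' \code{Cn}. The convention the stored `lnC` refers to is recorded in the
#' `normalized` flag; the normalized convention is the package default because
#' fitted log-amplitudes are reported for the normalized model.
#'
#' @param lnC Log amplitude (log-signal units): `ln Cn` when
#'   `normalized = TRUE` (default), `ln C` otherwise.
#' @param nu1 Asymmetry of the antigen axis (> 0).
#' @param nu2 Asymmetry of the serum axis (> 0).
#' @param k Shared rate (> 0), used for both axes unless `k2` is given.
#' @param x_i Antigen-axis inflection abscissa (ln molar).
#' @param y_i Serum-axis inflection abscissa (ln dilution).
#' @param k2 Optional second rate for the serum axis (> 0); defaults to `k`,
#'   the shared-rate model.
#' @param normalized Logical; amplitude convention flag (see above).
#' @return An object of class `double_richards_params`.
#' @seealso [normalize_amplitude()] for exact interconversion of the two
#'   amplitude conventions.
#' @export
double_richards_params <- function(lnC, nu1, nu2, k, x_i, y_i, k2 = NULL,
                                   normalized = TRUE) {
  check_real(lnC, "lnC")
  check_positive(nu1, "nu1")
  check_positive(nu2, "nu2")
  check_positive(k, "k")
  check_real(x_i, "x_i")
  check_real(y_i, "y_i")
  shared_k <- is.null(k2)
  if (shared_k) k2 <- k else check_positive(k2, "k2")
  structure(list(lnC = lnC, nu1 = nu1, nu2 = nu2, k = k, k2 = k2,
                 x_i = x_i, y_i = y_i, shared_k = shared_k,
                 normalized = isTRUE(normalized)),
            class = "double_richards_params")
}

#' Convert between raw and normalized amplitude conventions
#'
#' The raw product amplitude \code{C} and the normalized amplitude \code{Cn}
#' interconvert exactly through the per-factor inflection multipliers:
#' \deqn{Cn = C (1+\nu_1)^{-1/\nu_1} (1+\nu_2)^{-1/\nu_2}.}
#'
#' @param p A [double_richards_params()] object.
#' @param normalized Target convention.
#' @return A `double_richards_params` in the requested convention.
#' @export
normalize_amplitude <- function(p, normalized = TRUE) {
  stopifnot(inherits(p, "double_richards_params"))
  if (identical(p$normalized, isTRUE(normalized))) return(p)
  shift <- log1p(p$nu1) / p$nu1 + log1p(p$nu2) / p$nu2
  lnC <- if (normalized) p$lnC - shift else p$lnC + shift
  double_richards_params(lnC = lnC, nu1 = p$nu1, nu2 = p$nu2, k = p$k,
                         x_i = p$x_i, y_i = p$y_i,
                         k2 = if (p$shared_k) NULL else p$k2,
                         normalized = normalized)
}

#' @export
print.richards_params <- function(x, ...) {
  cat("Richards curve parameters\n")
  cat(sprintf("  A = %g, nu = %g (d = %g), k = %g, x_i = %g", x$A, x$nu, x$d, x$k, x$x_i))
  if (x$c0 > 0) cat(sprintf(", baseline c0 = %g", x$c0))
  cat("\n")
  invisible(x)
}

#' @export
print.double_richards_params <- function(x, ...) {
  cat("Double Richards surface parameters (",
      if (x$normalized) "normalized" else "raw", " amplitude)\n", sep = "")
  cat(sprintf("  lnC = %g, nu1 = %g, x_i = %g, nu2 = %g, y_i = %g\n",
              x$lnC, x$nu1, x$x_i, x$nu2, x$y_i))
  if (x$shared_k) cat(sprintf("  shared rate k = %g\n", x$k))
  else cat(sprintf("  rates k = %g (antigen axis), k2 = %g (serum axis)\n", x$k, x$k2))
  invisible(x)
}

#' Serialize parameters to a flat key-value config string
#'
#' Writes parameters as plain-text `key = value` lines (keys `A`, `nu`, `k`,
#' `x_i`, `c0` for a single curve; `lnC`, `nu1`, `nu2`, `k`, `k2`, `x_i`,
#' `y_i`, `normalized` for a surface), and reads them back.
#'
#' @param p Parameter object.
#' @param path Optional file to write; when `NULL` the lines are returned.
#' @return Character vector of config lines, invisibly when written to file.
#' @export
write_params_config <- function(p, path = NULL) {
  if (inherits(p, "richards_params")) {
    kv <- c(A = p$A, nu = p$nu, k = p$k, x_i = p$x_i, c0 = p$c0)
  } else if (inherits(p, "double_richards_params")) {
    kv <- c(lnC = p$lnC, nu1 = p$nu1, nu2 = p$nu2, k = p$k, k2 = p$k2,
            x_i = p$x_i, y_i = p$y_i, normalized = as.numeric(p$normalized))
  } else stop_domain("unsupported parameter object")
  lines <- sprintf("%s = %.17g", names(kv), kv)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' @rdname write_params_config
#' @param lines Character vector of `key = value` lines (or a file path in
#'   `path`).
#' @export
read_params_config <- function(path = NULL, lines = NULL) {
  if (is.null(lines)) lines <- readLines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(parts, `[`, "", 1L))
  vals <- as.numeric(trimws(vapply(parts, `[`, "", 2L)))
  kv <- stats::setNames(vals, keys)
  if ("lnC" %in% keys) {
    double_richards_params(lnC = kv[["lnC"]], nu1 = kv[["nu1"]], nu2 = kv[["nu2"]],
                           k = kv[["k"]],
                           k2 = if ("k2" %in% keys && kv[["k2"]] != kv[["k"]]) kv[["k2"]] else NULL,
                           x_i = kv[["x_i"]], y_i = kv[["y_i"]],
                           normalized = isTRUE(kv[["normalized"]] > 0))
  } else {
    richards_params(A = kv[["A"]], nu = kv[["nu"]], k = kv[["k"]], x_i = kv[["x_i"]],
                    c0 = if ("c0" %in% keys) kv[["c0"]] else 0)
  }
}
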