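# The separable two-variable product model for dual titration surfaces.

# One normalized Richards log-factor: (1/nu) * ln((1+nu) / (1 + nu e^{-k(z - z0)})).
log_norm_factor <- function(z, z0, nu, k) {
  if (nu < NU_GOMPERTZ_SWITCH) return(1 - exp(-k * (z - z0)))
  (log1p(nu) - log1pexp(log(nu) - k * (z - z0))) / nu
}

# One raw Richards log-factor: -(1/nu) * ln(1 + nu e^{-k(z - z0)}).
log_raw_factor <- function(z, z0, nu, k) {
  if (nu < NU_GOMPERTZ_SWITCH) return(-exp(-k * (z - z0)))
  -log1pexp(log(nu) - k * (z - z0)) / nu
}

#' Evaluate the double Richards surface
#'
#' The dual-titration model is the product of one Richards factor in the log
#' antigen concentration `x` and one in the log serum dilution `y`, sharing a
#' rate `k` by default:
#' \deqn{R(x, y) = C (1 + \nu_1 e^{-k(x - x_i)})^{-1/\nu_1}
#'                  (1 + \nu_2 e^{-k_2(y - y_i)})^{-1/\nu_2}.}
#' `double_value()` returns the signal under the raw amplitude convention;
#' `log_double_normalized()` returns the log surface under the
#' inflection-normalized convention, which equals `lnC` at \eqn{(x_i, y_i)}
#' because both normalized factors are one at their inflection points.
#'
#' @param x,y Numeric vectors (recycled) of log antigen concentration and log
#'   serum dilution.
#' @param p A [double_richards_params()] object. `double_value()` requires the
#'   raw convention and `log_double_normalized()` the normalized one; convert
#'   with [normalize_amplitude()].
#' @return Numeric vector of signal (`double_value`) or log-signal
#'   (`log_double_normalized`) values.
#' @export
double_value <- function(x, y, p) {
  stopifnot(inherits(p, "double_richards_params"))
  if (p$normalized) p <- normalize_amplitude(p, normalized = FALSE)
  exp(p$lnC + log_raw_factor(x, p$x_i, p$nu1, p$k) +
        log_raw_factor(y, p$y_i, p$nu2, p$k2))
}

#' @rdname double_value
#' @export
log_double_normalized <- function(x, y, p) {
  stopifnot(inherits(p, "double_richards_params"))
  if (!p$normalized) p <- normalize_amplitude(p, normalized = TRUE)
  p$lnC + log_norm_factor(x, p$x_i, p$nu1, p$k) +
    log_norm_factor(y, p$y_i, p$nu2, p$k2)
}

#' Evaluate the model on a grid
#'
#' Evaluates the double Richards model at every pair of a sorted antigen grid
#' and a sorted dilution grid. Rows index `x` (antigen axis), columns index
#' `y` (serum axis), both ascending.
#'
#' @param p A [double_richards_params()] object.
#' @param x_grid,y_grid Sorted, non-empty numeric grids.
#' @param scale `"log"` for the normalized log surface (the fitting scale) or
#'   `"linear"` for raw signal.
#' @return An object of class `titration_surface`: list with `x_grid`,
#'   `y_grid`, `values` (matrix, `length(x_grid)` rows), and `scale`.
#' @export
eval_surface <- function(p, x_grid, y_grid, scale = c("log", "linear")) {
  stopifnot(inherits(p, "double_richards_params"))
  scale <- match.arg(scale)
  if (length(x_grid) == 0L || length(y_grid) == 0L)
    stop_domain("grids must be non-empty")
  if (is.unsorted(x_grid, strictly = FALSE) || is.unsorted(y_grid, strictly = FALSE))
    stop_domain("grids must be sorted ascending")
  f <- if (scale == "log") log_double_normalized else double_value
  values <- outer(x_grid, y_grid, function(xx, yy) f(xx, yy, p))
  structure(list(x_grid = x_grid, y_grid = y_grid, values = values,
                 scale = scale),
            class = "titration_surface")
}

#' Export a surface
#'
#' `surface_to_df()` flattens a surface to tidy long format (one row per grid
#' point, columns `x`, `y`, `value`); `write_surface()` writes either that
#' tidy CSV or a dense matrix text format whose first row holds the `y` grid
#' and first column the `x` grid.
#'
#' @param s A `titration_surface` from [eval_surface()].
#' @param path Output file path.
#' @param format `"tidy"` or `"matrix"`.
#' @return `surface_to_df()`: a data.frame. `write_surface()`: `path`,
#'   invisibly.
#' @export
surface_to_df <- function(s) {
  stopifnot(inherits(s, "titration_surface"))
  data.frame(x = rep(s$x_grid, times = length(s$y_grid)),
             y = rep(s$y_grid, each = length(s$x_grid)),
             value = as.vector(s$values))
}

#' @rdname surface_to_df
#' @export
write_surface <- function(s, path, format = c("tidy", "matrix")) {
  stopifnot(inherits(s, "titration_surface"))
  format <- match.arg(format)
  if (format == "tidy") {
    utils::write.csv(surface_to_df(s), path, row.names = FALSE)
  } else {
    m <- rbind(c(NA, s$y_grid), cbind(s$x_grid, s$values))
    utils::write.table(m, path, sep = "\t", row.names = FALSE,
                       col.names = FALSE, na = "")
  }
  invisible(path)
}

#' @export
print.titration_surface <- function(x, ...) {
  cat(sprintf("Titration surface (%s scale): %d x-points x %d y-points\n",
              x$scale, length(x$x_grid), length(x$y_grid)))
  cat(sprintf("  x in [%g, %g], y in [%g, %g], values in [%g, %g]\n",
              min(x$x_grid), max(x$x_grid), min(x$y_grid), max(x$y_grid),
              min(x$values), max(x$values)))
  invisible(x)
}
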