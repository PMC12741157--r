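# Tabular input/output and result serialization.
#
# The one input dialect is tidy long format: one measurement per row, header
# columns x, y, fi and optionally replicate. Log-concentration columns are
# natural logarithms throughout. Delimiter is sniffed from the extension
# (.tsv/.txt -> tab, otherwise comma).

#' Read and write titration data
#'
#' `read_titration()` reads a tidy CSV/TSV with required columns `x` (ln
#' antigen concentration), `y` (ln serum dilution) and `fi` (fluorescence
#' intensity), plus an optional `replicate`. Rows with non-finite `fi` are
#' rejected with their line numbers reported; rows with `fi <= 0` are kept
#' but flagged (they are dropped later by log-scale fitting).
#' `write_titration()` writes the same format, so the pair round-trips
#' exactly.
#'
#' @param path File path; delimiter sniffed from the extension.
#' @return `read_titration()`: a [titration_dataset()].
#' @export
read_titration <- function(path) {
  if (!file.exists(path)) stop_domain("input file not found: %s", path)
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, comment.char = "#")
  if (nrow(raw) == 0L) stop_domain("empty input file: %s", path)
  for (col in c("x", "y", "fi"))
    if (!col %in% names(raw)) stop_domain("missing column: %s", col)
  bad <- which(!is.finite(raw$fi) | !is.finite(raw$x) | !is.finite(raw$y))
  if (length(bad)) {
    message(sprintf("read_titration: rejecting %d row(s) with non-finite values (data rows: %s)",
                    length(bad), paste(utils::head(bad, 10), collapse = ", ")))
    raw <- raw[-bad, , drop = FALSE]
    if (nrow(raw) == 0L) stop_domain("no valid rows in %s", path)
  }
  titration_dataset(x = raw$x, y = raw$y, fi = raw$fi,
                    replicate = if ("replicate" %in% names(raw)) raw$replicate else "r1",
                    meta = list(source = path,
                                units = "x, y: natural log; fi: fluorescence intensity"))
}

#' @rdname read_titration
#' @param data A [titration_dataset()].
#' @return `write_titration()`: `path`, invisibly.
#' @export
write_titration <- function(data, path) {
  stopifnot(inherits(data, "titration_dataset"))
  sep <- if (grepl("\\.(tsv|txt)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(as.data.frame(data)[, c("x", "y", "fi", "replicate")],
                     path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

fit_estimates_list <- function(fit) {
  est <- as.list(fit$estimates)
  unc <- if (fit$method == "bayes" && !is.null(fit$uncertainty$ci)) {
    ci <- fit$uncertainty$ci
    lapply(colnames(ci), function(nm) list(q2.5 = ci[1, nm], q97.5 = ci[2, nm]))
  } else if (!is.null(fit$uncertainty$se)) {
    as.list(fit$uncertainty$se)
  } else NULL
  if (!is.null(unc) && is.null(names(unc))) names(unc) <- colnames(fit$uncertainty$ci)
  list(estimates = est, uncertainty = unc)
}

#' Serialize a fit result to JSON
#'
#' Writes parameters, uncertainty, diagnostics and the convergence flag,
#' together with provenance fields: package version, an MD5 hash of the
#' serialized fit configuration, and an MD5 checksum of the input file when
#' one is known.
#'
#' @param fit A `richards_fit`.
#' @param path Output path.
#' @param input_path Optional path of the input data file, checksummed into
#'   the provenance block.
#' @return `path`, invisibly.
#' @export
write_fit_json <- function(fit, path, input_path = NULL) {
  stopifnot(inherits(fit, "richards_fit"))
  diag <- fit$diagnostics
  diag <- diag[vapply(diag, function(v) is.atomic(v) && length(v) < 50, TRUE)]
  cfg <- list(method = fit$method, model = fit$model,
              estimates = as.list(fit$estimates))
  cfg_file <- tempfile()
  on.exit(unlink(cfg_file))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), cfg_file)
  provenance <- list(
    package = "richtitr",
    version = as.character(utils::packageVersion("richtitr")),
    config_hash = unname(tools::md5sum(cfg_file)),
    input_checksum = if (!is.null(input_path) && file.exists(input_path))
      unname(tools::md5sum(input_path)) else NULL)
  payload <- c(list(method = fit$method, model = fit$model,
                    converged = fit$converged, reason = fit$reason),
               fit_estimates_list(fit),
               list(residual_rmse = fit$residual_rmse,
                    diagnostics = diag, provenance = provenance))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       na = "null", null = "null")
  invisible(path)
}

#' Write a flat parameter table
#'
#' One row per fit, columns `method, lnC, nu1, x_i, nu2, y_i` (the reporting
#' layout for normalized double Richards fits), written as CSV.
#'
#' @param fits A `richards_fit` or list of them (2-D fits only).
#' @param path Output path.
#' @return The table, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  if (inherits(fits, "richards_fit")) fits <- list(fits)
  rows <- lapply(fits, function(f) {
    stopifnot(inherits(f, "richards_fit"))
    if (!inherits(f$params, "double_richards_params"))
      stop_domain("the parameter table layout applies to 2-D fits")
    data.frame(method = f$method, lnC = f$params$lnC, nu1 = f$params$nu1,
               x_i = f$params$x_i, nu2 = f$params$nu2, y_i = f$params$y_i)
  })
  tab <- do.call(rbind, rows)
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(tab)
}

#' Read a fit result back from JSON
#'
#' Restores the estimates, convergence flag and (for 2-D fits) the parameter
#' object from a file written by [write_fit_json()]; enough to feed
#' [assay_report()].
#'
#' @param path JSON file written by [write_fit_json()].
#' @return A `richards_fit`.
#' @export
read_fit_json <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  est <- unlist(j$estimates)
  params <- if (identical(j$model, "double_richards")) {
    double_richards_params(lnC = est[["lnC"]], nu1 = est[["nu1"]],
                           nu2 = est[["nu2"]], k = est[["k"]],
                           x_i = est[["x_i"]], y_i = est[["y_i"]],
                           k2 = if ("k2" %in% names(est)) est[["k2"]] else NULL,
                           normalized = TRUE)
  } else {
    richards_params(A = est[["A"]], nu = est[["nu"]], k = est[["k"]],
                    x_i = est[["x_i"]],
                    c0 = if ("c0" %in% names(est)) est[["c0"]] else 0)
  }
  new_fit_result(params, j$method, est, list(), isTRUE(j$converged),
                 j$reason, as.list(j$diagnostics), j$residual_rmse,
                 model = j$model)
}
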