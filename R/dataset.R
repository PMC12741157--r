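#' Titration dataset
#'
#' Tidy container for dual-titration measurements: one record per measured
#' spot, with log antigen concentration `x` (ln molar), log serum dilution `y`
#' (ln of the dilution fraction), fluorescence intensity `fi` and an optional
#' replicate label. Records with non-positive `fi` are kept but flagged, since
#' they cannot enter log-scale fitting.
#'
#' @param x,y,fi Numeric vectors of equal length.
#' @param replicate Replicate labels (recycled); defaults to `"r1"`.
#' @param meta Optional named list of metadata (sample ID, units note, ...).
#' @return A data.frame of class `titration_dataset` with columns `x`, `y`,
#'   `fi`, `replicate` and attribute `meta`.
#' @export
titration_dataset <- function(x, y, fi, replicate = "r1", meta = list()) {
  n <- length(fi)
  if (n == 0L) stop_domain("a titration dataset needs at least one record")
  if (length(x) != n || length(y) != n)
    stop_domain("'x', 'y' and 'fi' must have equal length")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop_domain("'x' and 'y' must be finite")
  if (any(!is.finite(fi)))
    stop_domain("'fi' must be finite")
  d <- data.frame(x = as.numeric(x), y = as.numeric(y), fi = as.numeric(fi),
                  replicate = as.character(rep_len(replicate, n)))
  n_nonpos <- sum(d$fi <= 0)
  if (n_nonpos > 0)
    message(sprintf("titration_dataset: %d record(s) with fi <= 0 flagged; they are dropped from log-scale fitting", n_nonpos))
  attr(d, "meta") <- meta
  class(d) <- c("titration_dataset", "data.frame")
  d
}

#' @export
print.titration_dataset <- function(x, ...) {
  cat(sprintf("Titration dataset: %d records, %d distinct x, %d distinct y, %d replicate label(s)\n",
              nrow(x), length(unique(x$x)), length(unique(x$y)),
              length(unique(x$replicate))))
  meta <- attr(x, "meta")
  if (length(meta)) {
    keys <- names(meta)[vapply(meta, function(v) is.atomic(v) && length(v) == 1L, TRUE)]
    if (length(keys))
      cat("  meta:", paste(sprintf("%s=%s", keys, unlist(meta[keys])), collapse = ", "), "\n")
  }
  utils::str(utils::head(as.data.frame(x), 3), give.attr = FALSE)
  invisible(x)
}

# Records usable for log-scale fitting; messages a count when rows are dropped.
fitting_records <- function(data, quiet = FALSE) {
  keep <- is.finite(data$fi) & data$fi > 0
  if (!all(keep) && !quiet)
    message(sprintf("dropping %d record(s) with fi <= 0 before log-scale fitting", sum(!keep)))
  data[keep, , drop = FALSE]
}
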