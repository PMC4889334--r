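#' Read and validate an intensity-trace CSV
#'
#' The trace schema has columns `mrna_id`, `time_s`, `green` and
#' optionally `red`, `frame`, `dataset_id`, `x_um`, `y_um`.  Validation
#' errors name the offending column.
#'
#' @param path CSV file path.
#' @param require One of `"traces"` (needs `green`) or `"tracks"` (needs
#'   `x_um`, `y_um`).
#' @return A tibble.
#' @export
read_traces <- function(path, require = c("traces", "tracks")) {
  require <- match.arg(require)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  x <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  if (nrow(x) == 0) abort("trace file is empty")
  need <- c("mrna_id", "time_s",
            if (require == "traces") "green" else c("x_um", "y_um"))
  missing <- setdiff(need, names(x))
  if (length(missing) > 0)
    abort(sprintf("missing required column(s): %s", paste(missing, collapse = ", ")))
  for (col in intersect(c("time_s", "green", "red", "x_um", "y_um"), names(x))) {
    bad <- which(!is.finite(x[[col]]))
    if (length(bad) > 0)
      abort(sprintf("non-finite value in column '%s' at row %d", col, bad[1]))
  }
  x
}

#' @rdname read_traces
#' @param traces A trace tibble.
#' @export
write_traces <- function(traces, path) {
  write.csv(traces, path, row.names = FALSE)
  invisible(path)
}
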