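# Timestamped-series CSV reader/writer.

#' CSV dialect for timestamped series files
#'
#' @param delimiter field separator (default `","`).
#' @param timestamp_col,value_col column names (defaults `"timestamp_s"`,
#'   `"value"`).
#' @param header whether files carry a header row (default `TRUE`; without a
#'   header the first two columns are taken as timestamp and value).
#' @return an object of class `series_dialect`.
#' @export
series_dialect <- function(delimiter = ",", timestamp_col = "timestamp_s",
                           value_col = "value", header = TRUE) {
  structure(
    list(delimiter = delimiter, timestamp_col = timestamp_col,
         value_col = value_col, header = isTRUE(header)),
    class = "series_dialect"
  )
}

#' Read a timestamped series from CSV
#'
#' Rows with non-finite timestamp or value are dropped with a warning giving
#' the count; the result is sorted by timestamp.
#'
#' @param path file path.
#' @param dialect a [series_dialect()].
#' @return a validated [sampled_series()].
#' @export
read_series <- function(path, dialect = series_dialect()) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  df <- tryCatch(
    utils::read.table(path, sep = dialect$delimiter, header = dialect$header,
                      stringsAsFactors = FALSE),
    error = function(e) stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                             call. = FALSE)
  )
  if (dialect$header) {
    miss <- setdiff(c(dialect$timestamp_col, dialect$value_col), names(df))
    if (length(miss)) {
      stop(sprintf("missing column(s) in %s: %s", path, paste(miss, collapse = ", ")),
           call. = FALSE)
    }
    ts <- df[[dialect$timestamp_col]]
    val <- df[[dialect$value_col]]
  } else {
    if (ncol(df) < 2L) stop(sprintf("%s needs at least two columns", path), call. = FALSE)
    ts <- df[[1L]]
    val <- df[[2L]]
  }
  ts <- suppressWarnings(as.double(ts))
  val <- suppressWarnings(as.double(val))
  ok <- is.finite(ts) & is.finite(val)
  if (sum(ok) < 1L) stop(sprintf("%s contains no valid rows", path), call. = FALSE)
  if (any(!ok)) warning(sprintf("dropped %d row(s) with non-finite entries", sum(!ok)))
  ord <- order(ts[ok])
  sampled_series(ts[ok][ord], val[ok][ord])
}

#' Write a timestamped series to CSV
#'
#' Values are written with 17 significant digits (full double precision) and
#' a locale-independent decimal point, so [read_series()] round-trips
#' exactly.
#'
#' @param series a [sampled_series()].
#' @param path output file path.
#' @param dialect a [series_dialect()].
#' @return the path, invisibly.
#' @export
write_series <- function(series, path, dialect = series_dialect()) {
  stopifnot(inherits(series, "sampled_series"))
  lines <- sprintf(paste0("%.17g", dialect$delimiter, "%.17g"),
                   series$timestamps, series$values)
  if (dialect$header) {
    lines <- c(paste(dialect$timestamp_col, dialect$value_col,
                     sep = dialect$delimiter), lines)
  }
  writeLines(lines, path)
  invisible(path)
}
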