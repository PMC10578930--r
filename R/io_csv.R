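#' Read and write epoch tables as CSV
#'
#' Epoch CSVs have the header `start,end` with an optional third `label`
#' column; times are seconds with `.` as decimal separator. On read, the
#' intervals are normalized exactly as [epoch_set()] does (sorted;
#' overlapping or abutting intervals merged, keeping the earliest label).
#'
#' @param path File path.
#' @param ep An [epoch_set] to write.
#' @return `read_epochs_csv` returns an [epoch_set];
#'   `write_epochs_csv` invisibly returns `path`.
#' @export
read_epochs_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  cols <- names(d)
  if (length(cols) < 2L || cols[1] != "start" || cols[2] != "end" ||
      (length(cols) == 3L && cols[3] != "label") || length(cols) > 3L) {
    stop("expected header 'start,end[,label]' but found '",
         paste(cols, collapse = ","), "' in ", path)
  }
  s <- suppressWarnings(as.numeric(d$start))
  e <- suppressWarnings(as.numeric(d$end))
  bad <- which(is.na(s) | is.na(e))
  if (length(bad)) stop("non-numeric start/end in row ", bad[1], " of ", path)
  bad <- which(e < s)
  if (length(bad)) {
    stop("end < start in row ", bad[1], " of ", path, " (start = ",
         s[bad[1]], ", end = ", e[bad[1]], ")")
  }
  epoch_set(s, e, labels = if (length(cols) == 3L) d$label else NULL)
}

#' @rdname read_epochs_csv
#' @export
write_epochs_csv <- function(ep, path) {
  utils::write.csv(as.data.frame(ep), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read behavioral tracking data from CSV
#'
#' Loads a tracking table (e.g. position or head-direction samples exported
#' by a video tracker) into a [ts_frame]. Rows with any missing value in
#' the used columns are dropped (their count is reported via `message`);
#' after dropping, times must be strictly increasing. The time support is
#' the single interval spanning the first and last sample.
#'
#' @param path File path.
#' @param time_column Name of the time column (seconds).
#' @param value_columns Names of the value columns; default: all columns
#'   except the time column.
#' @return A [ts_frame].
#' @export
read_tracking_csv <- function(path, time_column = "time",
                              value_columns = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (is.null(value_columns)) {
    value_columns <- setdiff(names(d), time_column)
  }
  missing <- setdiff(c(time_column, value_columns), names(d))
  if (length(missing)) {
    stop("column(s) not found in ", path, ": ",
         paste(missing, collapse = ", "))
  }
  use <- d[, c(time_column, value_columns), drop = FALSE]
  for (cc in names(use)) use[[cc]] <- suppressWarnings(as.numeric(use[[cc]]))
  ok <- stats::complete.cases(use)
  if (any(!ok)) {
    message("read_tracking_csv: dropped ", sum(!ok),
            " row(s) with missing values")
    use <- use[ok, , drop = FALSE]
  }
  tm <- use[[time_column]]
  if (length(tm) > 1L && any(diff(tm) <= 0)) {
    stop("time column '", time_column, "' is not strictly increasing in ",
         path)
  }
  ts_frame(tm, as.matrix(use[, value_columns, drop = FALSE]),
           columns = value_columns)
}
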