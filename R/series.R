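#' Time series containers
#'
#' Three containers hold time-resolved data, all indexed in seconds and all
#' carrying an [epoch_set] *time support* — the epochs over which the data
#' are valid. The time support is what distinguishes "no events were
#' observed here" from "this period was excluded".
#'
#' * `ts_events(times)`: discrete event times with no values (spikes, licks,
#'   stimulus onsets). Duplicated times are allowed (simultaneous events);
#'   decreasing times are rejected rather than silently sorted.
#' * `ts_signal(times, values)`: one sampled value per time (a position,
#'   an LFP trace, a fluorescence trace).
#' * `ts_frame(times, values, columns)`: a fixed-width row of named channels
#'   per time — all channels share the same timestamps.
#'
#' When no `time_support` is given, the support defaults to the single
#' spanning interval `[min(times), max(times)]`. Every time must lie inside
#' the support (closed-interval membership).
#'
#' @param times Non-decreasing numeric vector of times.
#' @param values For `ts_signal` a numeric vector (one value per time); for
#'   `ts_frame` a numeric matrix with one row per time.
#' @param columns Optional unique column names for `ts_frame`.
#' @param time_support Optional [epoch_set]; defaults to the spanning
#'   interval of `times`.
#' @param time_units Unit of the input times (`"s"`, `"ms"`, `"us"`);
#'   storage is always seconds.
#' @return An object of class `ts_events`, `ts_signal` or `ts_frame`.
#' @examples
#' spk <- ts_events(c(0.1, 0.5, 2.3), time_support = epoch_set(0, 10))
#' event_rate(spk)
#' @export
ts_events <- function(times, time_support = NULL, time_units = "s") {
  times <- check_times(times, time_units)
  time_support <- default_support(times, time_support)
  check_membership(times, time_support)
  structure(list(times = times, time_support = time_support),
            class = "ts_events")
}

#' @rdname ts_events
#' @export
ts_signal <- function(times, values, time_support = NULL, time_units = "s") {
  times <- check_times(times, time_units)
  values <- as.numeric(values)
  if (length(values) != length(times)) {
    stop("'values' must have one entry per time (", length(values), " vs ",
         length(times), ")")
  }
  time_support <- default_support(times, time_support)
  check_membership(times, time_support)
  structure(list(times = times, values = values, time_support = time_support),
            class = "ts_signal")
}

#' @rdname ts_events
#' @export
ts_frame <- function(times, values, columns = NULL, time_support = NULL,
                     time_units = "s") {
  times <- check_times(times, time_units)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (nrow(values) != length(times)) {
    stop("'values' must have one row per time (", nrow(values), " vs ",
         length(times), ")")
  }
  if (is.null(columns)) {
    columns <- colnames(values)
    if (is.null(columns)) columns <- paste0("V", seq_len(ncol(values)))
  }
  if (length(columns) != ncol(values)) stop("one column name per column required")
  if (anyDuplicated(columns)) stop("column names must be unique")
  colnames(values) <- columns
  time_support <- default_support(times, time_support)
  check_membership(times, time_support)
  structure(list(times = times, values = values, time_support = time_support),
            class = "ts_frame")
}

check_times <- function(times, time_units = "s") {
  times <- as.numeric(times)
  if (anyNA(times)) stop("times must not contain NA")
  if (is.unsorted(times)) {
    stop("times must be non-decreasing; refusing to sort implicitly")
  }
  times / time_unit_scale(time_units)
}

default_support <- function(times, time_support) {
  if (is.null(time_support)) {
    if (length(times) == 0L) return(epoch_set(numeric(0), numeric(0)))
    return(epoch_set(times[1], times[length(times)]))
  }
  validate_epoch_set(time_support, "time_support")
  time_support
}

check_membership <- function(times, support) {
  if (length(times) && !all(in_epochs(support, times))) {
    stop("all times must lie inside the time support")
  }
  invisible(TRUE)
}

#' Accessors for time series objects
#'
#' @param x A `ts_events`, `ts_signal`, `ts_frame` or `event_group`.
#' @return `sample_times` returns the time vector (seconds),
#'   `sample_values` the value vector/matrix, `time_support` the
#'   [epoch_set] support.
#' @export
sample_times <- function(x) x$times

#' @rdname sample_times
#' @export
sample_values <- function(x) x$values

#' @rdname sample_times
#' @export
time_support <- function(x) x$time_support

#' @export
length.ts_events <- function(x) length(x$times)

#' @export
length.ts_signal <- function(x) length(x$times)

#' @export
length.ts_frame <- function(x) length(x$times)

#' @export
print.ts_events <- function(x, ...) {
  cat("ts_events:", length(x), "event(s) on support of",
      format(total_duration(x$time_support)), "s\n")
  invisible(x)
}

#' @export
print.ts_signal <- function(x, ...) {
  cat("ts_signal:", length(x), "sample(s) on support of",
      format(total_duration(x$time_support)), "s\n")
  invisible(x)
}

#' @export
print.ts_frame <- function(x, ...) {
  cat("ts_frame:", length(x), "sample(s) x", ncol(x$values),
      "channel(s) [", paste(colnames(x$values), collapse = ", "),
      "] on support of", format(total_duration(x$time_support)), "s\n")
  invisible(x)
}

#' @export
as.data.frame.ts_signal <- function(x, ...) {
  data.frame(time = x$times, value = x$values)
}

#' @export
as.data.frame.ts_frame <- function(x, ...) {
  cbind(data.frame(time = x$times), as.data.frame(x$values))
}

#' @export
as.data.frame.ts_events <- function(x, ...) data.frame(time = x$times)

#' Express times in another unit
#'
#' Returns a display view of a series or epoch set with times expressed in
#' the requested unit (`"s"`, `"ms"`, `"us"`) as a data frame. Internal
#' storage is always seconds; the conversion is display-only and the
#' round trip second -> unit -> second is exact for representable values
#' (displayed times are `t * scale`, ingest divides by the same scale).
#'
#' @param x A series object or an [epoch_set].
#' @param units Target unit: `"s"`, `"ms"` or `"us"`.
#' @return A data frame with time columns in the requested unit.
#' @export
as_units <- function(x, units = "s") UseMethod("as_units")

#' @export
as_units.ts_events <- function(x, units = "s") {
  data.frame(time = x$times * time_unit_scale(units))
}

#' @export
as_units.ts_signal <- function(x, units = "s") {
  data.frame(time = x$times * time_unit_scale(units), value = x$values)
}

#' @export
as_units.ts_frame <- function(x, units = "s") {
  cbind(data.frame(time = x$times * time_unit_scale(units)),
        as.data.frame(x$values))
}

#' @export
as_units.epoch_set <- function(x, units = "s") {
  sc <- time_unit_scale(units)
  d <- data.frame(start = x$start * sc, end = x$end * sc)
  if (!is.null(x$label)) d$label <- x$label
  d
}

validate_series <- function(x, name = deparse(substitute(x))) {
  if (!inherits(x, c("ts_events", "ts_signal", "ts_frame"))) {
    stop("'", name, "' is not a time series object")
  }
  if (anyNA(x$times) || is.unsorted(x$times)) {
    stop("invalid series '", name, "': times must be sorted, no NA")
  }
  validate_epoch_set(x$time_support, name)
  check_membership(x$times, x$time_support)
  if (inherits(x, "ts_signal") && length(x$values) != length(x$times)) {
    stop("invalid series '", name, "': values length mismatch")
  }
  if (inherits(x, "ts_frame") &&
      (!is.matrix(x$values) || nrow(x$values) != length(x$times))) {
    stop("invalid series '", name, "': values row mismatch")
  }
  invisible(TRUE)
}
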