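#' Restrict a time series to a set of epochs
#'
#' Keeps the samples or events whose times fall inside `ep`
#' (closed-interval membership) and propagates the time support: the
#' result's support is the intersection of the original support with `ep`.
#' Restriction is idempotent and restricting to the object's own support is
#' the identity.
#'
#' @param x A `ts_events`, `ts_signal`, `ts_frame` or `event_group`.
#' @param ep An [epoch_set].
#' @return An object of the same class as `x`.
#' @export
restrict <- function(x, ep) UseMethod("restrict")

#' @export
restrict.ts_events <- function(x, ep) {
  keep <- in_epochs(ep, x$times)
  sup <- ep_intersect(x$time_support, ep)
  structure(list(times = x$times[keep], time_support = sup),
            class = "ts_events")
}

#' @export
restrict.ts_signal <- function(x, ep) {
  keep <- in_epochs(ep, x$times)
  sup <- ep_intersect(x$time_support, ep)
  structure(list(times = x$times[keep], values = x$values[keep],
                 time_support = sup), class = "ts_signal")
}

#' @export
restrict.ts_frame <- function(x, ep) {
  keep <- in_epochs(ep, x$times)
  sup <- ep_intersect(x$time_support, ep)
  structure(list(times = x$times[keep],
                 values = x$values[keep, , drop = FALSE],
                 time_support = sup), class = "ts_frame")
}

# nearest source index for each target time; ties go to the earlier sample
nearest_index <- function(target_times, source_times) {
  i <- findInterval(target_times, source_times)
  lo <- pmax(i, 1L)
  hi <- pmin(i + 1L, length(source_times))
  dlo <- abs(target_times - source_times[lo])
  dhi <- abs(source_times[hi] - target_times)
  out <- ifelse(i == 0L, hi, ifelse(i >= length(source_times) | dlo <= dhi,
                                    lo, hi))
  as.integer(out)
}

#' Sample one series at the times of another
#'
#' For each time of `target` (after restriction to the common support and
#' optionally `ep`), takes the value of `source` at its nearest timestamp;
#' equidistant ties go to the earlier source sample. No interpolation is
#' performed and no maximum-gap cutoff applies. The output carries the
#' target's surviving times, the source's value type, and the intersected
#' support.
#'
#' @param target A `ts_events` or `ts_signal` providing the output times.
#' @param source A `ts_signal` or `ts_frame` providing values.
#' @param ep Optional [epoch_set] further restricting the operation.
#' @return A `ts_signal` (or `ts_frame` if `source` is one) on the target's
#'   surviving times.
#' @examples
#' pos <- ts_signal(0:10, (0:10)^2)
#' spk <- ts_events(c(1.2, 4.9))
#' value_from(spk, pos)   # position at each spike time
#' @export
value_from <- function(target, source, ep = NULL) {
  if (!inherits(source, c("ts_signal", "ts_frame"))) {
    stop("'source' must be a ts_signal or ts_frame")
  }
  sup <- ep_intersect(target$time_support, source$time_support)
  if (!is.null(ep)) sup <- ep_intersect(sup, ep)
  tgt <- restrict(target, sup)
  if (length(source) == 0L || n_intervals(sup) == 0L) {
    stop("'source' has no samples available on the common time support")
  }
  # nearest lookup scans all source samples; only the target is restricted
  idx <- nearest_index(tgt$times, source$times)
  if (inherits(source, "ts_frame")) {
    ts_frame(tgt$times, source$values[idx, , drop = FALSE],
             columns = colnames(source$values), time_support = sup)
  } else {
    ts_signal(tgt$times, source$values[idx], time_support = sup)
  }
}

# bin edges tiling one interval [s, e] with full bins of width b
full_bin_edges <- function(s, e, b) {
  nb <- floor((e - s) / b + 1e-9)
  if (nb < 1L) return(NULL)
  s + (0:nb) * b
}

#' Bin event counts
#'
#' Counts events in regular bins of `bin_size` seconds. Within each interval
#' of `ep` (default: the object's time support), bins tile from the interval
#' start; only complete bins are kept and bins are half-open `[left, right)`
#' so an event is counted exactly once. Output times are bin centers and the
#' output support is `ep`.
#'
#' @param x A `ts_events` or an `event_group`.
#' @param bin_size Bin width in seconds (> 0).
#' @param ep Optional [epoch_set] over which to count.
#' @param ... Unused.
#' @return A `ts_signal` of counts (or a `ts_frame`, one column per unit,
#'   for an `event_group`).
#' @export
count <- function(x, bin_size, ep = NULL, ...) UseMethod("count")

#' @export
count.ts_events <- function(x, bin_size, ep = NULL, ...) {
  if (!is.numeric(bin_size) || bin_size <= 0) stop("'bin_size' must be > 0")
  if (is.null(ep)) ep <- x$time_support
  centers <- numeric(0); counts <- numeric(0)
  for (i in seq_len(n_intervals(ep))) {
    edges <- full_bin_edges(ep$start[i], ep$end[i], bin_size)
    if (is.null(edges)) next
    nb <- length(edges) - 1L
    t <- x$times[x$times >= ep$start[i] & x$times <= ep$end[i]]
    k <- findInterval(t, edges)
    k <- k[k >= 1L & k <= nb & t < edges[nb + 1L]]
    centers <- c(centers, ep$start[i] + (seq_len(nb) - 0.5) * bin_size)
    counts <- c(counts, tabulate(k, nbins = nb))
  }
  ts_signal(centers, counts, time_support = ep)
}

#' Threshold a sampled signal
#'
#' Keeps the samples strictly above (or below) `level`. The result's time
#' support is rebuilt from the data: one interval per maximal run of
#' consecutive qualifying samples, spanning from the first to the last
#' sample time of the run (no interpolation of crossing times).
#'
#' @param x A `ts_signal`.
#' @param level Threshold value.
#' @param mode `"above"` or `"below"`; comparison is strict.
#' @return A `ts_signal`; empty (with empty support) if no sample qualifies.
#' @export
threshold <- function(x, level, mode = c("above", "below")) {
  mode <- match.arg(mode)
  if (!inherits(x, "ts_signal")) stop("'x' must be a ts_signal")
  if (length(x) == 0L) stop("'x' must be non-empty")
  keep <- if (mode == "above") x$values > level else x$values < level
  idx <- which(keep)
  if (length(idx) == 0L) {
    return(ts_signal(numeric(0), numeric(0),
                     time_support = epoch_set(numeric(0), numeric(0))))
  }
  run_start <- idx[c(TRUE, diff(idx) > 1L)]
  run_end <- idx[c(diff(idx) > 1L, TRUE)]
  sup <- ep_intersect(
    epoch_set(x$times[run_start], x$times[run_end]), x$time_support)
  ts_signal(x$times[idx], x$values[idx], time_support = sup)
}

#' Event rate over a set of epochs
#'
#' The number of events divided by the duration of the (intersected) time
#' support: `n_events / total_duration(time_support(x) ∩ ep)`.
#'
#' @param x A `ts_events`.
#' @param ep Optional [epoch_set]; defaults to the object's own support.
#' @return Rate in events per second.
#' @export
event_rate <- function(x, ep = NULL) {
  sup <- if (is.null(ep)) x$time_support else ep_intersect(x$time_support, ep)
  dur <- total_duration(sup)
  if (dur <= 0) stop("time support has zero duration; rate is undefined")
  sum(in_epochs(sup, x$times)) / dur
}

# rate that maps a zero-duration support to 0 (used for group metadata)
event_rate0 <- function(x, warn = TRUE) {
  dur <- total_duration(x$time_support)
  if (dur <= 0) {
    if (warn) warning("zero-duration time support; rate set to 0")
    return(0)
  }
  length(x$times) / dur
}
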