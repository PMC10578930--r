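#' Epoch sets: collections of time intervals
#'
#' An `epoch_set` represents "when data is valid" or "when a condition
#' holds": a sorted collection of closed time intervals `[start, end]` in
#' seconds, with an optional per-interval label (e.g. a trial condition).
#' Construction normalizes the input: intervals are sorted by start and any
#' overlapping or abutting intervals are merged, so a shared endpoint is
#' never ambiguous. A merged interval inherits the label of its earliest
#' constituent.
#'
#' All times inside the package are stored in seconds; `time_units` only
#' rescales the input at construction (`"s"`, `"ms"` or `"us"`).
#'
#' @param start,end Numeric vectors of equal length; `end[i] >= start[i]`.
#' @param labels Optional vector, one entry per interval.
#' @param time_units Unit of the input times: `"s"` (default), `"ms"`, `"us"`.
#' @return An object of class `epoch_set` with fields `start`, `end` and
#'   optionally `label`.
#' @examples
#' ep <- epoch_set(c(0, 5), c(10, 15))   # overlap -> single [0, 15]
#' n_intervals(ep)
#' total_duration(ep)
#' @export
epoch_set <- function(start, end, labels = NULL, time_units = "s") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(start) != length(end)) {
    stop("'start' and 'end' must have the same length (", length(start),
         " vs ", length(end), ")")
  }
  if (!is.null(labels) && length(labels) != length(start)) {
    stop("'labels' must have one entry per interval")
  }
  if (anyNA(start) || anyNA(end)) stop("interval endpoints must not be NA")
  sc <- time_unit_scale(time_units)
  start <- start / sc
  end <- end / sc
  bad <- which(end < start)
  if (length(bad)) {
    stop("end < start at interval ", bad[1], " (start = ", start[bad[1]],
         ", end = ", end[bad[1]], ")")
  }
  o <- order(start)
  start <- start[o]; end <- end[o]
  if (!is.null(labels)) labels <- labels[o]
  # merge overlapping or abutting intervals; keep the earliest label
  n <- length(start)
  if (n > 1L) {
    ms <- numeric(n); me <- numeric(n); mi <- integer(n)
    k <- 1L; ms[1] <- start[1]; me[1] <- end[1]; mi[1] <- 1L
    for (i in 2:n) {
      if (start[i] <= me[k]) {
        me[k] <- max(me[k], end[i])
      } else {
        k <- k + 1L
        ms[k] <- start[i]; me[k] <- end[i]; mi[k] <- i
      }
    }
    start <- ms[seq_len(k)]; end <- me[seq_len(k)]
    if (!is.null(labels)) labels <- labels[mi[seq_len(k)]]
  }
  out <- list(start = start, end = end)
  if (!is.null(labels)) out$label <- labels
  class(out) <- "epoch_set"
  out
}

time_unit_scale <- function(units) {
  switch(match.arg(units, c("s", "ms", "us")), s = 1, ms = 1e3, us = 1e6)
}

#' @rdname epoch_set
#' @param ep An `epoch_set`.
#' @export
n_intervals <- function(ep) length(ep$start)

#' @rdname epoch_set
#' @export
total_duration <- function(ep) sum(ep$end - ep$start)

#' Closed-interval membership
#'
#' Tests which times fall inside an epoch set; both interval endpoints are
#' included.
#'
#' @param ep An `epoch_set`.
#' @param t Numeric vector of times (seconds).
#' @return Logical vector, same length as `t`.
#' @export
in_epochs <- function(ep, t) {
  if (n_intervals(ep) == 0L || length(t) == 0L) return(logical(length(t)))
  idx <- findInterval(t, ep$start)
  idx >= 1L & t <= ep$end[pmax(idx, 1L)]
}

#' Interval algebra on epoch sets
#'
#' Set operations returning normalized `epoch_set` objects. `ep_intersect`
#' covers the times in both inputs, `ep_union` the times in either, and
#' `ep_setdiff` the times in `a` not interior to `b` (the endpoints of a
#' removed region stay in the result as closed endpoints; zero-length
#' leftovers are dropped, so `ep_setdiff(a, a)` is empty). Labels are not
#' propagated through set operations.
#'
#' @param a,b `epoch_set` objects.
#' @return An `epoch_set`.
#' @examples
#' a <- epoch_set(c(0, 20), c(10, 30))
#' b <- epoch_set(5, 25)
#' ep_intersect(a, b)  # [5,10] and [20,25]
#' @export
ep_intersect <- function(a, b) {
  na <- n_intervals(a); nb <- n_intervals(b)
  if (na == 0L || nb == 0L) return(epoch_set(numeric(0), numeric(0)))
  rs <- numeric(0); re <- numeric(0)
  i <- 1L; j <- 1L
  while (i <= na && j <= nb) {
    lo <- max(a$start[i], b$start[j])
    hi <- min(a$end[i], b$end[j])
    if (hi >= lo) { rs <- c(rs, lo); re <- c(re, hi) }
    if (a$end[i] < b$end[j]) i <- i + 1L else j <- j + 1L
  }
  epoch_set(rs, re)
}

#' @rdname ep_intersect
#' @export
ep_union <- function(a, b) {
  epoch_set(c(a$start, b$start), c(a$end, b$end))
}

#' @rdname ep_intersect
#' @export
ep_setdiff <- function(a, b) {
  if (n_intervals(a) == 0L) return(epoch_set(numeric(0), numeric(0)))
  if (n_intervals(b) == 0L) return(epoch_set(a$start, a$end, a$label))
  rs <- numeric(0); re <- numeric(0)
  for (i in seq_len(n_intervals(a))) {
    cur <- a$start[i]; e <- a$end[i]
    ov <- which(b$end > cur & b$start < e)
    for (j in ov) {
      if (b$start[j] > cur) { rs <- c(rs, cur); re <- c(re, b$start[j]) }
      cur <- max(cur, b$end[j])
    }
    if (cur < e) { rs <- c(rs, cur); re <- c(re, e) }
  }
  epoch_set(rs, re)
}

#' Filter or merge intervals by duration and gap
#'
#' `drop_short_intervals` keeps intervals whose duration is at least
#' `min_dur`; `drop_long_intervals` keeps those at most `max_dur`;
#' `merge_close_intervals` merges consecutive intervals whose gap is at most
#' `max_gap`, applied transitively.
#'
#' @param ep An `epoch_set`.
#' @param min_dur,max_dur,max_gap Non-negative durations in seconds.
#' @return An `epoch_set`.
#' @export
drop_short_intervals <- function(ep, min_dur) {
  if (min_dur < 0) stop("'min_dur' must be non-negative")
  keep <- (ep$end - ep$start) >= min_dur
  epoch_set(ep$start[keep], ep$end[keep], ep$label[keep])
}

#' @rdname drop_short_intervals
#' @export
drop_long_intervals <- function(ep, max_dur) {
  if (max_dur < 0) stop("'max_dur' must be non-negative")
  keep <- (ep$end - ep$start) <= max_dur
  epoch_set(ep$start[keep], ep$end[keep], ep$label[keep])
}

#' @rdname drop_short_intervals
#' @export
merge_close_intervals <- function(ep, max_gap) {
  if (max_gap < 0) stop("'max_gap' must be non-negative")
  n <- n_intervals(ep)
  if (n <= 1L) return(ep)
  # single left-to-right pass is transitive on sorted disjoint intervals
  ms <- numeric(n); me <- numeric(n); mi <- integer(n)
  k <- 1L; ms[1] <- ep$start[1]; me[1] <- ep$end[1]; mi[1] <- 1L
  for (i in 2:n) {
    # compare as start <= end + gap: no subtraction, so representable
    # endpoint/gap combinations (e.g. 2.6 vs 2 + 0.6) merge as expected
    if (ep$start[i] <= me[k] + max_gap) {
      me[k] <- max(me[k], ep$end[i])
    } else {
      k <- k + 1L; ms[k] <- ep$start[i]; me[k] <- ep$end[i]; mi[k] <- i
    }
  }
  epoch_set(ms[seq_len(k)], me[seq_len(k)], ep$label[mi[seq_len(k)]])
}

#' @export
print.epoch_set <- function(x, ...) {
  cat("epoch_set with", n_intervals(x), "interval(s), total duration",
      format(total_duration(x)), "s\n")
  if (n_intervals(x) > 0L) print(utils::head(as.data.frame(x), 10L))
  if (n_intervals(x) > 10L) cat("... (", n_intervals(x) - 10L, " more)\n")
  invisible(x)
}

#' @export
as.data.frame.epoch_set <- function(x, ...) {
  d <- data.frame(start = x$start, end = x$end)
  if (!is.null(x$label)) d$label <- x$label
  d
}

validate_epoch_set <- function(ep, name = "epoch_set") {
  ok <- is.list(ep) && is.numeric(ep$start) && is.numeric(ep$end) &&
    length(ep$start) == length(ep$end) &&
    !anyNA(ep$start) && !anyNA(ep$end) &&
    all(ep$end >= ep$start) &&
    (length(ep$start) <= 1L ||
       (all(diff(ep$start) > 0) && all(ep$start[-1] > ep$end[-length(ep$end)])))
  if (!is.null(ep$label) && length(ep$label) != length(ep$start)) ok <- FALSE
  if (!ok) stop("invalid epoch_set in '", name,
                "': intervals must be sorted, disjoint and non-abutting")
  invisible(TRUE)
}
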