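#' Grouped event series with shared time support and metadata
#'
#' An `event_group` collects several [ts_events] series (typically
#' simultaneously recorded spike trains) under integer unit ids. All
#' members share one time support; each keeps its own timestamps. A
#' metadata table keyed by unit id always carries a `rate` column
#' (events/s over the shared support), recomputed automatically whenever
#' the support changes and never user-writable.
#'
#' If no `time_support` is given, the support is the single interval
#' spanning the first and last event over all members (explicit supports
#' are recommended: the true observation epoch usually extends beyond the
#' first and last event).
#'
#' @param units Named list of [ts_events] (or bare numeric time vectors);
#'   names must be unique non-negative integers.
#' @param time_support Optional [epoch_set] shared by all members; members
#'   are restricted to it.
#' @return An object of class `event_group` with fields `units`,
#'   `time_support` and `metadata` (a data frame with columns `unit_id`,
#'   `rate`, ...).
#' @examples
#' g <- event_group(list(`1` = c(0.1, 0.3, 2), `2` = c(1, 4)),
#'                  time_support = epoch_set(0, 5))
#' group_metadata(g)$rate
#' @export
event_group <- function(units, time_support = NULL) {
  if (!is.list(units) || length(units) == 0L) {
    stop("'units' must be a non-empty list")
  }
  ids <- names(units)
  if (is.null(ids)) stop("'units' must be named by integer unit ids")
  idn <- suppressWarnings(as.integer(ids))
  if (anyNA(idn) || any(idn < 0L)) {
    stop("unit ids must be non-negative integers")
  }
  if (anyDuplicated(idn)) stop("duplicate unit ids")
  units <- lapply(units, function(u) {
    if (inherits(u, "ts_events")) u else ts_events(u)
  })
  if (is.null(time_support)) {
    first <- unlist(lapply(units, function(u) u$times[1]))
    last <- unlist(lapply(units, function(u) u$times[length(u$times)]))
    if (length(first) == 0L) {
      stop("cannot infer a time support from units with no events; ",
           "provide 'time_support'")
    }
    time_support <- epoch_set(min(first), max(last))
  }
  validate_epoch_set(time_support, "time_support")
  # members adopt the shared support exactly; outside events are dropped
  units <- lapply(units, function(u) {
    ts_events(u$times[in_epochs(time_support, u$times)],
              time_support = time_support)
  })
  o <- order(idn)
  units <- units[o]; idn <- idn[o]
  names(units) <- idn
  g <- structure(list(units = units, time_support = time_support,
                      metadata = data.frame(unit_id = idn)),
                 class = "event_group")
  g$metadata$rate <- vapply(g$units, event_rate0, numeric(1))
  g
}

#' @rdname event_group
#' @param g An `event_group`.
#' @export
unit_ids <- function(g) g$metadata$unit_id

#' @rdname event_group
#' @export
group_metadata <- function(g) g$metadata

#' @export
length.event_group <- function(x) length(x$units)

#' Extract one unit's event series by id
#' @param x An `event_group`.
#' @param i Unit id (integer).
#' @return A [ts_events].
#' @export
`[[.event_group` <- function(x, i) {
  u <- .subset2(x, "units")[[as.character(i)]]
  if (is.null(u)) stop("no unit with id ", i)
  u
}

#' @export
print.event_group <- function(x, ...) {
  cat("event_group with", length(x), "unit(s) on support of",
      format(total_duration(x$time_support)), "s\n")
  print(x$metadata)
  invisible(x)
}

#' Attach per-unit metadata
#'
#' Adds (or replaces) a metadata column. Values must cover every unit id
#' exactly; the automatic `rate` column cannot be overwritten.
#'
#' @param g An `event_group`.
#' @param name Column name.
#' @param values Named vector or list keyed by unit id.
#' @return The modified `event_group`.
#' @export
set_metadata <- function(g, name, values) {
  if (identical(name, "rate") || identical(name, "unit_id")) {
    stop("'", name, "' is maintained automatically and cannot be set")
  }
  ids <- as.character(unit_ids(g))
  if (is.null(names(values)) || !setequal(names(values), ids) ||
      length(values) != length(ids)) {
    stop("'values' must be named and cover every unit id exactly")
  }
  g$metadata[[name]] <- unlist(values[ids], use.names = FALSE)
  g
}

# subgroup sharing the parent's support; metadata rows carried over,
# member data untouched, rates unchanged
subset_group <- function(g, ids) {
  keep <- unit_ids(g) %in% ids
  g2 <- g
  g2$units <- g$units[as.character(unit_ids(g)[keep])]
  g2$metadata <- g$metadata[keep, , drop = FALSE]
  rownames(g2$metadata) <- NULL
  g2
}

#' Filter an event group by metadata
#'
#' `getby_category` splits the group by the discrete labels of a metadata
#' column and returns one subgroup per label (together they partition the
#' units). `getby_threshold` keeps units whose numeric metadata passes a
#' comparison. `getby_intervals` bins units by a numeric column into
#' half-open bins `[edges[k], edges[k+1])`. Subgroups share the parent's
#' time support and unit ids are never renumbered.
#'
#' @param g An `event_group`.
#' @param column Metadata column name.
#' @param level Threshold value.
#' @param op Comparison operator: one of `">"`, `"<"`, `">="`, `"<="`.
#' @param edges Increasing numeric bin edges.
#' @return `getby_category`: named list of `event_group`s;
#'   `getby_threshold`: an `event_group` (NULL if no unit passes);
#'   `getby_intervals`: list with one entry per bin (NULL for empty bins).
#' @export
getby_category <- function(g, column) {
  v <- metadata_column(g, column)
  labs <- unique(v)
  out <- lapply(labs, function(l) subset_group(g, unit_ids(g)[v == l]))
  names(out) <- as.character(labs)
  out
}

#' @rdname getby_category
#' @export
getby_threshold <- function(g, column, level, op = ">") {
  v <- metadata_column(g, column, numeric = TRUE)
  op <- match.arg(op, c(">", "<", ">=", "<="))
  keep <- do.call(op, list(v, level))
  if (!any(keep)) return(NULL)
  subset_group(g, unit_ids(g)[keep])
}

#' @rdname getby_category
#' @export
getby_intervals <- function(g, column, edges) {
  v <- metadata_column(g, column, numeric = TRUE)
  if (length(edges) < 2L || is.unsorted(edges, strictly = TRUE)) {
    stop("'edges' must be strictly increasing with at least two values")
  }
  k <- findInterval(v, edges)
  k[v >= edges[length(edges)]] <- 0L  # right edge exclusive
  out <- vector("list", length(edges) - 1L)
  for (b in seq_along(out)) {
    ids <- unit_ids(g)[k == b]
    if (length(ids)) out[[b]] <- subset_group(g, ids)
  }
  names(out) <- paste0("[", edges[-length(edges)], ",", edges[-1], ")")
  out
}

metadata_column <- function(g, column, numeric = FALSE) {
  if (!column %in% names(g$metadata)) {
    stop("unknown metadata column '", column, "'")
  }
  v <- g$metadata[[column]]
  if (numeric && !is.numeric(v)) {
    stop("metadata column '", column, "' is not numeric")
  }
  v
}

#' @export
restrict.event_group <- function(x, ep) {
  sup <- ep_intersect(x$time_support, ep)
  x$units <- lapply(x$units, restrict, ep = sup)
  x$time_support <- sup
  warn <- total_duration(sup) <= 0
  x$metadata$rate <- vapply(x$units, event_rate0, numeric(1), warn = FALSE)
  if (warn) warning("zero-duration time support; rates set to 0")
  x
}

#' @export
count.event_group <- function(x, bin_size, ep = NULL, ...) {
  if (is.null(ep)) ep <- x$time_support
  per_unit <- lapply(x$units, count, bin_size = bin_size, ep = ep)
  m <- do.call(cbind, lapply(per_unit, sample_values))
  ts_frame(sample_times(per_unit[[1]]), m,
           columns = as.character(unit_ids(x)), time_support = ep)
}
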