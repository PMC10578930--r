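#' Peri-event alignment of event trains (PSTH)
#'
#' Aligns a target train to each event of a reference train: for reference
#' time `r`, the aligned events are `{t - r : -before <= t - r <= after}`.
#' When `bin_size` is given, a pooled peri-event rate trace is also
#' computed: bins of width `bin_size` tile `[-before, after]` (complete
#' bins only, half-open), and the trace is pooled counts divided by
#' `n_ref * bin_size` — the mean target rate around a reference event.
#'
#' @param target A [ts_events] or an [event_group] (aligned per unit).
#' @param ref A [ts_events] of reference times.
#' @param before,after Window extent in seconds (both >= 0, not both 0).
#' @param bin_size Optional bin width in seconds for the rate trace.
#' @param ... Unused.
#' @return A `peri_event` object with fields `window`, `trials` (list of
#'   aligned-time vectors, one per reference), `reference_times`, and when
#'   `bin_size` is given `rate_lags`/`rate` (bin centers and pooled rate).
#'   For an `event_group`, a named list of `peri_event` objects.
#' @examples
#' refs <- ts_events(c(10, 20), time_support = epoch_set(0, 30))
#' spk <- ts_events(c(10.1, 19.9, 20.1), time_support = epoch_set(0, 30))
#' peri_event(spk, refs, before = 0.5, after = 0.5, bin_size = 0.5)$rate
#' @export
peri_event <- function(target, ref, before, after, bin_size = NULL, ...) {
  UseMethod("peri_event")
}

#' @export
peri_event.ts_events <- function(target, ref, before, after,
                                 bin_size = NULL, ...) {
  check_window(before, after)
  r <- ref$times
  if (length(r) == 0L) stop("'ref' has no events")
  t <- target$times
  i1 <- findInterval(r - before, t, left.open = TRUE) + 1L
  i2 <- findInterval(r + after, t)
  trials <- lapply(seq_along(r), function(j) {
    if (i2[j] >= i1[j]) t[i1[j]:i2[j]] - r[j] else numeric(0)
  })
  out <- list(window = c(before = before, after = after), trials = trials,
              reference_times = r)
  if (!is.null(bin_size)) {
    edges <- full_bin_edges(-before, after, bin_size)
    if (is.null(edges)) stop("'bin_size' larger than the window")
    nb <- length(edges) - 1L
    d <- unlist(trials)
    k <- findInterval(d, edges)
    k <- k[k >= 1L & k <= nb & d < edges[nb + 1L]]
    out$rate_lags <- edges[-1] - bin_size / 2
    out$rate <- tabulate(k, nbins = nb) / (length(r) * bin_size)
  }
  structure(out, class = "peri_event")
}

#' @export
peri_event.event_group <- function(target, ref, before, after,
                                   bin_size = NULL, ...) {
  out <- lapply(target$units, peri_event, ref = ref, before = before,
                after = after, bin_size = bin_size)
  names(out) <- as.character(unit_ids(target))
  out
}

check_window <- function(before, after) {
  if (before < 0 || after < 0) stop("'before' and 'after' must be >= 0")
  if (before == 0 && after == 0) stop("window must have positive extent")
  invisible(TRUE)
}

#' Peri-event alignment of a sampled signal
#'
#' Samples a continuous trace on a shared relative-time grid around each
#' reference event, by nearest-neighbor lookup into the target (no
#' interpolation). References whose full window is not covered by the
#' target's time support are dropped; their number is recorded.
#'
#' @param target A `ts_signal` or `ts_frame`.
#' @param ref A [ts_events] of reference times.
#' @param before,after Window extent in seconds.
#' @param dt Step of the relative-time grid, seconds.
#' @return A `peri_event_continuous` object: `grid` (relative times),
#'   `trials` (references x grid matrix, or per-channel list for a
#'   `ts_frame`), `mean` (trial-mean trace), `reference_times` (kept) and
#'   `n_dropped`.
#' @export
peri_event_continuous <- function(target, ref, before, after, dt) {
  check_window(before, after)
  if (dt <= 0) stop("'dt' must be > 0")
  m <- floor((before + after) / dt + 1e-9)
  grid <- -before + (0:m) * dt
  r <- ref$times
  if (length(r) == 0L) stop("'ref' has no events")
  covered <- vapply(r, function(rj) all(in_epochs(target$time_support,
                                                  rj + grid)), logical(1))
  r <- r[covered]
  if (length(r) == 0L) stop("no reference window is covered by the target support")
  if (length(target$times) == 0L) stop("'target' has no samples")
  idx <- t(vapply(r, function(rj) nearest_index(rj + grid, target$times),
                  integer(length(grid))))
  if (inherits(target, "ts_frame")) {
    trials <- lapply(seq_len(ncol(target$values)), function(cc) {
      matrix(target$values[idx, cc], nrow = length(r))
    })
    names(trials) <- colnames(target$values)
    mean_trace <- vapply(trials, colMeans, numeric(length(grid)))
  } else {
    trials <- matrix(target$values[idx], nrow = length(r))
    mean_trace <- colMeans(trials)
  }
  structure(list(window = c(before = before, after = after), grid = grid,
                 trials = trials, mean = mean_trace, reference_times = r,
                 n_dropped = sum(!covered)),
            class = "peri_event_continuous")
}

#' @export
print.peri_event <- function(x, ...) {
  cat("peri_event: window [-", x$window["before"], ", +", x$window["after"],
      "] s, ", length(x$trials), " reference(s)\n", sep = "")
  invisible(x)
}

#' @export
print.peri_event_continuous <- function(x, ...) {
  cat("peri_event_continuous: window [-", x$window["before"], ", +",
      x$window["after"], "] s, ", length(x$reference_times),
      " reference(s) kept, ", x$n_dropped, " dropped\n", sep = "")
  invisible(x)
}

#' @export
plot.peri_event <- function(x, ...) {
  if (is.null(x$rate)) stop("compute with 'bin_size' to plot a rate trace")
  graphics::plot(x$rate_lags, x$rate, type = "s", xlab = "lag (s)",
                 ylab = "rate (events/s)", ...)
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}
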