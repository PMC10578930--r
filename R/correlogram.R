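#' Auto- and cross-correlograms of event trains
#'
#' A cross-correlogram histograms the time lags from every event of a
#' reference train to the events of a target train, expressing each lag
#' bin as the conditional event rate of the target around a reference
#' event. Lag bins are half-open `[left, right)`, uniform, and laid out so
#' that an odd number of bins spans `[-(K+1/2) b, (K+1/2) b]` with
#' `K = ceiling(window / bin_size)` — one bin is exactly centered at lag 0,
#' which makes the autocorrelogram symmetric.
#'
#' The autocorrelogram is the cross-correlogram of a train with itself with
#' identical-index (zero-lag self) pairs excluded; distinct events sharing
#' a timestamp still count.
#'
#' With `ep`, both trains are restricted first; pairs spanning an epoch gap
#' are still counted if both events survive restriction (no boundary
#' correction).
#'
#' @param ref,target,x [ts_events] trains; `ref` provides the reference
#'   events.
#' @param bin_size Lag bin width in seconds (> 0).
#' @param window Maximum lag of interest in seconds (>= `bin_size`).
#' @param ep Optional [epoch_set].
#' @param norm `"rate"` divides counts by `n_ref * bin_size`, giving the
#'   target rate in events/s conditional on a reference event; `"count"`
#'   returns raw pair counts.
#' @return An object of class `correlogram` with fields `lags` (bin
#'   centers, seconds), `values` (rate or count per bin), `n_reference`,
#'   `bin_size` and `norm`.
#' @examples
#' a <- ts_events(c(10), time_support = epoch_set(0, 20))
#' b <- ts_events(c(9.90, 10.05), time_support = epoch_set(0, 20))
#' cross_correlogram(a, b, bin_size = 0.1, window = 0.2)
#' @export
cross_correlogram <- function(ref, target, bin_size, window, ep = NULL,
                              norm = c("rate", "count")) {
  correlogram_impl(ref, target, bin_size, window, ep, match.arg(norm),
                   exclude_self = FALSE)
}

#' @rdname cross_correlogram
#' @export
auto_correlogram <- function(x, bin_size, window, ep = NULL,
                             norm = c("rate", "count")) {
  correlogram_impl(x, x, bin_size, window, ep, match.arg(norm),
                   exclude_self = TRUE)
}

correlogram_impl <- function(ref, target, bin_size, window, ep, norm,
                             exclude_self) {
  if (!is.numeric(bin_size) || bin_size <= 0) stop("'bin_size' must be > 0")
  if (window < bin_size) stop("'window' must be >= 'bin_size'")
  if (!is.null(ep)) {
    ref <- restrict(ref, ep)
    target <- restrict(target, ep)
  }
  r <- ref$times
  t <- target$times
  if (length(r) == 0L) stop("no reference events (after restriction)")
  K <- ceiling(window / bin_size - 1e-9)
  edges <- ((-K):(K + 1L) - 0.5) * bin_size
  nb <- 2L * K + 1L
  counts <- numeric(nb)
  if (length(t)) {
    lo <- r + edges[1]
    hi <- r + edges[nb + 1L]
    i1 <- findInterval(lo, t, left.open = TRUE) + 1L  # first t >= lo
    i2 <- findInterval(hi, t)                          # last t <= hi
    len <- pmax(i2 - i1 + 1L, 0L)
    if (sum(len) > 0) {
      tidx <- sequence(len, from = i1)
      ridx <- rep.int(seq_along(r), len)
      if (exclude_self) {
        keep <- tidx != ridx
        tidx <- tidx[keep]; ridx <- ridx[keep]
      }
      d <- t[tidx] - r[ridx]
      k <- findInterval(d, edges)          # left-closed bins
      k <- k[k >= 1L & k <= nb & d < edges[nb + 1L]]
      counts <- tabulate(k, nbins = nb)
    }
  }
  values <- if (norm == "rate") counts / (length(r) * bin_size) else counts
  structure(list(lags = ((-K):K) * bin_size, values = values,
                 n_reference = length(r), bin_size = bin_size, norm = norm),
            class = "correlogram")
}

#' @export
print.correlogram <- function(x, ...) {
  cat("correlogram (", x$norm, "): ", length(x$lags), " lag bins spanning ",
      format(x$lags[1] - x$bin_size / 2), " to ",
      format(x$lags[length(x$lags)] + x$bin_size / 2), " s, ",
      x$n_reference, " reference event(s)\n", sep = "")
  invisible(x)
}

#' @export
plot.correlogram <- function(x, ...) {
  graphics::barplot(x$values, names.arg = signif(x$lags, 3), space = 0,
                    xlab = "lag (s)",
                    ylab = if (x$norm == "rate") "rate (events/s)" else "count",
                    ...)
  invisible(x)
}
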