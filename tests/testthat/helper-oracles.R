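# Independent brute-force oracles used across the suite. These deliberately
# use naive nested-loop / dense-mask logic, not the package's algorithms.

# random epoch set with endpoints on a 1 ms lattice over [0, hi] seconds
random_lattice_epochs <- function(n_max = 8, hi = 100) {
  n <- sample.int(n_max, 1)
  pts <- sort(sample(0:(hi * 1000), 2 * n)) / 1000
  epoch_set(pts[seq(1, 2 * n, 2)], pts[seq(2, 2 * n, 2)])
}

# probe times at half-lattice offsets: never on an interval endpoint, so
# closed-vs-open boundary conventions are invisible to the comparison
lattice_probes <- function(hi = 100) (0:(hi * 1000 - 1)) / 1000 + 0.0005

# membership of probe points, by direct per-interval scan
probe_mask <- function(ep, probes) {
  m <- rep(FALSE, length(probes))
  for (i in seq_along(ep$start)) {
    m <- m | (probes >= ep$start[i] & probes <= ep$end[i])
  }
  m
}

probe_mask_times <- probe_mask  # same scan, arbitrary query times

# brute-force nearest neighbor with earlier-sample tie break
brute_nearest <- function(tt, st) {
  vapply(tt, function(t) {
    d <- abs(st - t)
    which(d == min(d))[1]
  }, integer(1))
}

# brute-force full-bin histogram over one interval
brute_count_interval <- function(times, s, e, b) {
  nb <- floor((e - s) / b + 1e-9)
  cnt <- integer(nb)
  for (k in seq_len(nb)) {
    l <- s + (k - 1) * b
    r <- s + k * b
    cnt[k] <- sum(times >= l & times < r)
  }
  cnt
}

# brute-force pairwise-difference correlogram counts
brute_xcorr_counts <- function(r, t, b, K, exclude_self = FALSE) {
  cnt <- numeric(2 * K + 1)
  for (i in seq_along(r)) {
    for (j in seq_along(t)) {
      if (exclude_self && i == j) next
      d <- t[j] - r[i]
      for (k in seq_len(2 * K + 1)) {
        l <- (k - K - 1.5) * b   # left edge of bin centered at (k-K-1)*b
        if (d >= l && d < l + b) cnt[k] <- cnt[k] + 1
      }
    }
  }
  cnt
}

# brute-force peri-event pooled counts on bins tiling [-before, after]
brute_psth_counts <- function(tgt, refs, before, after, b) {
  nb <- floor((before + after) / b + 1e-9)
  cnt <- numeric(nb)
  for (r in refs) {
    for (t in tgt) {
      d <- t - r
      for (k in seq_len(nb)) {
        l <- -before + (k - 1) * b
        if (d >= l && d < l + b) cnt[k] <- cnt[k] + 1
      }
    }
  }
  cnt
}

random_events <- function(n, lo = 0, hi = 100) {
  ts_events(sort(stats::runif(n, lo, hi)), time_support = epoch_set(lo, hi))
}
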