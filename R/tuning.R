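#' Tuning curve objects
#'
#' Container for occupancy-normalized tuning curves returned by
#' [tuning_1d()], [tuning_2d()] and [tuning_continuous()]. `rates` holds
#' events/s per feature bin per unit (or the mean trace value for the
#' continuous variant); `occupancy` holds seconds spent per bin. Bins that
#' were never visited are `NA`, not 0 — "never sampled" is not "silent".
#'
#' @param bin_centers Numeric vector of feature-bin centers (1D), or a list
#'   of two axes (2D).
#' @param rates Matrix of rates, bins x units (1D), or a 3-d array
#'   `nx x ny x units` (2D).
#' @param occupancy Seconds per bin (vector or matrix matching the bins).
#' @param unit_ids Integer unit ids (or channel names).
#' @param kind `"rate"` for event-rate curves, `"mean"` for continuous-trace
#'   means.
#' @param circular Whether the feature is an angle on `[0, 2*pi)`.
#' @return An object of class `tuning_curve`.
#' @export
tuning_curve <- function(bin_centers, rates, occupancy, unit_ids,
                         kind = "rate", circular = FALSE) {
  structure(list(bin_centers = bin_centers, rates = rates,
                 occupancy = occupancy, unit_ids = unit_ids,
                 kind = kind, circular = circular),
            class = "tuning_curve")
}

#' @export
print.tuning_curve <- function(x, ...) {
  nb <- if (is.list(x$bin_centers)) {
    paste(lengths(x$bin_centers), collapse = " x ")
  } else {
    length(x$bin_centers)
  }
  cat("tuning_curve (", x$kind, "): ", nb, " bins x ",
      length(x$unit_ids), " unit(s)", if (x$circular) ", circular", "\n",
      sep = "")
  invisible(x)
}

#' @export
plot.tuning_curve <- function(x, ...) {
  if (is.list(x$bin_centers)) {
    graphics::image(x$bin_centers[[1]], x$bin_centers[[2]],
                    x$rates[, , 1], xlab = "feature 1", ylab = "feature 2",
                    main = paste("unit", x$unit_ids[1]), ...)
  } else {
    graphics::matplot(x$bin_centers, x$rates, type = "l", lty = 1,
                      xlab = "feature", ylab = x$kind, ...)
  }
  invisible(x)
}

#' Preferred feature value of each unit
#'
#' For a linear feature, the bin center at each unit's maximum rate (ties:
#' first bin). For a circular feature, the baseline-subtracted rate-weighted
#' circular mean of the bin centers (the population-vector estimate that is
#' standard for head-direction preferred directions) — unlike the raw
#' argmax, it is not quantized to the bin grid.
#'
#' @param tc A [tuning_curve] (1D).
#' @return Named numeric vector, one entry per unit.
#' @export
preferred_feature <- function(tc) {
  stopifnot(!is.list(tc$bin_centers))
  out <- apply(tc$rates, 2, function(r) {
    if (tc$circular) {
      w <- r - min(r, na.rm = TRUE)
      w[is.na(w)] <- 0
      atan2(sum(w * sin(tc$bin_centers)),
            sum(w * cos(tc$bin_centers))) %% (2 * pi)
    } else {
      tc$bin_centers[which.max(r)]
    }
  })
  names(out) <- tc$unit_ids
  out
}

#' Firing rate per discrete condition
#'
#' Rate of every unit restricted to each labelled condition epoch, e.g.
#' stimulus ON/OFF.
#'
#' @param g An [event_group].
#' @param conditions Named list of [epoch_set]s, each with positive
#'   duration after intersection with the group support.
#' @return Matrix of rates, conditions x units.
#' @export
tuning_discrete <- function(g, conditions) {
  if (is.null(names(conditions))) stop("'conditions' must be named")
  out <- matrix(NA_real_, length(conditions), length(g),
                dimnames = list(names(conditions),
                                as.character(unit_ids(g))))
  for (ci in seq_along(conditions)) {
    ep <- conditions[[ci]]
    if (total_duration(ep_intersect(g$time_support, ep)) <= 0) {
      stop("condition '", names(conditions)[ci], "' has zero duration")
    }
    out[ci, ] <- vapply(g$units, function(u) event_rate(u, ep), numeric(1))
  }
  out
}

# common binning machinery: half-open bins, top edge closed for linear
# features so the range maximum is not lost
feature_bin <- function(v, edges, circular) {
  nb <- length(edges) - 1L
  k <- findInterval(v, edges, rightmost.closed = !circular)
  k[k < 1L | k > nb] <- NA_integer_
  k
}

resolve_range <- function(range, v, circular) {
  if (!is.null(range)) return(as.numeric(range))
  if (circular) c(0, 2 * pi) else range(v)
}

#' Occupancy-normalized 1D tuning curve
#'
#' Firing rate of each unit as a function of a continuously sampled feature
#' (position, head direction, speed, ...). The feature's visits to each bin
#' are converted to occupancy time by weighting each feature sample with the
#' median sampling interval (`occupancy_dt` overrides this); each spike is
#' assigned the feature value at its nearest feature sample (see
#' [value_from()]); the curve is spike count divided by occupancy. Bins with
#' zero occupancy are `NA`.
#'
#' @param g An [event_group].
#' @param feature A `ts_signal` sampled quasi-regularly.
#' @param nb_bins Number of feature bins (>= 1).
#' @param range Optional `c(lo, hi)` feature range; defaults to the data
#'   range, or `c(0, 2*pi)` when `circular`.
#' @param ep Optional [epoch_set]; defaults to the intersection of the group
#'   and feature supports.
#' @param circular If `TRUE`, feature values are wrapped to `[0, 2*pi)`.
#' @param occupancy_dt Optional occupancy weight per feature sample
#'   (seconds); defaults to the median sampling interval.
#' @return A [tuning_curve].
#' @export
tuning_1d <- function(g, feature, nb_bins, range = NULL, ep = NULL,
                      circular = FALSE, occupancy_dt = NULL) {
  stopifnot(nb_bins >= 1)
  if (is.null(ep)) ep <- ep_intersect(g$time_support, feature$time_support)
  feat <- restrict(feature, ep)
  if (length(feat) == 0L) stop("no feature samples on the analysis epochs")
  fv <- if (circular) feat$values %% (2 * pi) else feat$values
  rng <- resolve_range(range, fv, circular)
  edges <- seq(rng[1], rng[2], length.out = nb_bins + 1)
  dt <- if (is.null(occupancy_dt)) stats::median(diff(feat$times)) else occupancy_dt
  occ <- tabulate(feature_bin(fv, edges, circular), nbins = nb_bins) * dt
  if (all(occ == 0)) stop("zero occupancy in every bin")
  rates <- matrix(NA_real_, nb_bins, length(g))
  feat_wrapped <- ts_signal(feat$times, fv, time_support = feat$time_support)
  for (ui in seq_along(g$units)) {
    u <- restrict(g$units[[ui]], ep)
    if (length(u) == 0L) {
      cnt <- numeric(nb_bins)
    } else {
      sv <- value_from(u, feat_wrapped)$values
      cnt <- tabulate(feature_bin(sv, edges, circular), nbins = nb_bins)
    }
    rates[, ui] <- ifelse(occ > 0, cnt / occ, NA_real_)
  }
  colnames(rates) <- as.character(unit_ids(g))
  tuning_curve(edges[-1] - diff(edges) / 2, rates, occ, unit_ids(g),
               kind = "rate", circular = circular)
}

#' Occupancy-normalized 2D tuning curve
#'
#' As [tuning_1d()] with product binning over the two channels of
#' `features` (e.g. x/y position for place fields).
#'
#' @param g An [event_group].
#' @param features A `ts_frame` with exactly two columns.
#' @param nb_bins Bins per axis; length 1 (shared) or 2.
#' @param ranges Optional list of two `c(lo, hi)` ranges.
#' @param ep Optional [epoch_set].
#' @param occupancy_dt As in [tuning_1d()].
#' @return A [tuning_curve] whose `rates` is an `nx x ny x units` array.
#' @export
tuning_2d <- function(g, features, nb_bins, ranges = NULL, ep = NULL,
                      occupancy_dt = NULL) {
  if (!inherits(features, "ts_frame") || ncol(features$values) != 2L) {
    stop("'features' must be a ts_frame with exactly 2 columns")
  }
  nb <- rep_len(nb_bins, 2L)
  if (is.null(ep)) ep <- ep_intersect(g$time_support, features$time_support)
  feat <- restrict(features, ep)
  if (length(feat) == 0L) stop("no feature samples on the analysis epochs")
  rng <- list(
    if (is.null(ranges)) range(feat$values[, 1]) else as.numeric(ranges[[1]]),
    if (is.null(ranges)) range(feat$values[, 2]) else as.numeric(ranges[[2]]))
  edges <- lapply(1:2, function(a) seq(rng[[a]][1], rng[[a]][2],
                                       length.out = nb[a] + 1))
  dt <- if (is.null(occupancy_dt)) stats::median(diff(feat$times)) else occupancy_dt
  kx <- feature_bin(feat$values[, 1], edges[[1]], FALSE)
  ky <- feature_bin(feat$values[, 2], edges[[2]], FALSE)
  cell <- (ky - 1L) * nb[1] + kx
  occ <- matrix(tabulate(cell, nbins = nb[1] * nb[2]), nb[1], nb[2]) * dt
  if (all(occ == 0)) stop("zero occupancy in every bin")
  rates <- array(NA_real_, c(nb[1], nb[2], length(g)))
  for (ui in seq_along(g$units)) {
    u <- restrict(g$units[[ui]], ep)
    if (length(u) == 0L) {
      cnt <- matrix(0, nb[1], nb[2])
    } else {
      sv <- value_from(u, feat)$values
      skx <- feature_bin(sv[, 1], edges[[1]], FALSE)
      sky <- feature_bin(sv[, 2], edges[[2]], FALSE)
      cnt <- matrix(tabulate((sky - 1L) * nb[1] + skx, nbins = nb[1] * nb[2]),
                    nb[1], nb[2])
    }
    rates[, , ui] <- ifelse(occ > 0, cnt / occ, NA_real_)
  }
  centers <- lapply(edges, function(e) e[-1] - diff(e) / 2)
  tuning_curve(centers, rates, occ, unit_ids(g), kind = "rate")
}

#' Tuning of a continuous trace with respect to a feature
#'
#' For continuous signals (calcium fluorescence, membrane potential) where
#' event counting does not apply: each value sample is assigned to the
#' feature bin of its nearest feature sample, and each bin reports the mean
#' of its assigned values. Bins with no assigned samples are `NA`.
#'
#' @param values A `ts_signal` or `ts_frame` (the trace(s)).
#' @param feature A `ts_signal`.
#' @param nb_bins Number of feature bins.
#' @param range Optional feature range.
#' @param ep Optional [epoch_set].
#' @param circular Wrap the feature to `[0, 2*pi)`.
#' @return A [tuning_curve] with `kind = "mean"`; `occupancy` counts the
#'   assigned value samples times the value-series median sampling interval.
#' @export
tuning_continuous <- function(values, feature, nb_bins, range = NULL,
                              ep = NULL, circular = FALSE) {
  if (is.null(ep)) ep <- ep_intersect(values$time_support, feature$time_support)
  val <- restrict(values, ep)
  feat <- restrict(feature, ep)
  if (length(val) == 0L || length(feat) == 0L) {
    stop("'values' and 'feature' do not overlap in time on the analysis epochs")
  }
  fv <- if (circular) feat$values %% (2 * pi) else feat$values
  rng <- resolve_range(range, fv, circular)
  edges <- seq(rng[1], rng[2], length.out = nb_bins + 1)
  k <- feature_bin(fv[nearest_index(val$times, feat$times)], edges, circular)
  vmat <- if (inherits(val, "ts_frame")) val$values else
    matrix(val$values, ncol = 1, dimnames = list(NULL, "value"))
  means <- matrix(NA_real_, nb_bins, ncol(vmat))
  for (b in seq_len(nb_bins)) {
    rows <- which(k == b)
    if (length(rows)) means[b, ] <- colMeans(vmat[rows, , drop = FALSE])
  }
  colnames(means) <- colnames(vmat)
  dt <- if (length(val) > 1L) stats::median(diff(val$times)) else 1
  occ <- tabulate(k, nbins = nb_bins) * dt
  tuning_curve(edges[-1] - diff(edges) / 2, means, occ, colnames(vmat),
               kind = "mean", circular = circular)
}
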