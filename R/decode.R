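#' Bayesian population decoding of a 1D feature
#'
#' Decodes a feature value (e.g. head direction or linearized position)
#' from population spike counts, assuming Poisson spiking conditioned on
#' the feature (Zhang et al. 1998 style). For each decoding window of
#' length `bin_size` with count vector `n` over units `i` and candidate
#' feature bin `x` with tuning rates `f_i(x)`:
#'
#' \deqn{\log P(x | n) = \log P(x) + \sum_i [ n_i \log f_i(x) - \tau f_i(x) ] + C}
#'
#' computed in log space and normalized per window. Tuning rates are
#' floored at `1e-12` events/s so zero-rate bins stay in the state space
#' with near-zero likelihood; bins with undefined tuning (zero occupancy,
#' `NA` rate) are removed from the state space entirely.
#'
#' @param tc A [tuning_curve] (1D, `kind = "rate"`) for the decoded units.
#' @param g The [event_group] providing the spike trains; must contain
#'   every unit of `tc`.
#' @param bin_size Decoding window in seconds.
#' @param ep [epoch_set] over which to decode.
#' @param prior `"uniform"` (default) or `"occupancy"` (proportional to the
#'   tuning curve's occupancy).
#' @return An object of class `decoded_trajectory` with fields `times`
#'   (window centers), `posterior` (windows x feature bins, rows sum to 1),
#'   `map_estimate` (bin center of the posterior maximum per window),
#'   `bin_centers` and `unit_ids`.
#' @examples
#' # two-state, one-unit closed-form check: f = (10, 1) Hz, tau = 1 s
#' tc <- tuning_curve(c(0.5, 1.5), matrix(c(10, 1), 2, 1),
#'                    occupancy = c(1, 1), unit_ids = 1L)
#' g <- event_group(list(`1` = seq(0.05, 0.95, length.out = 8)),
#'                  time_support = epoch_set(0, 1))
#' decode_bayes_1d(tc, g, 1, epoch_set(0, 1))$map_estimate  # 0.5: 10 Hz wins
#' @export
decode_bayes_1d <- function(tc, g, bin_size, ep,
                            prior = c("uniform", "occupancy")) {
  prior <- match.arg(prior)
  if (is.list(tc$bin_centers)) stop("'tc' must be a 1D tuning curve")
  ids <- as.character(tc$unit_ids)
  if (!all(ids %in% as.character(unit_ids(g)))) {
    stop("every unit of the tuning curve must be present in the group")
  }
  valid <- tc$occupancy > 0 & apply(is.finite(tc$rates), 1, all)
  if (!any(valid)) stop("tuning curve has no defined bins")
  f <- pmax(tc$rates[valid, , drop = FALSE], 1e-12)
  centers <- tc$bin_centers[valid]
  lp <- if (prior == "uniform") {
    rep(0, sum(valid))
  } else {
    log(tc$occupancy[valid] / sum(tc$occupancy[valid]))
  }
  cnt <- count(g, bin_size, ep)
  n <- cnt$values[, ids, drop = FALSE]
  # windows x bins: n %*% log f' - tau * sum_i f_i(x) + log prior
  ll <- n %*% t(log(f))
  ll <- sweep(ll, 2, bin_size * rowSums(f) - lp, "-")
  mx <- apply(ll, 1, max)
  post <- exp(ll - mx)
  post <- post / rowSums(post)
  structure(list(times = cnt$times,
                 posterior = post,
                 map_estimate = centers[max.col(post, ties.method = "first")],
                 bin_centers = centers,
                 unit_ids = tc$unit_ids),
            class = "decoded_trajectory")
}

#' @export
print.decoded_trajectory <- function(x, ...) {
  cat("decoded_trajectory:", length(x$times), "window(s),",
      length(x$bin_centers), "feature bin(s),", length(x$unit_ids),
      "unit(s)\n")
  invisible(x)
}

#' Circular distance between angles
#'
#' Absolute angular difference wrapped to `[0, pi]`; the natural error
#' metric for circular features such as head direction.
#'
#' @param a,b Angles in radians.
#' @return Absolute circular distance, in radians.
#' @export
circ_dist <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  pmin(d, 2 * pi - d)
}
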