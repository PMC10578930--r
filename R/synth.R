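#' Von Mises tuning profile for simulated head-direction cells
#'
#' Describes a circular tuning curve
#' `f(theta) = r_base + (r_max - r_base) * exp(kappa * (cos(theta - mu) - 1))`,
#' which peaks at `f(mu) = r_max`, decays towards `r_base` away from the
#' preferred direction, and is non-negative everywhere.
#'
#' @param mu Preferred direction, radians.
#' @param kappa Concentration (>= 0); `kappa = 0` gives a flat profile at
#'   `r_max`.
#' @param r_max Peak rate, events/s.
#' @param r_base Baseline rate, events/s (`0 <= r_base <= r_max`).
#' @return An object of class `von_mises_tuning`.
#' @export
von_mises_tuning <- function(mu, kappa, r_max, r_base = 0.5) {
  stopifnot(kappa >= 0, r_max >= 0, r_base >= 0, r_base <= r_max)
  structure(list(mu = mu %% (2 * pi), kappa = kappa, r_max = r_max,
                 r_base = r_base), class = "von_mises_tuning")
}

#' @rdname von_mises_tuning
#' @param vmt A `von_mises_tuning`.
#' @param theta Angles, radians.
#' @return `tuning_rate` returns the rate `f(theta)` in events/s.
#' @export
tuning_rate <- function(vmt, theta) {
  vmt$r_base + (vmt$r_max - vmt$r_base) *
    exp(vmt$kappa * (cos(theta - vmt$mu) - 1))
}

#' Simulate a head-direction trajectory
#'
#' A wrapped Gaussian random walk on the circle:
#' `theta[k+1] = wrap(theta[k] + N(0, sigma^2 * dt))`, sampled every `dt`
#' seconds, starting from a uniform random angle. This emulates the heading
#' of a foraging rodent; it has no directional persistence or resting
#' periods.
#'
#' @param duration Total duration, seconds (> 0).
#' @param dt Sampling interval, seconds (> 0).
#' @param sigma Angular diffusion, rad/sqrt(s) (> 0).
#' @param seed Optional integer seed (applied via [set.seed()]).
#' @return A [ts_signal] of angles wrapped to `[0, 2*pi)`, with support
#'   `[0, duration]`.
#' @export
simulate_hd_trajectory <- function(duration, dt = 0.05, sigma = 1.2,
                                   seed = NULL) {
  if (duration <= 0 || dt <= 0 || sigma <= 0) {
    stop("'duration', 'dt' and 'sigma' must be > 0")
  }
  if (!is.null(seed)) set.seed(seed)
  n <- floor(duration / dt + 1e-9) + 1L
  steps <- stats::rnorm(n - 1L, 0, sigma * sqrt(dt))
  theta <- (stats::runif(1, 0, 2 * pi) + cumsum(c(0, steps))) %% (2 * pi)
  ts_signal((seq_len(n) - 1L) * dt, theta,
            time_support = epoch_set(0, duration))
}

#' Simulate an inhomogeneous Poisson train from a rate signal
#'
#' Thinning (rejection sampling): homogeneous candidates at the peak rate
#' are generated on each support interval and accepted with probability
#' `rate(t) / max(rate)`, where the rate between samples is held constant
#' at the left sample. Exact for piecewise-constant rates.
#'
#' @param rate A [ts_signal] of non-negative rates (events/s).
#' @param seed Optional integer seed.
#' @return A [ts_events] with the rate's time support.
#' @export
simulate_poisson_from_rate <- function(rate, seed = NULL) {
  if (!inherits(rate, "ts_signal")) stop("'rate' must be a ts_signal")
  if (any(rate$values < 0)) stop("rates must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  rmax <- if (length(rate)) max(rate$values) else 0
  sup <- rate$time_support
  times <- numeric(0)
  if (rmax > 0) {
    for (i in seq_len(n_intervals(sup))) {
      dur <- sup$end[i] - sup$start[i]
      ncand <- stats::rpois(1, rmax * dur)
      if (ncand == 0L) next
      cand <- sort(stats::runif(ncand, sup$start[i], sup$end[i]))
      k <- pmax(findInterval(cand, rate$times), 1L)  # left-sample rate
      acc <- stats::runif(ncand) < rate$values[k] / rmax
      times <- c(times, cand[acc])
    }
  }
  ts_events(times, time_support = sup)
}

#' Simulate a population of head-direction cells
#'
#' End-to-end fixture: one shared trajectory from
#' [simulate_hd_trajectory()], one von Mises tuning profile per unit, and
#' per-unit spikes drawn as an inhomogeneous Poisson process with rate
#' `f_i(theta(t))` via [simulate_poisson_from_rate()]. A single seed fixes
#' the whole simulation; draws are consumed in a fixed order (trajectory,
#' tunings, then each unit's spikes), so the result is reproducible
#' unit by unit.
#'
#' @param n_units Number of units (>= 1).
#' @param duration Trajectory duration, seconds.
#' @param dt Trajectory sampling interval, seconds.
#' @param tunings `"random"` (preferred directions uniform on the circle,
#'   `kappa ~ U(2, 6)`, `r_max ~ U(8, 25)` Hz, `r_base ~ U(0.1, 1)` Hz) or
#'   a list of [von_mises_tuning] objects of length `n_units`.
#' @param sigma Trajectory diffusion, rad/sqrt(s).
#' @param seed Optional integer seed for the whole simulation.
#' @return A list with `group` (an [event_group], unit ids `1..n_units`),
#'   `trajectory` (the [ts_signal] of angles) and `tunings` (the
#'   ground-truth profiles, for recovery tests).
#' @export
make_hd_population <- function(n_units, duration, dt = 0.05,
                               tunings = "random", sigma = 1.2,
                               seed = NULL) {
  if (n_units < 1L) stop("'n_units' must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  traj <- simulate_hd_trajectory(duration, dt, sigma, seed = NULL)
  if (identical(tunings, "random")) {
    tunings <- lapply(seq_len(n_units), function(i) {
      von_mises_tuning(mu = stats::runif(1, 0, 2 * pi),
                       kappa = stats::runif(1, 2, 6),
                       r_max = stats::runif(1, 8, 25),
                       r_base = stats::runif(1, 0.1, 1))
    })
  }
  if (length(tunings) != n_units) {
    stop("'tunings' must provide one profile per unit")
  }
  units <- lapply(tunings, function(vm) {
    r <- ts_signal(traj$times, tuning_rate(vm, traj$values),
                   time_support = traj$time_support)
    simulate_poisson_from_rate(r, seed = NULL)
  })
  names(units) <- seq_len(n_units)
  list(group = event_group(units, time_support = traj$time_support),
       trajectory = traj, tunings = tunings)
}

#' Simulate a calcium-like fluorescence trace from a spike train
#'
#' Convolves the spike train with a single-exponential decay kernel
#' (unit amplitude per spike, e-fold decay per `tau_decay`) sampled on a
#' regular grid of step `dt` over the spike train's support, and adds
#' Gaussian noise. A crude but convenient stand-in for an indicator
#' trace; it has no rise time or saturation.
#'
#' @param spikes A [ts_events].
#' @param tau_decay Decay time constant, seconds (> 0).
#' @param dt Sampling interval, seconds (> 0).
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param seed Optional integer seed (noise only).
#' @return A [ts_signal] on the grid.
#' @export
make_calcium_trace <- function(spikes, tau_decay, dt, noise_sd = 0,
                               seed = NULL) {
  if (tau_decay <= 0 || dt <= 0) stop("'tau_decay' and 'dt' must be > 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  sup <- spikes$time_support
  grid <- numeric(0); trace <- numeric(0)
  decay <- exp(-dt / tau_decay)
  for (i in seq_len(n_intervals(sup))) {
    g <- sup$start[i] + (0:floor((sup$end[i] - sup$start[i]) / dt + 1e-9)) * dt
    tt <- spikes$times[spikes$times >= sup$start[i] &
                         spikes$times <= sup$end[i]]
    # spike impulses land in the grid bin containing them
    imp <- tabulate(pmin(pmax(findInterval(tt, g), 1L), length(g)),
                    nbins = length(g))
    tr <- as.numeric(stats::filter(imp, decay, method = "recursive"))
    grid <- c(grid, g)
    trace <- c(trace, tr)
  }
  if (noise_sd > 0) trace <- trace + stats::rnorm(length(trace), 0, noise_sd)
  ts_signal(grid, trace, time_support = sup)
}
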