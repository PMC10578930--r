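---
title: "Models and methods behind neurotime"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind neurotime}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurotime)
```

## Why time supports

Most errors in spike-train analysis come from bookkeeping, not statistics:
an event array says nothing about *when observation was possible*. If a
neuron fired nothing between minutes 10 and 20, was it silent, or was that
period cut from the recording? `neurotime` therefore attaches an
`epoch_set` *time support* to every object and propagates it through every
operation: `restrict()` intersects supports, `threshold()` rebuilds the
support from the surviving samples, and `event_rate()` always divides by
the support duration — never by "last event minus first event".

All times are stored in seconds as 64-bit doubles. Membership tests use
exact float comparison with **closed** intervals `[start, end]`; because
construction merges overlapping *and abutting* intervals, a shared
endpoint can never be claimed by two intervals of the same set.

## Interval algebra conventions

`ep_intersect`, `ep_union` and `ep_setdiff` return normalized epoch sets.
Two conventions are worth spelling out:

* **Set difference.** `ep_setdiff(a, b)` keeps the times of `a` not
  interior to `b`; the endpoints of a removed region stay in the result as
  closed endpoints (`[0,10] \ [3,5]` is `[0,3] ∪ [5,10]`). Zero-length
  leftovers are dropped, so `a \ a` is empty. The measure-zero departure
  from strict set difference is deliberate: it keeps boundary samples from
  silently vanishing.
* **Gap merging.** `merge_close_intervals` compares `start <= end + gap`
  rather than `start - end <= gap`. The two are equivalent in exact
  arithmetic but not in floating point (`2.6 - 2 > 0.6` in doubles); the
  addition form merges all representable endpoint/gap combinations a user
  would write down.

A related numerical choice: the number of full bins in an interval (used
by `count()`, PSTH bins, sampling grids) is `floor((end - start)/bin +
1e-9)`. A pure floor loses bins to representation error (`(0.3 - 0)/0.1 <
3` in doubles); the `1e-9` s guard is nine orders of magnitude below any
meaningful bin width.

## Core method semantics

* `value_from(target, source)` is **nearest-neighbor, no interpolation, no
  maximum-gap cutoff**; equidistant ties go to the earlier source sample
  (deterministic, unbiased in expectation). The target is restricted to
  the intersection of the supports; the nearest value may come from a
  source sample just outside it — the alternative (restricting the source
  first) changes answers at epoch edges in a way users rarely intend.
* `count(x, b, ep)` tiles bins from each epoch's start and **drops
  trailing partial bins**: a rate read off a partial bin is biased, and a
  consumer can always widen the epoch if the tail matters. Consequently
  `sum(counts) <= n_events`, with equality when epoch lengths are bin
  multiples.
* `threshold(x, level)` keeps *strict* exceedances and rebuilds the
  support from maximal runs of qualifying samples. No crossing-time
  interpolation is attempted: the result is exact on the stored samples
  and makes no claims between them.
* Duplicate timestamps are legal (simultaneous events); *decreasing*
  input is rejected rather than sorted, so a mangled time base cannot
  slip through silently.

## Tuning curves

`tuning_1d()` estimates a rate map as

\[ \hat f(b) \;=\; \frac{\text{spikes assigned to bin } b}
                        {\text{occupancy}(b)} ,\qquad
   \text{occupancy}(b) = \#\{\text{feature samples in } b\}\cdot\Delta t .\]

The occupancy weight \(\Delta t\) defaults to the **median feature
sampling interval** of the restricted feature — robust to the occasional
large gap at epoch boundaries — and can be overridden with
`occupancy_dt`. Spikes are assigned the feature value of their nearest
feature sample (the same rule as `value_from`), never an interpolated
one. Bins never visited are `NA`, not 0: an unvisited bin carries no
evidence. Total occupancy equals the analyzed duration to within one
\(\Delta t\).

Circular features (`circular = TRUE`) are wrapped to \([0, 2\pi)\) and
binned over that full range. `preferred_feature()` estimates each unit's
preferred direction by the baseline-subtracted, rate-weighted circular
mean of the bin centers — the population-vector estimate standard for
head-direction work — rather than the raw argmax, which is quantized to
the bin width. For linear features it returns the argmax bin center.

`tuning_2d()` applies the same formula with product binning;
`tuning_continuous()` replaces counts by per-bin means of a trace (for
calcium fluorescence and similar signals where "rate" is meaningless).

## Bayesian decoding

`decode_bayes_1d()` assumes spiking is Poisson conditioned on the feature
and units are independent given the feature. With window \(\tau\), counts
\(n_i\) and tuning rates \(f_i(x)\):

\[ \log P(x \mid n) = \log P(x) + \sum_i\bigl[n_i \log f_i(x) - \tau
   f_i(x)\bigr] + C. \]

Everything is computed in log space with a max-subtraction softmax, so
long windows or many units cannot underflow. Two guards matter:

* bins whose tuning is **undefined** (zero occupancy) leave the state
  space entirely — no evidence, no candidate;
* rates are floored at \(10^{-12}\) events/s so observed zero-rate bins
  stay in the state space with a near-zero, finite likelihood instead of
  \(-\infty\).

The default prior is uniform; `prior = "occupancy"` weights states by
dwell time. The paper-style decoder typically reports the MAP bin center;
ties go to the first bin.

## Correlograms

`cross_correlogram(ref, target, b, w)` lays out an **odd** number of
half-open lag bins `[left, right)`, one exactly centered at lag 0,
spanning \([-(K+\tfrac12)b, (K+\tfrac12)b]\) with \(K=\lceil w/b\rceil\).
This layout makes the autocorrelogram of continuous-time data symmetric
bin-for-bin, since every pair contributes lags \(+d\) and \(-d\).
`norm = "rate"` divides counts by \(n_{ref} \cdot b\): the value is the
conditional rate (events/s) of the target around a reference event, flat
at the target's mean rate for independent trains. `auto_correlogram`
excludes identical-index pairs only, so duplicated (simultaneous) events
still count each other. With an epoch restriction both trains are
restricted first; pairs straddling an epoch gap are kept if both events
survive — no boundary correction is applied, which biases lags comparable
to the epoch lengths (documented, out of scope).

## Peri-event alignment

`peri_event()` aligns events in a closed window \([-b_{-}, +b_{+}]\)
around each reference; the pooled rate divides by \(n_{ref}\cdot b\), so
an uncorrelated target shows its mean rate. `peri_event_continuous()`
samples a trace on a fixed relative grid by nearest neighbor and drops
references whose full window is not covered by the target's support
(reporting how many), so edge references cannot dilute the trial mean.

## The synthetic fixtures

The generator emulates the canonical head-direction recording:

* **Trajectory**: wrapped Gaussian random walk,
  \(\theta_{k+1} = \theta_k + \mathcal N(0, \sigma^2\,dt)\), default
  \(\sigma = 1.2\ \mathrm{rad}/\sqrt{s}\) and \(dt = 50\) ms — brisk but
  plausible head turning that covers the circle well within a few
  minutes.
* **Tuning**: von Mises-shaped profiles
  \(f(\theta)=r_b+(r_{max}-r_b)e^{\kappa(\cos(\theta-\mu)-1)}\) with, by
  default, \(\mu\sim U[0,2\pi)\), \(\kappa\sim U[2,6]\),
  \(r_{max}\sim U[8,25]\) Hz and \(r_b\sim U[0.1,1]\) Hz — the range of
  sharpness and peak rates typical of anterodorsal-thalamus
  head-direction cells.
* **Spikes**: inhomogeneous Poisson by **thinning** against the peak
  rate, with the rate held constant at the left sample between samples —
  exact for the piecewise-constant rate actually represented, unlike
  time-rescaling which would require integrating an interpolant.
* **Calcium traces**: spike deltas convolved with a single-exponential
  decay kernel plus Gaussian noise. No rise time, saturation or indicator
  nonlinearity — adequate for testing alignment and continuous tuning,
  not for benchmarking deconvolution.

One seed fixes an entire population; draws are consumed in a fixed order
(trajectory, tunings, unit 1 spikes, unit 2 spikes, ...), so any unit can
be regenerated by rerunning the same call.

What these fixtures do *not* emulate: angular velocity autocorrelation,
behavioral state changes, bursting/refractoriness, electrode drift, or
correlated noise across units. Tests passing on them demonstrate the
*analysis code* is correct, not that real data will be as clean.

The standard test problem is 20 units over 300 s at \(dt=50\) ms; the
correlogram checks use two independent 10 Hz trains over 1000 s and the
peri-event check injects a rate doubling on \([+25, +75]\) ms after each
of 500 references on a 5 Hz background. For that check the window is
taken as \([-0.225, +0.275]\) s with 50 ms bins so that one bin is
exactly the injection window \([0.025, 0.075)\) — the bin containing
+50 ms. At these sizes the whole suite runs in well under a minute on one
core.

## Persistence

Sessions are saved as a single JSON document (`format`, `name`,
`metadata`, `objects`, each object tagged with its type). All numbers are
written as decimal strings with 17 significant digits, which round-trips
IEEE doubles **bit-exactly** — a property we verified directly and that
generic JSON number emission does not provide. Every object is run
through its type validator on load, and a corrupted entry names the
offending object. The built-in loaders assume all streams already share
time zero; aligning acquisition clocks belongs in the custom loader
(`register_loader()`), which is also the extension point for lab-specific
formats (NWB, Phy, ...). The container is deliberately format-simple
rather than an NWB implementation; an NWB reader can be attached through
the registry without touching the core.

## Known limitations

* No smoothing or kernel-density options on tuning curves or
  correlograms; estimates are raw bin statistics.
* Decoding is 1D only; no continuity prior across windows (each window is
  decoded independently).
* No spectral/filtering DSP; `threshold` does not interpolate crossing
  times.
* Correlograms apply no epoch-boundary correction (see above).
* Everything is in memory; no lazy or streamed series.
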