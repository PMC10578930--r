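Package: neurotime
Title: Time Series Objects and Foundational Analyses for Systems Neuroscience
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Containers and methods for time-resolved neurophysiology data:
    event timestamps, sampled signals, multi-channel frames, grouped spike
    trains and interval (epoch) sets, with an interval algebra and automatic
    time-support propagation. On top of these, the package provides the
    foundational analyses of systems neuroscience: occupancy-normalized
    tuning curves (discrete, 1D, 2D and continuous-trace), Bayesian
    population decoding from Poisson spike counts, auto- and
    cross-correlograms, and peri-event alignment. A JSON-backed session
    container, CSV epoch and tracking loaders and a loader registry cover
    persistence, and a synthetic-data module generates head-direction
    trajectories, tuned Poisson spike trains and calcium-like traces for
    fully reproducible examples and tests.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
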