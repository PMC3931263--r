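Package: sweepkit
Title: Kinetic Analysis of Patch-Clamp Sweeps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying intracellular electrophysiological
    recordings: principal kinetic measurements on patch-clamp sweeps
    (baseline, peak, rise time, half duration, fixed-interval maximal
    slopes, threshold crossings, synaptic latencies), least-squares model
    fitting with measurement-derived initial estimates, spontaneous
    synaptic event detection by sliding template matching and FFT
    deconvolution, min-max trace reduction for display, and synthetic-data
    generators (analytic trace families, noisy action-potential waveforms,
    a single-compartment interneuron simulation, Poisson EPSC trains with
    colored noise) used to validate every algorithm against known ground
    truth. Recordings are read and written as ATF-style text, CSV/TSV, or
    HDF5.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    graphics,
    minpack.lm,
    purrr,
    rhdf5,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
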