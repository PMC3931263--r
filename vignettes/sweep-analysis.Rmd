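---
title: "Quantifying patch-clamp sweeps with sweepkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying patch-clamp sweeps with sweepkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sweepkit)
```

sweepkit quantifies intracellular electrophysiological recordings: action
potentials and synaptic currents acquired as repetitive sweeps. This
vignette is the package's account of its methods — what each algorithm
assumes, which tunable parameters matter, how the synthetic benchmark data
are built, and where the known limits are.

## The data model

A **trace** is one sweep of uniformly sampled signal: a numeric vector plus
a sampling interval `dt` in milliseconds and a unit label (mV or pA). A
**region** is a pair of cursors — a 1-based, inclusive window of sample
indices — within which a measurement operates, mirroring the paired
vertical cursors of an oscilloscope display. We use 1-based inclusive
indexing because it is the R idiom (compare IRanges); the sample at index
`i` sits at time `t0 + (i - 1) dt`. Channels group sweeps acquired with one
amplifier; recordings group channels with free-form metadata.

Every result type is a tibble (or carries `tidy()`/`glance()` methods), so
pipelines compose with the usual dplyr verbs, and `autoplot()` methods
display traces, fits and detection criteria.

## Principal measurements

All kinetic analysis reduces to a small set of principal measurements:

* **baseline** — mean and *population* SD over the baseline region. The
  population SD (divide by n) is deliberate: it is used directly as a noise
  estimate when scaling detection thresholds, where an unbiased estimate of
  a hypothetical infinite population is not the quantity of interest.
* **peak** — extremum of an `n_average`-point moving average within the
  peak region, reported baseline-subtracted. Ties on the smoothed extremum
  resolve toward the largest raw deviation, then toward the earlier sample,
  so the reported peak index is deterministic.
* **rise time** — interpolated times of the last crossings of 20% and 80%
  of the peak amplitude before the peak. Crossings are searched *backward*
  from the peak so noise before the event onset cannot capture them, and
  located by linear interpolation between the bracketing samples. The
  interpolation is what delivers one-sampling-point accuracy even at low
  sampling rates.
* **half duration** — interpolated crossings of 50% amplitude on both
  sides of the peak (the event's FWHM).
* **maximal slopes** of rise and decay — the extremum of
  `(y(t + w) - y(t)) / w` with the window `w` fixed at 0.05 ms (50 µs),
  rounded to the nearest whole number of samples (minimum one). A fixed
  window matters at high sampling rates: the temporal derivative of
  instrument noise grows with the rate, so adjacent-sample differences
  overestimate slopes and their spread; a fixed 50 µs window keeps the
  estimate nearly rate-independent (demonstrated below).
* **threshold crossing** — the first sample whose fixed-window slope
  reaches a user-set rate, the operational definition of action-potential
  threshold.

Derived quantities: the **foot** of an event is the extrapolated
intersection of the baseline with the straight line through the 20% and
80% rise points, a robust onset estimate; **synaptic latency** defaults to
the interval from the presynaptic maximal rising slope (the moment of
maximal inward current during the action potential) to the postsynaptic
foot. Peak-to-peak and half-rise latencies are also available.

```{r}
sine <- gen_sine(A = 10, f = 1, n = 10000, dt = 1e-4)
tidy(measure_all(sine, region(1, 10000), region(1, 10000), direction = "up"))
```

For a unit-frequency sine the rise time is 0.23 π rad of phase and the half
duration 2/3 π rad — the closed forms `(asin 0.8 - asin 0.2)/(2 pi f)` and
`2 (asin 1 - asin 0.5)/(2 pi f)` — which is how the implementation is
validated (see below).

## Model fitting

`fit_model()` minimizes the sum of squared errors between a trace region
and a parametric model by Levenberg–Marquardt least squares (backend:
minpack.lm). The model registry covers the standard waveforms of cellular
neuroscience: mono- and bi-exponentials, a delayed bi-exponential product
form `A (1 - exp(-(t-δ)/τ₁)) exp(-(t-δ)/τ₂)`, the alpha synapse function
`A (t/τ) exp(1 - t/τ)` (peak `A` at `t = τ`), Hodgkin–Huxley-style
`A (1 - exp(-t/τ_m))³ exp(-t/τ_h)` and two-gate `A (1 - exp(-t/τ_m))
exp(-t/τ_h)` sodium-conductance transients, and a Gaussian pulse. Model
time runs from zero at the first sample of the fit region.

Two design choices matter in practice:

**Initial estimates come from the measurements.** Exponential decays are
initialized by linear regression on log-transformed data (amplitude-squared
weights down-weight the tail, where subtracting the estimated offset biases
the logarithm most). Peaked models take their kinetic parameters from the
principal measurements: time-to-peak for the alpha function's τ, the FWHM
identity `σ = FWHM / (2 √(2 ln 2))` for the Gaussian, the extrapolated foot
for the delay, the 20–80% rise time (scaled by the model's rise-shape
factor) for activation time constants, and the measured peak for the
amplitude. For initialization the baseline reference is the *median* of
the fit window — it sits on the resting level both for onset-from-zero
transients and for pulses clipped by the window edge — with moment-based
fallbacks where a crossing does not exist. Starting values land inside the
basin of the global minimum for every registered model over wide (±30%
multiplicative, often far wider) parameter neighborhoods.

**Success is judged on the normalized trace.** With `rescale = TRUE`
(default) residuals are computed on the trace rescaled to span [0, 1], and
a fit is *successful* when that normalized SSE is at most 0.001. One
scale-free number therefore applies across models fitted in mV, pA or
dimensionless units; parameters are reported back-transformed.

`validate_fit_grid()` packages the convergence benchmark: noise-free traces
with every parameter multiplied by an independent N(1, 0.3) draw (redrawn
outside constraints), fitted either with measurement inits or with every
fit started from the grid's mean parameter vector. The measurement strategy
reaches 0% unsuccessful fits for every registered model; the average-start
contrast condition does not, which is the point of the comparison.
Reference grids (chosen as physiologically plausible, fixed once): alpha
(A = 1, τ = 5 ms), monoexp (A = 1, τ = 10 ms), delayed biexp (A = 1, τ₁ =
1 ms, τ₂ = 10 ms, δ = 1 ms), gated models (A = 1, τ_m = 0.5 ms, τ_h =
3 ms), Gaussian (A = 1, μ = 10 ms, σ = 2 ms); windows cover several decay
constants at sampling fine enough to resolve the fastest randomized rise.

## Spontaneous-event detection

Both detectors start from a **template**: the time course of a typical
event, baseline zero, extremum normalized to magnitude one *with polarity
retained* (an inward current's template is negative-going; a criterion
maximum then always signals a match, for either polarity).
`make_template()` bootstraps one from the recording itself: candidate peaks
beyond `k_sd` (default 5) all-point SDs are located on a smoothed copy of
the trace — aligning on raw noisy extrema jitters the alignment and smears
the average's rising phase — preferring isolated events, and the pointwise
average of the extracted windows is fitted with the delayed bi-exponential
model; the fitted curve from its onset onward becomes the template.

**Template matching** slides the template across the trace; at each
position the optimal scale `m` and offset `c` minimize χ² against the
window, which is just a straight-line fit relating template and data.
Running sums plus one FFT cross-correlation make the cost O(N log N)
independent of template length, and the result equals a naive per-window
regression to 1e-8. Two criteria are derived: the Pearson correlation
between window and scaled template, and the scale factor normalized by the
fit's standard error, `m / sqrt(χ²/(n-1))`. The final `n - 1` window
positions are marked invalid rather than padded.

**Deconvolution** treats the recording as the convolution of an
event-onset delta train with the template and estimates the onsets by
spectral division, `f' = IFFT(FFT(r)/FFT(p))`, followed by a zero-phase
Gaussian low-pass. The low-pass is the regularizer: the inverse filter
amplifies noise steeply toward the band edge (for a bi-exponential
template the deconvolved noise density grows roughly as f⁴), so the
criterion's signal-to-noise ratio *improves* as the cutoff comes down,
while onset spikes stay far narrower than typical inter-event intervals.
The default cutoff is 0.5 kHz — half a typical 1 kHz recording-noise band;
we found a 1 kHz cutoff costs roughly a fifth of true events at a 4 SD
threshold on the benchmark train below, while 0.5 kHz recovers over 90%.
Template spectral magnitudes below 1e-6 of the spectral maximum are floored
with phase preserved.

Thresholds are expressed in multiples of the criterion's noise SD,
estimated by fitting a Gaussian to the *all-point histogram* of the
criterion (Freedman–Diaconis bins, fitted only within two interquartile
ranges of the mode so event tails do not inflate the estimate; the bin
count is capped at 2000 so nearly noise-free series stay tractable).
Contiguous supra-threshold runs become events at their criterion maximum;
runs closer than the template's 20–80% rise time merge, keeping the larger
peak. `evaluate_detection()` scores detections against known onsets by
greedy nearest-first one-to-one matching.

A practical caution that the benchmarks quantify: at a 2.5 SD threshold —
with SD read as the histogram's Gaussian-core SD — a 60 s criterion trace
of colored noise alone crosses threshold hundreds of times, whatever the
template or event amplitude. The template criteria at low SD multiples are
therefore best used as a *sensitive first pass* followed by curation of the
event table (the `accepted` column exists for exactly that), while the
deconvolution criterion at 4 SD is selective enough to use unsupervised.

## Trace reduction for display

`reduce_trace()` implements min–max pixel-column downsampling: when `n`
samples map onto `w` pixel columns, each column's many sample-to-sample
line drawings are replaced by a single vertical segment spanning the
column's min–max range plus one connector into the next column — exactly
`2w - 1` segments regardless of `n`, covering the same vertical pixel span
per column as the naive polyline. Columns partition near-evenly (column
`k` gets samples `⌊(k-1)n/w⌋+1 … ⌊kn/w⌋`); the vertical segment is drawn
toward whichever extremum occurs first, a deterministic choice that does
not affect coverage. Reduction only pays when `n > 2w + 2`, so smaller
inputs return the unreduced polyline. Output is device-independent data
coordinates; rasterization is the plotting backend's concern.

## Synthetic benchmark data

The generators define the package's validation conditions; every algorithm
above is certified against them.

* **Analytic families** (`gen_sine`, `gen_monoexp`, `gen_gaussian_pulse`)
  evaluate their formulas exactly, so every principal measurement has a
  closed-form expectation. `validate_measurement_grid()` draws randomized
  parameter sets (multiplicative N(1, 0.3) factors; the Gaussian family
  jointly redraws until the pre-pulse baseline region exists, μ > 5σ) and
  requires each measurement to agree with its analytic value to one
  sampling point — one `dt` for times, the signal (or slope) change across
  one interval for values. 1000 traces per family at 1000 samples each
  pass at 100%.
* **Noisy action potentials**: `simulate_wang_buzsaki()` integrates the
  standard fast-spiking interneuron membrane model (leak, transient sodium
  with instantaneous activation m∞³h, delayed-rectifier n⁴; gating rates
  accelerated fivefold; E_Na = 55, E_K = −90, E_L = −65 mV) with
  fixed-step RK4. With the default 1e-4 cm² membrane area a 100 pA
  injection is 1 µA/cm² and drives repetitive firing. Thermal noise is
  added as white Gaussian noise with σ = √(4 k_B T B Z) volts
  (`thermal_noise_sd()`), the trace is decimated without interpolation to
  the target rate (aliased noise included, as in real acquisition at that
  rate), and rounded to the 2 V/2¹⁶ ADC grid. Across 100 noise
  realizations per condition the 5–95 percentile spread of the 50 µs-window
  slope estimate is strictly smaller than the adjacent-sample spread at
  every rate above 20 kHz; at exactly 20 kHz the window spans one sampling
  interval and the two estimators coincide by construction.
* **EPSC trains**: `gen_epsc_train()` draws Poisson onsets (5 Hz over
  60 s by default), gives each event a peak-normalized
  difference-of-exponentials kernel (τ_onset = 0.2 ms, τ_decay = 2.5 ms;
  per-event CV 0.3 on time constants, 0.1 on amplitudes; negative polarity
  for inward currents), sums events linearly and adds colored noise (white
  noise low-pass filtered at 1 kHz, scaled to SD 0.15 of the unit peak — a
  typical miniature-EPSC signal-to-noise ratio). The exact truth table is
  returned with the trace. This generator *emulates* the output statistics
  of a compartmental neuron driven by distributed synapses; it does not
  model dendritic cable filtering (its kinetic consequences are subsumed in
  the randomized kernel time constants), conductance driving forces, or
  non-stationary noise, so passing benchmarks demonstrate detector
  correctness on stationary, linear data — not performance on recordings
  with drift, seal instability or strongly filtered dendritic events.

All stochastic generators are bit-reproducible under a seed.

## Numerical choices

* Fraction and threshold crossings interpolate linearly between bracketing
  samples; times are exact to float precision on noise-free ramps.
* The slope window rounds to the nearest whole sample count,
  `w = max(1, round(0.05 ms / dt))`, so rates that are not multiples of
  20 kHz use the closest achievable interval.
* The zero-phase low-pass is a truncated (±4σ) discrete Gaussian kernel
  parameterized by its −3 dB frequency, normalized to unit DC gain, with
  replicated-end padding; zero phase preserves latency and onset
  measurements. Convolution is direct (the kernel is short), avoiding FFT
  length pathologies on arbitrary trace lengths.
* LM stopping: 1000 iterations, 1e-8 relative tolerances on SSE and
  parameters; bounds are enforced by the optimizer. Non-finite model
  values during the search are replaced by large residuals.
* Cursor positions given in ms convert to sample indices by rounding
  half-up.
* Text I/O verifies time-axis uniformity to one part in 1e4; HDF5 stores
  float64 and round-trips bit-exactly. Text export flattens channel/sweep
  pairs to columns (single-sweep channels keep their bare name), and the
  reader maps columns back to single-sweep channels, so a second
  write-read-write cycle is byte-identical even though the nesting is not
  preserved.

## Problem sizes used in the shipped tests

The test suite exercises the same procedures at sizes chosen to make each
property decisive: 10,000-sample analytic sines; 1000 randomized traces per
analytic family; 200-trace fit grids per model; 100 noise realizations per
slope condition on a 40 ms simulated action-potential waveform; one 60 s,
5 Hz benchmark train for the detectors; 1000 random traces for the
reduction oracle. Larger sizes change none of the conclusions — the
analytic checks are deterministic and the stochastic ones are far from
their decision boundaries.

## Known limitations

* The averaging of sweeps of unequal length is rejected for `align =
  "none"`; peak alignment operates at sample resolution (no sub-sample
  shifts), consistent with the one-sampling-point accuracy contract.
* Binary vendor acquisition formats are out of scope; recordings arrive as
  ATF-style text, CSV/TSV or HDF5 (an external parser can hand any
  structure to `recording()` directly).
* The detectors assume linear event summation and stationary noise; see
  the caution above on low template-matching thresholds.
* The interneuron simulation is a single compartment: it produces realistic
  action-potential kinetics for estimator benchmarks, not morphologically
  detailed dynamics.
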