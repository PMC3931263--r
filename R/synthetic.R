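# Synthetic-data generators. These define the study conditions every
# validation in the package runs under: analytic trace families with known
# measurement values, a simulated action potential degraded by thermal and
# quantization noise, and Poisson EPSC trains with colored noise for the
# event detectors.

#' Analytic trace families
#'
#' Exact evaluation of a sine `A sin(2 pi f x)`, a mono-exponential
#' `A exp(-t/tau) + C`, and a Gaussian pulse `A exp(-(t-mu)^2/(2 sigma^2))`
#' at the sample times. These waveforms have closed-form peak, rise-time,
#' half-duration, slope, threshold and baseline values, so every principal
#' measurement can be validated against an analytic expectation.
#'
#' @param A Amplitude (y-units).
#' @param f Frequency in cycles per ms (for `gen_sine`).
#' @param tau,C Exponential time constant (ms) and offset.
#' @param mu,sigma Gaussian center and SD in ms.
#' @param n Number of samples (>= 2).
#' @param dt Sampling interval in ms.
#' @param y_unit Signal unit label.
#' @return A [trace()] with `t0 = 0`.
#' @examples
#' gen_sine(A = 10, f = 1, n = 1000, dt = 1e-3)
#' @export
gen_sine <- function(A, f, n, dt, y_unit = "mV") {
  check_gen(n, dt, positive = c(f = f))
  x <- (seq_len(n) - 1) * dt
  trace(A * sin(2 * pi * f * x), dt = dt, y_unit = y_unit)
}

#' @rdname gen_sine
#' @export
gen_monoexp <- function(A, tau, C = 0, n, dt, y_unit = "mV") {
  check_gen(n, dt, positive = c(tau = tau))
  x <- (seq_len(n) - 1) * dt
  trace(A * exp(-x / tau) + C, dt = dt, y_unit = y_unit)
}

#' @rdname gen_sine
#' @export
gen_gaussian_pulse <- function(A, mu, sigma, n, dt, y_unit = "mV") {
  check_gen(n, dt, positive = c(sigma = sigma))
  x <- (seq_len(n) - 1) * dt
  trace(A * exp(-(x - mu)^2 / (2 * sigma^2)), dt = dt, y_unit = y_unit)
}

check_gen <- function(n, dt, positive = numeric()) {
  if (n < 2 || dt <= 0 || any(!is.finite(positive)) || any(positive <= 0)) {
    rlang::abort("Generator needs n >= 2, dt > 0 and positive kinetic parameters.",
                 class = "sweepkit_error_argument")
  }
}

#' Randomize a reference parameter set
#'
#' Draws `count` parameter vectors, each the reference multiplied
#' componentwise by independent N(1, cv) factors, redrawing any vector that
#' falls outside the `[lower, upper]` constraints — the scheme used to
#' emulate the spread of values seen in real recordings.
#'
#' @param reference Named numeric vector of reference parameters.
#' @param cv SD of the multiplicative factors (scalar or per-parameter).
#' @param count Number of parameter sets.
#' @param lower,upper Optional per-parameter bounds (defaults: unbounded).
#' @param seed Optional RNG seed.
#' @return List of `count` named parameter vectors.
#' @examples
#' randomize_params(c(A = 1, tau = 5), cv = 0.3, count = 3, seed = 1)
#' @export
randomize_params <- function(reference, cv, count, lower = NULL, upper = NULL,
                             seed = NULL) {
  if (any(cv < 0) || count < 1L) {
    rlang::abort("Need cv >= 0 and count >= 1.", class = "sweepkit_error_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  k <- length(reference)
  cv <- rep_len(cv, k)
  if (is.null(lower)) lower <- rep(-Inf, k)
  if (is.null(upper)) upper <- rep(Inf, k)
  draw <- function() {
    for (i in seq_len(1000L)) {
      p <- reference * stats::rnorm(k, mean = 1, sd = cv)
      if (all(p >= lower & p <= upper)) return(p)
    }
    rlang::abort("Could not draw parameters inside constraints.",
                 class = "sweepkit_error_argument")
  }
  purrr::map(seq_len(count), function(i) draw())
}

#' Thermal (Johnson-Nyquist) noise SD
#'
#' `sigma = sqrt(4 kB T B Z)` in volts, for an impedance `Z` (MOhm),
#' absolute temperature `T` (K) and noise bandwidth `B` (kHz, the Nyquist
#' frequency of the acquisition).
#'
#' @param impedance_mohm Source impedance in MOhm (>= 0).
#' @param bandwidth_khz Noise bandwidth (Nyquist frequency) in kHz.
#' @param temperature_k Absolute temperature in K.
#' @return Noise SD in volts.
#' @examples
#' thermal_noise_sd(100, bandwidth_khz = 100)  # ~ 4.06e-4 V
#' @export
thermal_noise_sd <- function(impedance_mohm, bandwidth_khz, temperature_k = 298) {
  if (impedance_mohm < 0 || bandwidth_khz <= 0 || temperature_k <= 0) {
    rlang::abort("Need Z >= 0, B > 0, T > 0.", class = "sweepkit_error_argument")
  }
  kB <- 1.380649e-23
  sqrt(4 * kB * temperature_k * bandwidth_khz * 1e3 * impedance_mohm * 1e6)
}

#' Acquisition noise model
#'
#' Bundles the thermal-noise parameters with the ADC quantization settings
#' (full scale 2 V over 16 bits by default, i.e. a step of 2/65536 V).
#'
#' @inheritParams thermal_noise_sd
#' @param full_scale_v ADC full-scale range in volts.
#' @param bits ADC resolution in bits.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(impedance_mohm, bandwidth_khz, temperature_k = 298,
                        full_scale_v = 2, bits = 16L) {
  structure(list(impedance_mohm = impedance_mohm, bandwidth_khz = bandwidth_khz,
                 temperature_k = temperature_k, full_scale_v = full_scale_v,
                 bits = as.integer(bits)),
            class = "noise_model")
}

unit_to_volts <- function(y_unit) {
  switch(y_unit, V = 1, mV = 1e-3, uV = 1e-6,
         rlang::abort(sprintf("Cannot convert unit `%s` to volts.", y_unit),
                      class = "sweepkit_error_argument"))
}

#' Add thermal noise and ADC quantization to a trace
#'
#' Adds white Gaussian noise with SD [thermal_noise_sd()] (in volts,
#' converted to the trace's unit) and then rounds every sample to the ADC
#' grid `full_scale / 2^bits`.
#'
#' @param trace A [trace()] whose `y_unit` is convertible to volts
#'   (`"V"`, `"mV"`, `"uV"`).
#' @param noise A [noise_model()].
#' @param seed Optional RNG seed.
#' @return The degraded [trace()], in the original unit.
#' @export
add_noise_and_quantize <- function(trace, noise, seed = NULL) {
  stopifnot(is_trace(trace), inherits(noise, "noise_model"))
  if (!is.null(seed)) set.seed(seed)
  scale <- unit_to_volts(trace$y_unit)
  v <- trace$samples * scale
  sd_v <- thermal_noise_sd(noise$impedance_mohm, noise$bandwidth_khz,
                           noise$temperature_k)
  if (sd_v > 0) v <- v + stats::rnorm(length(v), sd = sd_v)
  step <- noise$full_scale_v / 2^noise$bits
  v <- round(v / step) * step
  trace(v / scale, dt = trace$dt, y_unit = trace$y_unit, t0 = trace$t0)
}

#' Decimate a trace to a lower sampling rate
#'
#' Plain decimation by a nearest-integer stride (no interpolation, no
#' anti-alias filtering — the point is to emulate acquisition at a lower
#' rate, aliased noise included).
#'
#' @param trace A [trace()].
#' @param new_rate_khz Target sampling rate in kHz (at most the current
#'   rate).
#' @return Decimated [trace()]; the reported `dt` is exactly
#'   `stride * dt`.
#' @export
resample_trace <- function(trace, new_rate_khz) {
  stopifnot(is_trace(trace))
  rate <- 1 / trace$dt
  if (new_rate_khz > rate + 1e-9) {
    rlang::abort("Upsampling is not supported.", class = "sweepkit_error_argument")
  }
  stride <- max(1L, as.integer(round(rate / new_rate_khz)))
  keep <- seq.int(1L, length(trace$samples), by = stride)
  trace(trace$samples[keep], dt = trace$dt * stride,
        y_unit = trace$y_unit, t0 = trace$t0)
}

#' Poisson EPSC train with colored noise
#'
#' Generates a spontaneous-activity benchmark: event onsets from a
#' homogeneous Poisson process (default 5 Hz over 60 s), each event a
#' peak-normalized difference-of-exponentials kernel
#' `(1 - exp(-t/tau_onset)) * exp(-t/tau_decay)` (defaults 0.2/2.5 ms)
#' scaled by a randomized amplitude (negative = inward current). Per-event
#' time constants vary with CV 0.3 and amplitudes with CV 0.1; events sum
#' linearly; colored noise (white Gaussian noise low-pass filtered at
#' `noise_fc_khz`, default 1 kHz, then scaled to `noise_sd`) is added. The
#' exact ground truth is returned alongside the trace.
#'
#' @param duration_s Trace duration in seconds.
#' @param rate_hz Mean event rate in Hz.
#' @param tau_onset,tau_decay Kernel time constants in ms.
#' @param amplitude Peak amplitude in y-units (positive number; applied as a
#'   negative, inward deflection).
#' @param cv_tau,cv_amp CVs of the per-event kinetic and amplitude
#'   randomization.
#' @param noise_fc_khz Cutoff of the noise-shaping low-pass in kHz.
#' @param noise_sd Post-filtering noise SD in y-units (0 disables noise).
#' @param dt Sampling interval in ms.
#' @param seed Optional RNG seed.
#' @param y_unit Signal unit.
#' @return A list with `trace` (a [trace()]) and `truth`, a tibble with one
#'   row per event: `onset_ms`, `amplitude`, `tau_onset`, `tau_decay`.
#' @examples
#' sim <- gen_epsc_train(duration_s = 2, seed = 1)
#' nrow(sim$truth)
#' @export
gen_epsc_train <- function(duration_s = 60, rate_hz = 5,
                           tau_onset = 0.2, tau_decay = 2.5,
                           amplitude = 1, cv_tau = 0.3, cv_amp = 0.1,
                           noise_fc_khz = 1, noise_sd = 0.15,
                           dt = 0.05, seed = NULL, y_unit = "pA") {
  if (duration_s <= 0 || rate_hz <= 0 || dt <= 0) {
    rlang::abort("Need positive duration, rate and dt.",
                 class = "sweepkit_error_argument")
  }
  if (!is.null(seed)) set.seed(seed)
  dur_ms <- duration_s * 1e3
  n <- as.integer(round(dur_ms / dt))
  # homogeneous Poisson onsets via exponential inter-arrival times
  gaps <- stats::rexp(ceiling(rate_hz * duration_s * 2) + 20, rate = rate_hz / 1e3)
  onsets <- cumsum(gaps)
  while (sum(gaps) < dur_ms) {  # extend in the unlikely case of a short draw
    gaps <- c(gaps, stats::rexp(100, rate = rate_hz / 1e3))
    onsets <- cumsum(gaps)
  }
  onsets <- onsets[onsets < dur_ms - 10 * tau_decay]
  m <- length(onsets)
  draw_pos <- function(ref, cv, k) {
    x <- ref * stats::rnorm(k, 1, cv)
    while (any(x <= 0)) x[x <= 0] <- ref * stats::rnorm(sum(x <= 0), 1, cv)
    x
  }
  taus_on <- draw_pos(tau_onset, cv_tau, m)
  taus_de <- draw_pos(tau_decay, cv_tau, m)
  amps <- draw_pos(amplitude, cv_amp, m)
  y <- numeric(n)
  for (j in seq_len(m)) {
    k <- epsc_kernel(taus_on[j], taus_de[j], dt)
    i0 <- as.integer(floor(onsets[j] / dt)) + 1L
    i1 <- min(n, i0 + length(k) - 1L)
    y[i0:i1] <- y[i0:i1] - amps[j] * k[seq_len(i1 - i0 + 1L)]
  }
  tr <- trace(y, dt = dt, y_unit = y_unit)
  if (noise_sd > 0) {
    wn <- trace(stats::rnorm(n), dt = dt, y_unit = y_unit)
    cn <- lowpass_filter(wn, noise_fc_khz)$samples
    cn <- cn / sqrt(mean(cn^2)) * noise_sd
    tr$samples <- tr$samples + cn
  }
  list(trace = tr,
       truth = tibble::tibble(onset_ms = onsets, amplitude = -amps,
                              tau_onset = taus_on, tau_decay = taus_de))
}

# Peak-normalized difference-of-exponentials kernel sampled at dt, truncated
# once the decay falls below 1e-5 of peak.
epsc_kernel <- function(tau_onset, tau_decay, dt) {
  t_end <- tau_decay * log(1e5) + 5 * tau_onset
  t <- seq(0, t_end, by = dt)
  k <- (1 - exp(-t / tau_onset)) * exp(-t / tau_decay)
  k / max(k)
}
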