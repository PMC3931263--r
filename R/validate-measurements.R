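# Randomized analytic validation of the principal measurements: sine,
# mono-exponential and Gaussian trace families with closed-form expected
# values. A measurement passes when it agrees with the analytic value to
# one sampling point: one dt for time-like results, and the signal (or
# slope) change across one sampling interval for value-like results.

sine_expectations <- function(A, f) {
  list(peak = A,
       rise = (asin(0.8) - asin(0.2)) / (2 * pi * f),
       half = 2 * (asin(1) - asin(0.5)) / (2 * pi * f),
       slope_rise = 2 * pi * f * A,
       slope_decay = -2 * pi * f * A)
}

validate_sine_once <- function(A, f, n) {
  dt <- 1 / (f * n)                     # exactly one period
  tr <- gen_sine(A, f, n, dt)
  ex <- sine_expectations(A, f)
  bl <- measure_baseline(tr, region(1, n))
  pk <- measure_peak(tr, bl, region(1, n), direction = "up")
  rise <- measure_rise_time(tr, bl, pk)
  half <- measure_half_duration(tr, bl, pk)
  sr <- measure_max_slope(tr, region(1, n), window_ms = dt, sign = "rise")
  sd_ <- measure_max_slope(tr, region(1, n), window_ms = dt, sign = "decay")
  tol_y <- ex$slope_rise * dt           # max |dy| across one interval
  tol_s <- (2 * pi * f)^2 * A * dt      # max |dslope| across one interval
  c(peak = abs(pk$value - ex$peak) <= tol_y,
    rise = abs(rise$duration - ex$rise) <= dt,
    half = abs(half$width - ex$half) <= dt,
    slope_rise = abs(sr$value - ex$slope_rise) <= tol_s,
    slope_decay = abs(sd_$value - ex$slope_decay) <= tol_s)
}

validate_monoexp_once <- function(A, tau, n) {
  dt <- 6 * tau / n                     # six time constants
  tr <- gen_monoexp(A, tau, C = 0, n = n, dt = dt)
  # slope of A e^(-t/tau) is -A/tau e^(-t/tau), rising toward zero; the
  # predefined rate -A/(2 tau) is first exceeded at t = tau ln 2
  thr <- -A / (2 * tau)
  t_true <- tau * log(2)
  cr <- threshold_crossing(tr, region(1, n), rate_threshold = thr, window_ms = dt)
  c(threshold = abs(cr$time - t_true) <= dt)
}

validate_gaussian_once <- function(A, mu, sigma, C, n) {
  dt <- (mu + 5 * sigma) / n
  x <- (seq_len(n) - 1) * dt
  tr <- trace(A * exp(-(x - mu)^2 / (2 * sigma^2)) + C, dt = dt)
  # baseline region ends 4 sigma before the pulse centre
  bl_end <- max(2L, as.integer(floor((mu - 4 * sigma) / dt)))
  bl <- measure_baseline(tr, region(1, bl_end))
  pk <- measure_peak(tr, bl, region(1, n), direction = "up")
  rise <- measure_rise_time(tr, bl, pk)
  half <- measure_half_duration(tr, bl, pk)
  rise_true <- sigma * (sqrt(2 * log(5)) - sqrt(2 * log(1.25)))
  half_true <- 2 * sigma * sqrt(2 * log(2))
  slope_max <- A / (sigma * exp(0.5))   # max |dy/dt| of the pulse
  c(baseline = abs(bl$mean - C) <= max(A * exp(-8), slope_max * dt),
    peak = abs(pk$value - A) <= slope_max * dt,
    rise = abs(rise$duration - rise_true) <= dt,
    half = abs(half$width - half_true) <= dt)
}

#' Randomized analytic validation of the principal measurements
#'
#' Generates `n_per_family` traces per analytic family — sines (peak, rise
#' time, half duration, maximal slopes), mono-exponentials (slope threshold
#' crossing) and offset Gaussian pulses (baseline, peak, rise, half) — with
#' parameters multiplied by independent N(1, cv) draws, measures each, and
#' checks every measurement against its closed-form value to one sampling
#' point (one dt for times; the signal or slope change across one interval
#' for values).
#'
#' @param n_per_family Traces per family.
#' @param n_samples Samples per trace.
#' @param cv SD of the parameter randomization.
#' @param seed Optional RNG seed.
#' @return Tibble with one row per family: `family`, `n_traces`,
#'   `n_measurements`, `n_pass`, `pct_pass`.
#' @export
validate_measurement_grid <- function(n_per_family = 1000L, n_samples = 1000L,
                                      cv = 0.3, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  run_family <- function(family, reference, lower, fun) {
    grid <- randomize_params(reference, cv = cv, count = n_per_family,
                             lower = lower)
    res <- purrr::map(grid, fun)
    flags <- unlist(res)
    tibble::tibble(family = family, n_traces = n_per_family,
                   n_measurements = length(flags),
                   n_pass = sum(flags),
                   pct_pass = 100 * mean(flags))
  }
  dplyr::bind_rows(
    run_family("sine", c(A = 10, f = 1), c(1e-3, 1e-3),
               function(p) validate_sine_once(p[["A"]], p[["f"]], n_samples)),
    run_family("monoexp", c(A = 5, tau = 10), c(1e-3, 1e-3),
               function(p) validate_monoexp_once(p[["A"]], p[["tau"]], n_samples)),
    {
      # joint redraw: the pre-pulse baseline region must exist (mu > 5 sigma)
      ref <- c(A = 1, mu = 10, sigma = 1.5, C = 0.5)
      grid <- purrr::map(seq_len(n_per_family), function(i) {
        repeat {
          p <- ref * stats::rnorm(4, 1, cv)
          if (p[["A"]] > 1e-3 && p[["sigma"]] > 1e-3 &&
              p[["mu"]] > 5 * p[["sigma"]]) return(p)
        }
      })
      flags <- unlist(purrr::map(grid, function(p) {
        validate_gaussian_once(p[["A"]], p[["mu"]], p[["sigma"]], p[["C"]], n_samples)
      }))
      tibble::tibble(family = "gaussian", n_traces = n_per_family,
                     n_measurements = length(flags), n_pass = sum(flags),
                     pct_pass = 100 * mean(flags))
    }
  )
}
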