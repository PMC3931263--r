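#' Baseline mean and noise estimate
#'
#' Mean and population standard deviation of the signal over the baseline
#' cursor region. The SD is the population SD (divide by n, not n - 1)
#' because it is used directly as the noise estimate when scaling detection
#' thresholds.
#'
#' @param trace A [trace()].
#' @param region Baseline [region()].
#' @return A one-row tibble with columns `mean`, `sd`, `start`, `end`.
#' @export
measure_baseline <- function(trace, region) {
  stopifnot(is_trace(trace))
  check_region(region, trace)
  y <- trace$samples[region_indices(region)]
  tibble::tibble(mean = mean(y),
                 sd = sqrt(mean((y - mean(y))^2)),
                 start = region$start, end = region$end)
}

#' Peak measurement (local extremum relative to baseline)
#'
#' Finds the extremum of the `n_average`-point moving average of the signal
#' within the peak cursor region. `direction = "up"` takes the maximum,
#' `"down"` the minimum, and `"both"` the largest absolute deviation from the
#' baseline mean (ties resolved toward the earlier sample). The reported
#' `value` is baseline-subtracted; `absolute_value` is in raw signal units.
#'
#' @param trace A [trace()].
#' @param baseline Result of [measure_baseline()].
#' @param region Peak search [region()].
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param n_average Odd number of points in the moving average (1 = raw
#'   samples); averaging suppresses noise when picking the extremum.
#' @return A one-row tibble: `value`, `absolute_value`, `index`, `time`,
#'   `direction`, `n_average`.
#' @export
measure_peak <- function(trace, baseline, region, direction = c("up", "down", "both"),
                         n_average = 1L) {
  stopifnot(is_trace(trace))
  direction <- match.arg(direction)
  check_region(region, trace)
  n_average <- as.integer(n_average)
  if (n_average < 1L || n_average %% 2L == 0L) {
    rlang::abort("`n_average` must be a positive odd integer.",
                 class = "sweepkit_error_argument")
  }
  if (n_average > region$end - region$start + 1L) {
    rlang::abort("`n_average` exceeds the region length.", class = "sweepkit_error_argument")
  }
  idx <- region_indices(region)
  if (n_average == 1L) {
    y <- trace$samples[idx]
  } else {
    half <- (n_average - 1L) %/% 2L
    n <- length(trace$samples)
    # moving average centred on each region sample, truncated at trace edges
    y <- vapply(idx, function(i) {
      mean(trace$samples[max(1L, i - half):min(n, i + half)])
    }, numeric(1))
  }
  rel <- y - baseline$mean
  crit <- switch(direction, up = y, down = -y, both = abs(rel))
  k <- which.max(crit)
  # ties on the smoothed extremum resolve toward the largest raw deviation,
  # then toward the earlier sample (which.max's default)
  ties <- which(crit >= crit[k] - 1e-12 * max(abs(crit[k]), 1))
  if (length(ties) > 1L) {
    raw <- abs(trace$samples[idx[ties]] - baseline$mean)
    k <- ties[which.max(raw)]
  }
  i <- idx[k]
  tibble::tibble(value = rel[k], absolute_value = y[k], index = i,
                 time = trace$t0 + (i - 1L) * trace$dt,
                 direction = direction, n_average = n_average)
}

# Last interpolated crossing of `level` (on the baseline-subtracted,
# peak-normalized signal `a`, a[peak_rel] ~= 1) strictly before `peak_rel`,
# scanning backward from the peak so pre-event noise cannot capture it.
# Returns a fractional index into `a`, or NA if never crossed.
cross_before <- function(a, peak_rel, level) {
  i <- peak_rel
  while (i > 1L) {
    if (a[i - 1L] < level && a[i] >= level) {
      return((i - 1L) + (level - a[i - 1L]) / (a[i] - a[i - 1L]))
    }
    i <- i - 1L
  }
  NA_real_
}

# First interpolated crossing below `level` after the peak (decay side).
cross_after <- function(a, peak_rel, level) {
  n <- length(a)
  i <- peak_rel
  while (i < n) {
    if (a[i] >= level && a[i + 1L] < level) {
      return(i + (a[i] - level) / (a[i] - a[i + 1L]))
    }
    i <- i + 1L
  }
  NA_real_
}

# Normalized amplitude a(t) = (y - baseline)/peak_value over [start, peak],
# shared by rise_time/half_duration. Positive-going regardless of polarity.
normalized_amplitude <- function(trace, baseline, peak, from, to) {
  (trace$samples[from:to] - baseline$mean) / peak$value
}

#' Rise time between peak fractions (default 20 to 80 percent)
#'
#' Times at which the baseline-subtracted signal last crosses
#' `frac_low * |peak|` and `frac_high * |peak|` before the peak, located by
#' linear interpolation between the bracketing samples, and their
#' difference. Interpolation is what achieves one-sampling-point accuracy at
#' low sampling rates.
#'
#' @param trace A [trace()].
#' @param baseline Result of [measure_baseline()].
#' @param peak Result of [measure_peak()] (non-zero `value`).
#' @param frac_low,frac_high Peak fractions in (0, 1), `frac_low < frac_high`.
#' @param search_start First sample index of the rising-phase search (defaults
#'   to the start of the trace).
#' @return One-row tibble: `t_low`, `t_high`, `duration` (ms), `frac_low`,
#'   `frac_high`.
#' @export
measure_rise_time <- function(trace, baseline, peak, frac_low = 0.2, frac_high = 0.8,
                              search_start = 1L) {
  stopifnot(is_trace(trace))
  if (!(frac_low > 0 && frac_high < 1 && frac_low < frac_high)) {
    rlang::abort("Need 0 < frac_low < frac_high < 1.", class = "sweepkit_error_argument")
  }
  if (peak$value == 0) {
    rlang::abort("Peak value is zero; rise time undefined.",
                 class = "sweepkit_error_undefined")
  }
  from <- as.integer(search_start)
  a <- normalized_amplitude(trace, baseline, peak, from, peak$index)
  prel <- peak$index - from + 1L
  xl <- cross_before(a, prel, frac_low)
  xh <- cross_before(a, prel, frac_high)
  if (is.na(xl) || is.na(xh)) {
    rlang::abort("Fraction level is never crossed before the peak.",
                 class = "sweepkit_error_undefined")
  }
  t_low <- trace$t0 + (from - 1L + xl - 1) * trace$dt
  t_high <- trace$t0 + (from - 1L + xh - 1) * trace$dt
  tibble::tibble(t_low = t_low, t_high = t_high, duration = t_high - t_low,
                 frac_low = frac_low, frac_high = frac_high)
}

#' Half duration (full width at half-maximal amplitude)
#'
#' Interpolated crossings of half the baseline-subtracted peak amplitude on
#' each side of the peak, and their difference (the FWHM of the event).
#'
#' @inheritParams measure_rise_time
#' @return One-row tibble: `t_left`, `t_right`, `width` (ms).
#' @export
measure_half_duration <- function(trace, baseline, peak, search_start = 1L) {
  stopifnot(is_trace(trace))
  if (peak$value == 0) {
    rlang::abort("Peak value is zero; half duration undefined.",
                 class = "sweepkit_error_undefined")
  }
  from <- as.integer(search_start)
  a <- normalized_amplitude(trace, baseline, peak, from, length(trace$samples))
  prel <- peak$index - from + 1L
  xl <- cross_before(a, prel, 0.5)
  xr <- cross_after(a, prel, 0.5)
  if (is.na(xl) || is.na(xr)) {
    rlang::abort("Half-maximal level is not crossed on both sides of the peak.",
                 class = "sweepkit_error_undefined")
  }
  t_left <- trace$t0 + (from - 1L + xl - 1) * trace$dt
  t_right <- trace$t0 + (from - 1L + xr - 1) * trace$dt
  tibble::tibble(t_left = t_left, t_right = t_right, width = t_right - t_left)
}

# Fixed-interval slope samples: (y[i + w] - y[i]) / (w dt) for all i with
# both ends inside the region. w = max(1, round(window_ms / dt)): at high
# sampling rates the ~50 us window suppresses the noise amplification that
# adjacent-sample differences suffer; when dt > window_ms it degrades
# gracefully to adjacent samples.
slope_samples <- function(trace, region, window_ms) {
  w <- max(1L, as.integer(round(window_ms / trace$dt)))
  idx <- region_indices(region)
  if (length(idx) < w + 1L) {
    rlang::abort("Region shorter than the slope window.", class = "sweepkit_error_range")
  }
  i <- idx[seq_len(length(idx) - w)]
  list(w = w,
       i = i,
       slope = (trace$samples[i + w] - trace$samples[i]) / (w * trace$dt))
}

#' Maximal slope of rise or decay over a fixed time interval
#'
#' The derivative is estimated as the signal difference across a fixed
#' interval (default 50 us = 0.05 ms) rather than between adjacent samples:
#' at high sampling rates the temporal derivative of the noise grows with
#' rate, and the fixed window keeps the slope estimate and its spread nearly
#' rate-independent. The window is rounded to the nearest whole number of
#' samples (minimum 1).
#'
#' @param trace A [trace()].
#' @param region Search [region()].
#' @param window_ms Derivative interval in ms (default 0.05 = 50 us).
#' @param sign `"rise"` (maximum slope) or `"decay"` (minimum slope).
#' @return One-row tibble: `value` (y-units/ms), `at_time` (ms, midpoint of
#'   the winning interval), `window_ms`, `window_samples`.
#' @export
measure_max_slope <- function(trace, region, window_ms = 0.05,
                              sign = c("rise", "decay")) {
  stopifnot(is_trace(trace))
  sign <- match.arg(sign)
  check_region(region, trace, min_len = 2L)
  s <- slope_samples(trace, region, window_ms)
  k <- if (sign == "rise") which.max(s$slope) else which.min(s$slope)
  tibble::tibble(value = s$slope[k],
                 at_time = trace$t0 + (s$i[k] - 1L + s$w / 2) * trace$dt,
                 window_ms = s$w * trace$dt, window_samples = s$w)
}

#' Threshold crossing by slope
#'
#' First sample in the region where the fixed-window slope reaches a
#' predefined rate — the standard operational definition of action-potential
#' threshold.
#'
#' @inheritParams measure_max_slope
#' @param rate_threshold Slope threshold in y-units/ms.
#' @return One-row tibble: `time` (ms), `value` (y-units at the crossing
#'   sample), `index`.
#' @export
threshold_crossing <- function(trace, region, rate_threshold, window_ms = 0.05) {
  stopifnot(is_trace(trace))
  check_region(region, trace, min_len = 2L)
  s <- slope_samples(trace, region, window_ms)
  k <- which(s$slope >= rate_threshold)
  if (length(k) == 0L) {
    rlang::abort("Slope never exceeds the rate threshold in the region.",
                 class = "sweepkit_error_undefined")
  }
  i <- s$i[k[1]]
  tibble::tibble(time = trace$t0 + (i - 1L) * trace$dt,
                 value = trace$samples[i], index = i)
}

#' Extrapolated event onset ("foot") time
#'
#' Intersection of the baseline with the straight line through the 20% and
#' 80% rise points — the robust estimate of the commencement of a
#' postsynaptic current used for synaptic latencies.
#'
#' @param rise Result of [measure_rise_time()] computed with fractions
#'   0.2/0.8 (any pair works; the extrapolation uses the stored fractions).
#' @return Foot time in ms.
#' @export
foot_time <- function(rise) {
  if (rise$t_high <= rise$t_low) {
    rlang::abort("Degenerate rise (t_high <= t_low); foot undefined.",
                 class = "sweepkit_error_undefined")
  }
  rise$t_low - (rise$frac_low / (rise$frac_high - rise$frac_low)) *
    (rise$t_high - rise$t_low)
}

#' Latency between two measured events
#'
#' Reference-time difference `target - source` under one of three
#' physiological conventions: between peaks, between half-maximal amplitudes
#' on the rising phase, or — the synaptic definition — from the source's
#' maximal rising slope (the time of maximal inward current during the
#' presynaptic action potential) to the target's extrapolated foot.
#'
#' @param source,target [measurement_set] objects from [measure_all()].
#' @param mode `"max_slope_to_foot"` (default, synaptic latency),
#'   `"peak_to_peak"`, or `"half_rise"`.
#' @return Latency in ms.
#' @export
latency <- function(source, target,
                    mode = c("max_slope_to_foot", "peak_to_peak", "half_rise")) {
  mode <- match.arg(mode)
  need <- function(set, field, who) {
    if (is.null(set[[field]])) {
      rlang::abort(sprintf("%s measurement set lacks `%s` (required for mode %s).",
                           who, field, mode), class = "sweepkit_error_argument")
    }
    set[[field]]
  }
  switch(mode,
    peak_to_peak = need(target, "peak", "target")$time - need(source, "peak", "source")$time,
    half_rise =
      # the left FWHM crossing is the half-maximal time on the rising phase
      need(target, "half", "target")$t_left - need(source, "half", "source")$t_left,
    max_slope_to_foot = {
      sr <- need(source, "slope_rise", "source")
      tr <- need(target, "rise", "target")
      foot_time(tr) - sr$at_time
    })
}

#' All principal measurements in one call
#'
#' Runs baseline, peak, rise time, half duration, maximal rising/decaying
#' slopes and (optionally) the slope threshold crossing with mutually
#' consistent intermediate results: rise and half duration use exactly the
#' baseline and peak computed here. Errors from sub-measurements are
#' re-thrown naming the failing measurement.
#'
#' @param trace A [trace()].
#' @param baseline_region,peak_region [region()] cursors for baseline and
#'   peak/kinetics.
#' @param direction Peak polarity (see [measure_peak()]).
#' @param n_average Peak moving-average width.
#' @param frac_low,frac_high Rise-time fractions.
#' @param slope_window_ms Fixed derivative interval in ms.
#' @param rate_threshold Optional slope threshold (y-units/ms) for the
#'   threshold-crossing measurement.
#' @return A `measurement_set`: a list of the sub-result tibbles
#'   (`baseline`, `peak`, `rise`, `half`, `slope_rise`, `slope_decay`,
#'   optionally `threshold`) with a [tidy()] method flattening it to one row.
#' @examples
#' tr <- gen_sine(A = 10, f = 1, n = 10000, dt = 1e-4)
#' ms <- measure_all(tr, region(1, 100), region(1, 10000), direction = "up")
#' tidy(ms)
#' @export
measure_all <- function(trace, baseline_region, peak_region,
                        direction = "both", n_average = 1L,
                        frac_low = 0.2, frac_high = 0.8,
                        slope_window_ms = 0.05, rate_threshold = NULL) {
  stopifnot(is_trace(trace))
  step <- function(what, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Measurement `%s` failed: %s", what, conditionMessage(e)),
                   class = "sweepkit_error_measurement", parent = e)
    })
  }
  bl <- step("baseline", measure_baseline(trace, baseline_region))
  pk <- step("peak", measure_peak(trace, bl, peak_region, direction = direction,
                                  n_average = n_average))
  rise <- step("rise_time", measure_rise_time(trace, bl, pk, frac_low, frac_high,
                                              search_start = peak_region$start))
  half <- step("half_duration", measure_half_duration(trace, bl, pk,
                                                      search_start = peak_region$start))
  sl_r <- step("slope_rise", measure_max_slope(trace, peak_region, slope_window_ms, "rise"))
  sl_d <- step("slope_decay", measure_max_slope(trace, peak_region, slope_window_ms, "decay"))
  out <- list(baseline = bl, peak = pk, rise = rise, half = half,
              slope_rise = sl_r, slope_decay = sl_d)
  if (!is.null(rate_threshold)) {
    out$threshold <- step("threshold",
                          threshold_crossing(trace, peak_region, rate_threshold,
                                             slope_window_ms))
  }
  structure(out, class = "measurement_set", dt = trace$dt)
}

#' @export
print.measurement_set <- function(x, ...) {
  cat("<measurement_set>\n")
  print(tidy(x))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Flatten a measurement set to a one-row tibble
#'
#' @param x A `measurement_set` from [measure_all()].
#' @param ... Unused.
#' @return One-row tibble with columns `baseline_mean`, `baseline_sd`,
#'   `peak_value`, `peak_time`, `rise_t_low`, `rise_t_high`, `rise_time`,
#'   `half_width`, `slope_rise`, `slope_decay`, `foot_time` and, when
#'   measured, `threshold_time`/`threshold_value`.
#' @method tidy measurement_set
#' @export
tidy.measurement_set <- function(x, ...) {
  out <- tibble::tibble(
    baseline_mean = x$baseline$mean, baseline_sd = x$baseline$sd,
    peak_value = x$peak$value, peak_time = x$peak$time,
    rise_t_low = x$rise$t_low, rise_t_high = x$rise$t_high,
    rise_time = x$rise$duration,
    half_width = x$half$width,
    slope_rise = x$slope_rise$value, slope_decay = x$slope_decay$value,
    foot_time = foot_time(x$rise)
  )
  if (!is.null(x$threshold)) {
    out$threshold_time <- x$threshold$time
    out$threshold_value <- x$threshold$value
  }
  out
}
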