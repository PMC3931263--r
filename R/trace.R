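#' Construct a sweep trace
#'
#' A trace is the atom every algorithm in sweepkit operates on: one sweep of
#' uniformly sampled signal values together with its sampling interval.
#' Internally time is always milliseconds and the signal unit is a free label
#' (typically `"mV"` for current clamp or `"pA"` for voltage clamp).
#'
#' @param samples Numeric vector of signal values (at least one sample).
#' @param dt Sampling interval in ms (> 0).
#' @param y_unit Signal unit label, e.g. `"mV"` or `"pA"`.
#' @param t0 Time of the first sample in ms.
#'
#' @return An object of class `sweep_trace`.
#' @examples
#' tr <- trace(sin(2 * pi * seq(0, 1, by = 1e-3)), dt = 1e-3)
#' tr
#' @export
trace <- function(samples, dt, y_unit = "mV", t0 = 0) {
  samples <- as.numeric(samples)
  if (length(samples) < 1L) {
    rlang::abort("`samples` must contain at least one value.", class = "sweepkit_error_argument")
  }
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0) {
    rlang::abort("`dt` must be a single positive number (ms).", class = "sweepkit_error_argument")
  }
  structure(
    list(samples = samples, dt = as.numeric(dt),
         y_unit = as.character(y_unit), t0 = as.numeric(t0)),
    class = "sweep_trace"
  )
}

#' @export
print.sweep_trace <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<sweep_trace> %d samples @ dt = %g ms (%.6g kHz), unit %s, t0 = %g ms\n",
              n, x$dt, 1 / x$dt, x$y_unit, x$t0))
  cat(sprintf("  range [%.6g, %.6g] %s over %.6g ms\n",
              min(x$samples), max(x$samples), x$y_unit, n * x$dt))
  invisible(x)
}

#' @export
length.sweep_trace <- function(x) length(x$samples)

#' Sample times of a trace
#'
#' @param trace A [trace()].
#' @return Numeric vector of times in ms, `t0 + (i - 1) * dt`.
#' @export
trace_times <- function(trace) {
  stopifnot(inherits(trace, "sweep_trace"))
  trace$t0 + (seq_along(trace$samples) - 1) * trace$dt
}

is_trace <- function(x) inherits(x, "sweep_trace")

#' Coerce to a trace
#'
#' Data frames with `time`/`value` columns (times in ms, uniformly spaced) and
#' plain numeric vectors (with an explicit `dt`) convert to [trace()] objects,
#' so tidy pipelines can enter the package's functions directly.
#'
#' @param x Object to coerce.
#' @param ... Passed on to methods; for numeric vectors supply `dt` (and
#'   optionally `y_unit`, `t0`).
#' @return A `sweep_trace`.
#' @export
as_trace <- function(x, ...) UseMethod("as_trace")

#' @export
as_trace.sweep_trace <- function(x, ...) x

#' @rdname as_trace
#' @export
as_trace.numeric <- function(x, ...) trace(x, ...)

#' @rdname as_trace
#' @param y_unit Signal unit label when not carried by `x`.
#' @export
as_trace.data.frame <- function(x, y_unit = "mV", ...) {
  if (!all(c("time", "value") %in% names(x))) {
    rlang::abort("Data frame must have `time` and `value` columns.",
                 class = "sweepkit_error_argument")
  }
  tt <- x$time
  if (length(tt) < 2L) {
    rlang::abort("Need at least two rows to infer the sampling interval.",
                 class = "sweepkit_error_argument")
  }
  dts <- diff(tt)
  dt <- dts[1]
  if (any(abs(dts - dt) > 1e-4 * dt)) {
    rlang::abort("`time` column is not uniformly spaced.", class = "sweepkit_error_format")
  }
  trace(x$value, dt = dt, y_unit = y_unit, t0 = tt[1])
}

#' @importFrom tibble as_tibble
#' @export
tibble::as_tibble

#' @method as_tibble sweep_trace
#' @export
as_tibble.sweep_trace <- function(x, ...) {
  tibble::tibble(time = trace_times(x), value = x$samples)
}

#' Cursor region delimiting part of a sweep
#'
#' Regions play the role of the paired vertical cursors of an oscilloscope
#' display: a contiguous 1-based, inclusive window of sample indices within
#' which a measurement operates.
#'
#' @param start First sample index (1-based, inclusive).
#' @param end Last sample index (inclusive, `>= start`).
#' @return An object of class `sweep_region`.
#' @examples
#' region(1, 100)
#' @export
region <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (length(start) != 1L || length(end) != 1L || is.na(start) || is.na(end) ||
      start < 1L || end < start) {
    rlang::abort("Region requires 1 <= start <= end.", class = "sweepkit_error_range")
  }
  structure(list(start = start, end = end), class = "sweep_region")
}

#' @export
print.sweep_region <- function(x, ...) {
  cat(sprintf("<sweep_region> samples [%d, %d] (%d samples)\n",
              x$start, x$end, x$end - x$start + 1L))
  invisible(x)
}

#' Convert a time window (ms) to a region on a trace
#'
#' Cursor positions given in ms are converted to sample indices by rounding
#' half-up, mirroring how oscilloscope cursors snap to samples.
#'
#' @param trace A [trace()].
#' @param t_start,t_end Window limits in ms (absolute time, i.e. including
#'   `t0`).
#' @return A [region()].
#' @export
region_ms <- function(trace, t_start, t_end) {
  stopifnot(is_trace(trace))
  i1 <- floor((t_start - trace$t0) / trace$dt + 0.5) + 1
  i2 <- floor((t_end - trace$t0) / trace$dt + 0.5) + 1
  n <- length(trace$samples)
  region(max(1, i1), min(n, i2))
}

region_indices <- function(reg) seq.int(reg$start, reg$end)

check_region <- function(reg, trace, min_len = 1L) {
  if (!inherits(reg, "sweep_region")) {
    rlang::abort("Expected a `sweep_region` (see `region()`).",
                 class = "sweepkit_error_argument")
  }
  if (reg$end > length(trace$samples)) {
    rlang::abort(sprintf("Region [%d, %d] exceeds trace length %d.",
                         reg$start, reg$end, length(trace$samples)),
                 class = "sweepkit_error_range")
  }
  if (reg$end - reg$start + 1L < min_len) {
    rlang::abort(sprintf("Region must contain at least %d samples.", min_len),
                 class = "sweepkit_error_range")
  }
  invisible(reg)
}

#' Channel: a set of sweeps sharing acquisition settings
#'
#' @param sweeps A list of [trace()] objects sharing `dt` and `y_unit`.
#' @param name Channel label.
#' @return An object of class `sweep_channel`.
#' @export
channel <- function(sweeps, name = "ch0") {
  if (is_trace(sweeps)) sweeps <- list(sweeps)
  if (length(sweeps) < 1L || !all(vapply(sweeps, is_trace, logical(1)))) {
    rlang::abort("`sweeps` must be a non-empty list of traces.",
                 class = "sweepkit_error_argument")
  }
  dts <- vapply(sweeps, function(s) s$dt, numeric(1))
  units <- vapply(sweeps, function(s) s$y_unit, character(1))
  if (any(abs(dts - dts[1]) > 1e-12 * dts[1]) || any(units != units[1])) {
    rlang::abort("All sweeps in a channel must share dt and y_unit.",
                 class = "sweepkit_error_incompatible")
  }
  structure(list(name = as.character(name), sweeps = sweeps), class = "sweep_channel")
}

#' Recording: channels plus free-form metadata
#'
#' @param channels A [channel()] or list of channels.
#' @param metadata Named character list (date, comment, source file, ...).
#' @return An object of class `sweep_recording`.
#' @export
recording <- function(channels, metadata = list()) {
  if (inherits(channels, "sweep_channel")) channels <- list(channels)
  if (length(channels) < 1L ||
      !all(vapply(channels, inherits, logical(1), "sweep_channel"))) {
    rlang::abort("`channels` must be a non-empty list of channels.",
                 class = "sweepkit_error_argument")
  }
  structure(list(channels = channels, metadata = metadata), class = "sweep_recording")
}

#' @export
print.sweep_recording <- function(x, ...) {
  cat(sprintf("<sweep_recording> %d channel(s)\n", length(x$channels)))
  for (ch in x$channels) {
    cat(sprintf("  %s: %d sweep(s) of %s @ dt = %g ms [%s]\n", ch$name,
                length(ch$sweeps),
                paste(unique(vapply(ch$sweeps, length, integer(1))), collapse = "/"),
                ch$sweeps[[1]]$dt, ch$sweeps[[1]]$y_unit))
  }
  invisible(x)
}
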