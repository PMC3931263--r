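#' Select sweeps from a channel
#'
#' Layer-III sweep selection: keep sweeps either by explicit index or by a
#' quantitative, measurement-based predicate evaluated on each sweep.
#'
#' @param channel A [channel()].
#' @param indices Explicit sweep indices (1-based); duplicates are dropped and
#'   the result is sorted.
#' @param predicate A function `function(trace) -> logical(1)`, typically
#'   wrapping a measurement (e.g. peak amplitude above a cutoff).
#' @return Sorted integer vector of selected sweep indices.
#' @examples
#' ch <- channel(lapply(1:3, function(a) trace(a * sin(seq(0, 6, 0.01)), dt = 0.01)))
#' select_sweeps(ch, predicate = function(tr) max(tr$samples) > 1.5)
#' @export
select_sweeps <- function(channel, indices = NULL, predicate = NULL) {
  stopifnot(inherits(channel, "sweep_channel"))
  n <- length(channel$sweeps)
  if (!is.null(indices)) {
    idx <- sort(unique(as.integer(indices)))
    if (any(idx < 1L | idx > n)) {
      rlang::abort(sprintf("Sweep index out of range 1..%d.", n),
                   class = "sweepkit_error_range")
    }
    return(idx)
  }
  if (is.null(predicate)) {
    return(seq_len(n))
  }
  keep <- vapply(channel$sweeps, function(tr) isTRUE(predicate(tr)), logical(1))
  which(keep)
}

#' Concatenate sweeps into one uninterrupted trace
#'
#' @param traces List of traces sharing `dt` and `y_unit`.
#' @return A single [trace()]; `t0` is taken from the first input.
#' @export
concatenate_sweeps <- function(traces) {
  if (is_trace(traces)) traces <- list(traces)
  if (length(traces) < 1L) {
    rlang::abort("Need at least one trace.", class = "sweepkit_error_argument")
  }
  dts <- vapply(traces, function(s) s$dt, numeric(1))
  units <- vapply(traces, function(s) s$y_unit, character(1))
  if (any(abs(dts - dts[1]) > 1e-12 * dts[1]) || any(units != units[1])) {
    rlang::abort("Cannot concatenate sweeps with different dt or y_unit.",
                 class = "sweepkit_error_incompatible")
  }
  trace(unlist(lapply(traces, `[[`, "samples"), use.names = FALSE),
        dt = dts[1], y_unit = units[1], t0 = traces[[1]]$t0)
}

#' Average sweeps, optionally peak-aligned
#'
#' With `align = "none"` the pointwise mean of equally long sweeps is
#' returned. With `align = "peak"` each sweep is shifted so that its peak
#' sample (sample-resolution, within `search`) coincides before averaging,
#' and the output is trimmed to the window covered by every shifted sweep —
#' the alignment used when building an event template from raw event
#' snippets.
#'
#' @param traces List of traces sharing `dt` and `y_unit`.
#' @param align `"none"` or `"peak"`.
#' @param direction Peak polarity for alignment: `"up"`, `"down"` or
#'   `"both"`.
#' @param search Optional [region()] restricting the peak search.
#' @return A [trace()].
#' @export
average_sweeps <- function(traces, align = c("none", "peak"),
                           direction = "both", search = NULL) {
  align <- match.arg(align)
  if (is_trace(traces)) traces <- list(traces)
  if (length(traces) < 1L) {
    rlang::abort("Need at least one trace to average.", class = "sweepkit_error_argument")
  }
  dts <- vapply(traces, function(s) s$dt, numeric(1))
  units <- vapply(traces, function(s) s$y_unit, character(1))
  if (any(abs(dts - dts[1]) > 1e-12 * dts[1]) || any(units != units[1])) {
    rlang::abort("Cannot average sweeps with different dt or y_unit.",
                 class = "sweepkit_error_incompatible")
  }
  if (align == "none") {
    ns <- vapply(traces, length, integer(1))
    if (length(unique(ns)) != 1L) {
      rlang::abort("align = \"none\" requires sweeps of equal length.",
                   class = "sweepkit_error_incompatible")
    }
    m <- rowMeans(vapply(traces, `[[`, numeric(ns[1]), "samples"))
    return(trace(m, dt = dts[1], y_unit = units[1], t0 = traces[[1]]$t0))
  }
  # peak alignment at sample resolution
  peak_idx <- vapply(traces, function(tr) {
    reg <- if (is.null(search)) region(1, length(tr$samples)) else check_region(search, tr)
    y <- tr$samples[region_indices(reg)]
    k <- switch(direction,
                up   = which.max(y),
                down = which.min(y),
                both = which.max(abs(y - mean(y))))
    reg$start + k - 1L
  }, integer(1))
  pre <- min(peak_idx) - 1L
  post <- min(vapply(traces, length, integer(1)) - peak_idx)
  mat <- vapply(seq_along(traces), function(i) {
    traces[[i]]$samples[(peak_idx[i] - pre):(peak_idx[i] + post)]
  }, numeric(pre + post + 1L))
  trace(rowMeans(mat), dt = dts[1], y_unit = units[1],
        t0 = traces[[1]]$t0 + (min(peak_idx) - 1L) * dts[1])
}

#' Subtract the baseline mean over a cursor region
#'
#' @param trace A [trace()].
#' @param region Baseline [region()].
#' @return The trace with `mean(samples[region])` subtracted everywhere.
#' @export
subtract_baseline <- function(trace, region) {
  stopifnot(is_trace(trace))
  check_region(region, trace)
  b <- mean(trace$samples[region_indices(region)])
  trace(trace$samples - b, dt = trace$dt, y_unit = trace$y_unit, t0 = trace$t0)
}

# -3 dB Gaussian kernel: time-domain sigma (ms) for cutoff fc (kHz).
# |H(fc)| = 2^(-1/2)  =>  sigma_t = sqrt(ln 2) / (2 pi fc)
gaussian_sigma_ms <- function(fc_khz) sqrt(log(2)) / (2 * pi * fc_khz)

#' Zero-phase Gaussian low-pass filter
#'
#' Smooths a trace with a symmetric (hence zero-phase) Gaussian kernel whose
#' half-power (-3 dB) frequency is `fc_khz`. Zero phase matters here: latency
#' and onset measurements must not be shifted by filtering. Edges are handled
#' by replicating the end samples, and the kernel is normalized so DC gain is
#' exactly 1.
#'
#' @param trace A [trace()].
#' @param fc_khz Cutoff (half-power) frequency in kHz; must be below the
#'   Nyquist frequency `1/(2 dt)`.
#' @return Filtered [trace()] of identical length.
#' @export
lowpass_filter <- function(trace, fc_khz) {
  stopifnot(is_trace(trace))
  nyquist <- 1 / (2 * trace$dt)
  if (!is.numeric(fc_khz) || length(fc_khz) != 1L || fc_khz <= 0 || fc_khz >= nyquist) {
    rlang::abort(sprintf("`fc_khz` must lie in (0, Nyquist = %g kHz).", nyquist),
                 class = "sweepkit_error_argument")
  }
  sigma <- gaussian_sigma_ms(fc_khz) / trace$dt   # in samples
  half <- max(1L, ceiling(4 * sigma))
  k <- exp(-0.5 * ((-half:half) / sigma)^2)
  k <- k / sum(k)
  y <- trace$samples
  padded <- c(rep(y[1], half), y, rep(y[length(y)], half))
  # direct convolution: the kernel is short, and this avoids FFT length
  # pathologies on arbitrary trace lengths
  sm <- stats::filter(padded, k, method = "convolution", sides = 2)
  sm <- as.numeric(sm[(half + 1L):(half + length(y))])
  trace(sm, dt = trace$dt, y_unit = trace$y_unit, t0 = trace$t0)
}
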