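# Spontaneous-event detection: sliding template matching (least-squares fit
# of a scaled + offset template at every position, with the correlation and
# scale detection criteria) and FFT deconvolution with all-point-histogram
# thresholding.

#' Construct an event template
#'
#' A template is the time course of a typical event: baseline 0, extremum
#' normalized to magnitude 1 with the event polarity retained, sampled at
#' the same interval as the target trace.
#'
#' @param waveform Numeric samples (first sample near 0).
#' @param dt Sampling interval in ms.
#' @return An object of class `event_template`.
#' @export
event_template <- function(waveform, dt) {
  waveform <- as.numeric(waveform)
  if (length(waveform) < 2L || dt <= 0) {
    rlang::abort("Template needs >= 2 samples and dt > 0.",
                 class = "sweepkit_error_argument")
  }
  pk <- which.max(abs(waveform))
  if (abs(waveform[pk]) == 0) {
    rlang::abort("Template has zero amplitude.", class = "sweepkit_error_argument")
  }
  w <- waveform / abs(waveform[pk])
  if (abs(w[1]) >= 0.05) {
    rlang::warn("Template does not start near baseline (|first sample| >= 0.05).")
  }
  structure(list(waveform = w, dt = dt, n = length(w), peak_index = pk),
            class = "event_template")
}

#' @export
print.event_template <- function(x, ...) {
  cat(sprintf("<event_template> %d samples @ %g ms, polarity %s, peak at %.3g ms\n",
              x$n, x$dt, if (x$waveform[x$peak_index] > 0) "up" else "down",
              (x$peak_index - 1) * x$dt))
  invisible(x)
}

# 20-80% rise time of the template magnitude, used as the default
# minimum inter-event interval.
template_rise_ms <- function(template) {
  a <- abs(template$waveform) / max(abs(template$waveform))
  pk <- which.max(a)
  xl <- cross_before(a, pk, 0.2)
  xh <- cross_before(a, pk, 0.8)
  if (is.na(xl) || is.na(xh)) return(template$dt)
  (xh - xl) * template$dt
}

#' Build a template from large events in a trace
#'
#' Bootstrap template construction: find peaks beyond `k_sd` baseline SDs
#' (all-point mean and SD of the trace), extract windows `[-pre_ms,
#' +post_ms]` around each, peak-align and average them, and fit the average
#' with a delayed bi-exponential event model (rising times decaying
#' exponential). The fitted curve from its onset onward, normalized to
#' magnitude 1, becomes the template.
#'
#' @param trace A [trace()].
#' @param k_sd Detection threshold for the bootstrap peaks, in all-point
#'   SDs from the mean (default 5).
#' @param pre_ms,post_ms Window before/after each candidate peak, ms.
#' @param polarity `"down"` (inward currents; default) or `"up"`.
#' @param align_fc_khz Cutoff of the Gaussian low-pass used only for
#'   candidate search and peak alignment (`NULL` to align on raw samples).
#' @return An `event_template`; the fitted model is attached as attribute
#'   `"fit"` and the number of averaged events as `"n_events"`.
#' @export
make_template <- function(trace, k_sd = 5, pre_ms = 2, post_ms = 10,
                          polarity = c("down", "up"), align_fc_khz = 0.5) {
  stopifnot(is_trace(trace))
  polarity <- match.arg(polarity)
  y <- trace$samples
  # candidate peaks are searched and aligned on a smoothed copy of the
  # trace: picking raw noisy extrema jitters the alignment and smears the
  # rising phase of the average
  ys <- if (!is.null(align_fc_khz) && align_fc_khz < 1 / (2 * trace$dt)) {
    lowpass_filter(trace, align_fc_khz)$samples
  } else y
  mu <- mean(ys); sd_all <- stats::sd(ys)
  thr <- if (polarity == "down") mu - k_sd * sd_all else mu + k_sd * sd_all
  beyond <- if (polarity == "down") ys < thr else ys > thr
  pre <- as.integer(round(pre_ms / trace$dt))
  post <- as.integer(round(post_ms / trace$dt))
  if (!any(beyond)) {
    rlang::abort(sprintf("No peaks beyond mean %+g SD; cannot bootstrap a template.",
                         if (polarity == "down") -k_sd else k_sd),
                 class = "sweepkit_error_bootstrap")
  }
  # one candidate peak per contiguous supra-threshold run
  runs <- rle(beyond)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  peaks <- purrr::map_int(which(runs$values), function(j) {
    seg <- starts[j]:ends[j]
    if (polarity == "down") seg[which.min(ys[seg])] else seg[which.max(ys[seg])]
  })
  # prefer isolated exemplary events: drop candidates with a neighbour
  # inside the extraction window (keep everything if too few would remain)
  if (length(peaks) > 5L) {
    gap <- diff(peaks)
    iso <- c(gap > pre + post, TRUE) & c(TRUE, gap > pre + post)
    if (sum(iso) >= 5L) peaks <- peaks[iso]
  }
  peaks <- peaks[peaks - pre >= 1L & peaks + post <= length(y)]
  if (length(peaks) == 0L) {
    rlang::abort("No candidate event fits the extraction window.",
                 class = "sweepkit_error_bootstrap")
  }
  snippets <- purrr::map(peaks, function(p) {
    trace(y[(p - pre):(p + post)], dt = trace$dt, y_unit = trace$y_unit)
  })
  # snippets are cut around their extremum, so they are already
  # peak-aligned at sample `pre + 1`; a plain pointwise mean keeps that
  # alignment even when a second event intrudes into a window
  avg <- average_sweeps(snippets, align = "none")
  # re-zero on the pre-event samples, then fit the event model
  nb <- max(3L, pre %/% 4L)
  avg0 <- subtract_baseline(avg, region(1L, nb))
  fit <- fit_model(avg0, "biexp_with_delay")
  p <- as.list(fit$params)
  t_on <- seq(0, (length(avg0$samples) - 1L) * trace$dt - p$delta, by = trace$dt)
  wave <- fit$model$fun(list(A = p$A, tau1 = p$tau1, tau2 = p$tau2, delta = 0), t_on)
  tpl <- event_template(wave, trace$dt)
  attr(tpl, "fit") <- fit
  attr(tpl, "n_events") <- length(peaks)
  tpl
}

# Cross-correlation sum_k r[s+k-1] p[k] for every window start s, via FFT.
sliding_cross_sum <- function(r, p) {
  N <- length(r); n <- length(p)
  L <- stats::nextn(N + n, c(2, 3, 5))
  R <- stats::fft(c(r, numeric(L - N)))
  P <- stats::fft(c(p, numeric(L - n)))
  cc <- Re(stats::fft(R * Conj(P), inverse = TRUE)) / L
  cc[seq_len(N - n + 1L)]
}

# histogram-based noise SD with a plain-SD fallback for short or
# noise-free series where the all-point histogram cannot be fitted
safe_histogram_sd <- function(vals) {
  tryCatch(histogram_gaussian_sd(vals), error = function(e) {
    structure(max(stats::sd(vals), 1e-12), center = stats::median(vals))
  })
}

new_criterion <- function(values, method, noise_sd, center, valid_n, trace,
                          template) {
  structure(list(values = values, method = method,
                 noise_sd = noise_sd, center = center,
                 valid_range = region(1L, valid_n),
                 dt = trace$dt, t0 = trace$t0,
                 template_peak_lag = template$peak_index - 1L,
                 min_interval_ms = template_rise_ms(template)),
            class = "criterion_trace")
}

#' @export
print.criterion_trace <- function(x, ...) {
  cat(sprintf("<criterion_trace> method %s, %d values (%d valid), noise SD %.4g\n",
              x$method, length(x$values), x$valid_range$end, x$noise_sd))
  invisible(x)
}

#' @method as_tibble criterion_trace
#' @export
as_tibble.criterion_trace <- function(x, ...) {
  i <- seq_len(x$valid_range$end)
  tibble::tibble(time = x$t0 + (i - 1) * x$dt, criterion = x$values[i])
}

#' Sliding-template detection criterion
#'
#' At every window position the template is optimally scaled (factor `m`)
#' and offset (`c`) to minimize the sum of squared errors against the trace
#' window — equivalent to fitting a straight line relating template and
#' data. Two detection criteria are derived from that fit: `"correlation"`,
#' the Pearson correlation between the window and the scaled template, and
#' `"scale"`, the scaling factor normalized by the standard error of the
#' window fit, `m / sqrt(SSE / (n - 1))`. Computed with running sums plus
#' one FFT cross-correlation, so cost is O(N log N) regardless of template
#' length.
#'
#' @param trace A [trace()].
#' @param template An [event_template()] with the same `dt`.
#' @param method `"correlation"` or `"scale"`.
#' @return A `criterion_trace`; values at index `s` refer to the window
#'   starting at sample `s`, and the trailing `n - 1` positions are outside
#'   `valid_range`. Its `noise_sd`/`center` come from
#'   [histogram_gaussian_sd()] on the valid values.
#' @export
template_criterion <- function(trace, template, method = c("correlation", "scale")) {
  stopifnot(is_trace(trace), inherits(template, "event_template"))
  method <- match.arg(method)
  if (abs(template$dt - trace$dt) > 1e-9 * trace$dt) {
    rlang::abort("Template dt must equal trace dt.", class = "sweepkit_error_incompatible")
  }
  p <- template$waveform
  n <- template$n
  N <- length(trace$samples)
  if (n > N) {
    rlang::abort("Template longer than trace.", class = "sweepkit_error_incompatible")
  }
  if (stats::var(p) == 0) {
    rlang::abort("Template has zero variance.", class = "sweepkit_error_argument")
  }
  r <- trace$samples
  Sp <- sum(p); Spp <- sum(p^2)
  cr <- c(0, cumsum(r)); crr <- c(0, cumsum(r^2))
  s <- seq_len(N - n + 1L)
  Sr <- cr[s + n] - cr[s]
  Srr <- crr[s + n] - crr[s]
  Srp <- sliding_cross_sum(r, p)
  sxx <- Spp - Sp^2 / n                # template sum of squares (centred)
  sxy <- Srp - Sr * Sp / n
  syy <- Srr - Sr^2 / n
  m <- sxy / sxx
  sse <- pmax(syy - m * sxy, 0)
  vals <- if (method == "correlation") {
    denom <- sqrt(sxx * pmax(syy, 0))
    ifelse(denom > 0, sxy / denom, 0)
  } else {
    se <- sqrt(sse / (n - 1))
    ifelse(se > 0, m / se, 0)
  }
  hg <- safe_histogram_sd(vals[seq_len(N - n + 1L)])
  new_criterion(vals, method, hg, attr(hg, "center"), N - n + 1L, trace, template)
}

#' Deconvolution detection criterion
#'
#' Estimates the event-onset time course by deconvolving the recorded trace
#' from the template: `f' = IFFT(FFT(r) / FFT(p))`, low-pass filtered with a
#' Gaussian at `lowpass_fc` to regularize the noise amplification inherent
#' in spectral division. Template spectral magnitudes below 1e-6 of the
#' spectral maximum are floored (phase preserved). Isolated events appear in
#' `f'` as sharp positive peaks at their onsets; the detection threshold is
#' scaled by the SD of a Gaussian fitted to the all-point histogram of `f'`.
#'
#' @param trace A [trace()].
#' @param template An [event_template()] with matching `dt`.
#' @param lowpass_fc Regularizing low-pass cutoff in kHz. The default
#'   (0.5, half a typical 1 kHz recording-noise band) reflects that the
#'   inverse filter amplifies noise steeply toward the band edge — for a
#'   bi-exponential template the deconvolved noise density grows roughly as
#'   f^4 — so the criterion's signal-to-noise ratio improves as the cutoff
#'   comes down, while onset spikes stay much narrower than typical
#'   inter-event intervals.
#' @return A `criterion_trace` covering every sample.
#' @export
deconvolution_criterion <- function(trace, template, lowpass_fc = 0.5) {
  stopifnot(is_trace(trace), inherits(template, "event_template"))
  if (abs(template$dt - trace$dt) > 1e-9 * trace$dt) {
    rlang::abort("Template dt must equal trace dt.", class = "sweepkit_error_incompatible")
  }
  N <- length(trace$samples)
  R <- stats::fft(trace$samples)
  P <- stats::fft(c(template$waveform, numeric(N - template$n)))
  mag <- Mod(P)
  floor_mag <- 1e-6 * max(mag)
  low <- mag < floor_mag
  if (any(low)) {
    P[low] <- floor_mag * exp(1i * Arg(P[low]))
  }
  # two-sided frequency axis in kHz
  k <- 0:(N - 1)
  f <- pmin(k, N - k) / (N * trace$dt)
  H <- exp(-0.5 * log(2) * (f / lowpass_fc)^2)
  fprime <- Re(stats::fft(R / P * H, inverse = TRUE)) / N
  hg <- safe_histogram_sd(fprime)
  new_criterion(fprime, "deconvolution", hg, attr(hg, "center"), N, trace, template)
}

#' Noise SD from a Gaussian fit to the all-point histogram
#'
#' Builds the all-point histogram of a detection-criterion series
#' (Freedman-Diaconis bin width) and fits a Gaussian to the bins within two
#' interquartile ranges of the mode, so that the sparse event tail does not
#' inflate the noise estimate. Returns the fitted SD with the fitted center
#' as attribute `"center"`.
#'
#' @param values Numeric vector (>= 1000 values).
#' @return Fitted SD (numeric scalar) with attribute `center`.
#' @export
histogram_gaussian_sd <- function(values) {
  values <- values[is.finite(values)]
  if (length(values) < 1000L) {
    rlang::abort("Need at least 1000 values for a stable all-point histogram.",
                 class = "sweepkit_error_argument")
  }
  iqr <- stats::IQR(values)
  if (iqr == 0 || stats::sd(values) == 0) {
    rlang::abort("Degenerate (near-constant) input.", class = "sweepkit_error_argument")
  }
  bw <- 2 * iqr * length(values)^(-1 / 3)
  # cap the bin count so near-noiseless series (tiny IQR, huge event
  # spikes) stay tractable
  bw <- max(bw, diff(range(values)) / 2000)
  brk <- seq(min(values) - bw, max(values) + bw, by = bw)
  h <- hist(values, breaks = brk, plot = FALSE)
  mode_mid <- h$mids[which.max(h$counts)]
  keep <- abs(h$mids - mode_mid) <= 2 * iqr
  if (sum(keep) < 5L) {
    # too few central bins to fit: widen symmetrically around the mode
    ord <- order(abs(h$mids - mode_mid))
    keep <- seq_along(h$mids) %in% ord[seq_len(min(7L, length(ord)))]
  }
  tr <- trace(h$counts[keep], dt = bw, t0 = h$mids[keep][1])
  gm <- get_model("gaussian")
  start <- c(A = max(h$counts), mu = mode_mid - tr$t0, sigma = max(iqr / 1.349, bw))
  fit <- tryCatch(fit_model(tr, gm, initial = start,
                            options = fit_options(rescale = TRUE)),
                  error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$params[["sigma"]])) {
    # robust fallback when the central mass cannot be fitted
    return(structure(iqr / 1.349, center = mode_mid))
  }
  sd_fit <- abs(unname(fit$params["sigma"]))
  structure(sd_fit, center = unname(fit$params["mu"]) + tr$t0)
}

#' Extract events from a detection-criterion trace
#'
#' Contiguous runs of the criterion above `center + threshold_sd * noise_sd`
#' become candidate events located at the run's criterion maximum; runs
#' whose maxima lie closer than `min_interval_ms` are merged, keeping the
#' larger criterion peak. The reported onset is the criterion-peak position
#' (the window start / deconvolution onset); the event peak follows one
#' template peak latency later.
#'
#' @param criterion A `criterion_trace`.
#' @param threshold_sd Detection threshold in multiples of the criterion
#'   noise SD (typical values: 2.5 for template matching, 4-4.5 for
#'   deconvolution).
#' @param min_interval_ms Minimum separation between events; default the
#'   template 20-80% rise time.
#' @return Tibble with one row per event: `onset_index`, `onset_ms`,
#'   `peak_index`, `peak_ms`, `criterion`, `accepted` (all `TRUE`; meant for
#'   downstream curation).
#' @export
detect_events <- function(criterion, threshold_sd, min_interval_ms = NULL) {
  stopifnot(inherits(criterion, "criterion_trace"))
  if (is.null(min_interval_ms)) min_interval_ms <- criterion$min_interval_ms
  thr <- criterion$center + threshold_sd * criterion$noise_sd
  nvalid <- criterion$valid_range$end
  v <- criterion$values[seq_len(nvalid)]
  above <- v > thr
  if (!any(above)) {
    return(tibble::tibble(onset_index = integer(), onset_ms = numeric(),
                          peak_index = integer(), peak_ms = numeric(),
                          criterion = numeric(), accepted = logical()))
  }
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  on <- which(runs$values)
  peak_i <- purrr::map_int(on, function(j) {
    seg <- starts[j]:ends[j]
    seg[which.max(v[seg])]
  })
  peak_v <- v[peak_i]
  # merge events closer than min_interval, keeping the larger criterion
  min_gap <- min_interval_ms / criterion$dt
  keep <- rep(TRUE, length(peak_i))
  if (length(peak_i) > 1L && min_gap > 0) {
    last <- 1L
    for (j in seq_along(peak_i)[-1]) {
      if (peak_i[j] - peak_i[last] < min_gap) {
        if (peak_v[j] > peak_v[last]) {
          keep[last] <- FALSE; last <- j
        } else {
          keep[j] <- FALSE
        }
      } else {
        last <- j
      }
    }
  }
  oi <- peak_i[keep]
  pi <- pmin(oi + criterion$template_peak_lag, length(criterion$values))
  tibble::tibble(
    onset_index = oi,
    onset_ms = criterion$t0 + (oi - 1L) * criterion$dt,
    peak_index = pi,
    peak_ms = criterion$t0 + (pi - 1L) * criterion$dt,
    criterion = peak_v[keep],
    accepted = TRUE)
}

#' Score detections against known event times
#'
#' Greedy one-to-one matching of detected onsets to the nearest true onset
#' within `tolerance_ms` (closest pairs first, ties toward the earlier true
#' event); unmatched detections are false positives, unmatched true events
#' false negatives.
#'
#' @param events Tibble from [detect_events()] (rows with
#'   `accepted = FALSE` are ignored).
#' @param truth_ms Sorted numeric vector of true onset times in ms.
#' @param tolerance_ms Matching tolerance in ms.
#' @return One-row tibble: `n_true`, `n_detected`, `false_positives`,
#'   `false_negatives`, `tolerance_ms`.
#' @export
evaluate_detection <- function(events, truth_ms, tolerance_ms = 2) {
  if (tolerance_ms < 0) {
    rlang::abort("`tolerance_ms` must be >= 0.", class = "sweepkit_error_argument")
  }
  det <- events$onset_ms[events$accepted]
  nt <- length(truth_ms); nd <- length(det)
  if (nd == 0L || nt == 0L) {
    return(tibble::tibble(n_true = nt, n_detected = nd,
                          false_positives = nd, false_negatives = nt,
                          tolerance_ms = tolerance_ms))
  }
  pairs <- expand.grid(d = seq_len(nd), t = seq_len(nt))
  pairs$dist <- abs(det[pairs$d] - truth_ms[pairs$t])
  pairs <- pairs[pairs$dist <= tolerance_ms, ]
  pairs <- pairs[order(pairs$dist, truth_ms[pairs$t]), ]
  used_d <- logical(nd); used_t <- logical(nt); matched <- 0L
  for (i in seq_len(nrow(pairs))) {
    d <- pairs$d[i]; tt <- pairs$t[i]
    if (!used_d[d] && !used_t[tt]) {
      used_d[d] <- TRUE; used_t[tt] <- TRUE; matched <- matched + 1L
    }
  }
  tibble::tibble(n_true = nt, n_detected = nd,
                 false_positives = nd - matched,
                 false_negatives = nt - matched,
                 tolerance_ms = tolerance_ms)
}
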