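test_that("template criterion equals the per-window regression oracle", {
  set.seed(30)
  k <- test_kernel(0.3, 3, 0.1)
  tpl <- event_template(-k, 0.1)
  y <- rnorm(1500)
  tr <- trace(y, dt = 0.1, y_unit = "pA")
  for (m in c("correlation", "scale")) {
    got <- template_criterion(tr, tpl, m)
    want <- brute_criterion(y, tpl$waveform, m)
    nv <- got$valid_range$end
    expect_equal(length(want), nv)
    expect_lt(max(abs(got$values[seq_len(nv)] - want) / pmax(abs(want), 1e-9)), 1e-8)
  }
})

test_that("an exact scaled+offset template gives correlation 1 and the true scale", {
  k <- test_kernel(0.2, 2.5, 0.05)
  tpl <- event_template(-k, 0.05)
  n <- 4000; s0 <- 1000
  y <- rep(7, n)
  y[s0:(s0 + tpl$n - 1L)] <- 3 * tpl$waveform + 7
  tr <- trace(y, dt = 0.05, y_unit = "pA")
  cc <- template_criterion(tr, tpl, "correlation")
  expect_equal(cc$values[s0], 1, tolerance = 1e-9)
  # scale fit at the event: recompute m, c directly
  w <- y[s0:(s0 + tpl$n - 1L)]
  f <- stats::lm(w ~ tpl$waveform)
  expect_equal(unname(stats::coef(f)), c(7, 3), tolerance = 1e-9)
})

test_that("correlation criterion is invariant under positive affine transforms", {
  set.seed(31)
  k <- test_kernel(0.3, 2, 0.1)
  tpl <- event_template(-k, 0.1)
  y <- rnorm(1200)
  c1 <- template_criterion(trace(y, dt = 0.1), tpl, "correlation")
  c2 <- template_criterion(trace(2.5 * y + 11, dt = 0.1), tpl, "correlation")
  nv <- c1$valid_range$end
  expect_equal(c1$values[seq_len(nv)], c2$values[seq_len(nv)], tolerance = 1e-9)
})

test_that("deconvolution recovers isolated and overlapping onsets and is linear", {
  k <- test_kernel(0.2, 2.5, 0.05)
  tpl <- event_template(-k, 0.05)
  n <- 8000
  mk <- function(onsets, amps) {
    y <- numeric(n)
    for (j in seq_along(onsets)) {
      i <- onsets[j]; L <- min(length(k), n - i + 1L)
      y[i:(i + L - 1L)] <- y[i:(i + L - 1L)] - amps[j] * k[1:L]
    }
    trace(y, dt = 0.05, y_unit = "pA")
  }
  # single event: dominant peak at the onset +/- 1 sample
  r1 <- mk(2000, 1)
  d1 <- deconvolution_criterion(r1, tpl)
  expect_lte(abs(which.max(d1$values) - 2000), 1)
  # two events 5 ms (100 samples) apart: two distinct supra-threshold peaks
  r2 <- mk(c(2000, 2100), c(1, 0.8))
  d2 <- deconvolution_criterion(r2, tpl)
  ev <- detect_events(d2, threshold_sd = 4, min_interval_ms = 1)
  expect_equal(nrow(ev), 2L)
  expect_lte(max(abs(sort(ev$onset_index) - c(2000, 2100))), 1)
  # linearity of the criterion values
  d12 <- deconvolution_criterion(mk(c(2000, 2100), c(1, 0.8)), tpl)
  da <- deconvolution_criterion(mk(2000, 1), tpl)
  db <- deconvolution_criterion(mk(2100, 0.8), tpl)
  expect_equal(d12$values, da$values + db$values, tolerance = 1e-8)
})

test_that("all-point-histogram Gaussian SD estimates the noise core robustly", {
  set.seed(32)
  x <- rnorm(2e5, sd = 2)
  expect_equal(as.numeric(histogram_gaussian_sd(x)), 2, tolerance = 0.025)
  expect_error(histogram_gaussian_sd(rep(1, 5000)), class = "sweepkit_error_argument")
  expect_error(histogram_gaussian_sd(rnorm(100)), class = "sweepkit_error_argument")
  # 1% large outliers barely move the central fit
  xo <- c(rnorm(1e5), runif(1e3, 20, 50))
  expect_equal(as.numeric(histogram_gaussian_sd(xo)), 1, tolerance = 0.1)
})

test_that("detect_events thresholds runs, merges close peaks and maps onsets", {
  k <- test_kernel(0.2, 2.5, 0.05)
  tpl <- event_template(-k, 0.05)
  crit <- structure(list(values = c(rep(0, 100), 0, 2, 8, 3, 0, rep(0, 20),
                                    6, 9, 2, rep(0, 80)),
                         method = "deconvolution", noise_sd = 1, center = 0,
                         valid_range = region(1, 209), dt = 0.05, t0 = 0,
                         template_peak_lag = tpl$peak_index - 1L,
                         min_interval_ms = 0.1),
                    class = "criterion_trace")
  ev <- detect_events(crit, threshold_sd = 4)
  expect_equal(nrow(ev), 2L)
  expect_equal(ev$onset_index, c(103L, 127L))
  expect_equal(ev$peak_index, ev$onset_index + tpl$peak_index - 1L)
  # merging keeps the larger criterion peak
  ev2 <- detect_events(crit, threshold_sd = 4, min_interval_ms = 5)
  expect_equal(nrow(ev2), 1L)
  expect_equal(ev2$onset_index, 127L)
  # all-subthreshold criterion yields an empty, well-formed table
  quiet <- structure(list(values = rnorm(1500, sd = 0.1), method = "scale",
                          noise_sd = 1, center = 0, valid_range = region(1, 1500),
                          dt = 0.05, t0 = 0, template_peak_lag = 0L,
                          min_interval_ms = 0.1),
                     class = "criterion_trace")
  expect_equal(nrow(detect_events(quiet, threshold_sd = 6)), 0L)
})

test_that("evaluate_detection matches greedily within tolerance", {
  truth <- c(10, 50, 90)
  mk_ev <- function(onsets) tibble::tibble(onset_ms = onsets,
                                           accepted = TRUE)
  perfect <- evaluate_detection(mk_ev(truth), truth, tolerance_ms = 2)
  expect_equal(perfect$false_positives, 0L)
  expect_equal(perfect$false_negatives, 0L)
  extra <- evaluate_detection(mk_ev(c(truth, 70)), truth, tolerance_ms = 2)
  expect_equal(extra$false_positives, 1L)
  expect_equal(extra$false_negatives, 0L)
  # jitter below tolerance never creates errors
  set.seed(33)
  jit <- truth + runif(3, -1.9, 1.9)
  jj <- evaluate_detection(mk_ev(jit), truth, tolerance_ms = 2)
  expect_equal(jj$false_positives + jj$false_negatives, 0L)
  expect_error(evaluate_detection(mk_ev(truth), truth, tolerance_ms = -1),
               class = "sweepkit_error_argument")
})

test_that("make_template recovers the generating kernel from clean repeated events", {
  k <- test_kernel(0.2, 2.5, 0.05)
  n <- 40000
  y <- numeric(n)
  onsets <- seq(2000, 38000, by = 2000)
  for (i in onsets) y[i:(i + length(k) - 1L)] <- y[i:(i + length(k) - 1L)] - k
  set.seed(34)
  y <- y + rnorm(n, sd = 0.02)
  tr <- trace(y, dt = 0.05, y_unit = "pA")
  tpl <- make_template(tr, k_sd = 5, pre_ms = 2, post_ms = 10)
  L <- min(tpl$n, length(k))
  rms <- sqrt(mean((tpl$waveform[1:L] - (-k[1:L]))^2))
  expect_lt(rms, 0.02)
  expect_lt(abs(tpl$waveform[1]), 0.05)
  expect_equal(max(abs(tpl$waveform)), 1)
  # polarity retained: template is negative-going
  expect_lt(tpl$waveform[tpl$peak_index], 0)
  # no qualifying peak
  expect_error(make_template(trace(rnorm(5000), dt = 0.05), k_sd = 50),
               class = "sweepkit_error_bootstrap")
})
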