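test_that("baseline returns mean and population SD", {
  tr <- trace(rep(5, 50), dt = 0.1)
  bl <- measure_baseline(tr, region(10, 40))
  expect_equal(bl$mean, 5)
  expect_equal(bl$sd, 0)
  expect_equal(measure_baseline(trace(1:4, dt = 1), region(1, 4))$mean, 2.5)
  # population (not sample) SD
  expect_equal(measure_baseline(trace(c(1, 3), dt = 1), region(1, 2))$sd, 1)
  set.seed(10)
  big <- trace(rnorm(1e5), dt = 0.01)
  expect_equal(measure_baseline(big, region(1, 1e5))$sd, 1, tolerance = 0.02)
})

test_that("peak finds the moving-average extremum per direction", {
  sine <- test_sine(A = 10, n = 2000)
  bl <- measure_baseline(sine, region(1, 2000))
  pk <- measure_peak(sine, bl, region(1, 2000), "up")
  expect_equal(pk$value, 10, tolerance = 10 * 2 * pi / 2000)
  neg <- trace(-sine$samples, dt = sine$dt)
  pkd <- measure_peak(neg, measure_baseline(neg, region(1, 2000)),
                      region(1, 2000), "down")
  expect_equal(pkd$value, -10, tolerance = 10 * 2 * pi / 2000)
  # moving-average oracle: n_average = 3 on a lone spike
  sp <- trace(c(0, 0, 9, 0, 0), dt = 1)
  blz <- measure_baseline(sp, region(1, 2))
  pk3 <- measure_peak(sp, blz, region(1, 5), "up", n_average = 3)
  expect_equal(pk3$value, 3)
  expect_equal(pk3$index, 3L)
  expect_error(measure_peak(sp, blz, region(1, 5), n_average = 2),
               class = "sweepkit_error_argument")
})

test_that("rise time matches the analytic sine and ramp values and is scale invariant", {
  sine <- test_sine()
  bl <- measure_baseline(sine, region(1, length(sine)))
  pk <- measure_peak(sine, bl, region(1, length(sine)), "up")
  rise <- measure_rise_time(sine, bl, pk)
  # one period of unit-frequency sine: duration * 2 pi f = 0.23 pi rad
  expect_equal(rise$duration * 2, (asin(0.8) - asin(0.2)) / pi, tolerance = 1e-4)
  expect_equal(round(rise$duration * 2, 2), 0.23)

  ramp <- trace(seq(0, 1, length.out = 101), dt = 0.01)
  blr <- tibble::tibble(mean = 0, sd = 0)
  pkr <- measure_peak(ramp, blr, region(1, 101), "up")
  riser <- measure_rise_time(ramp, blr, pkr)
  expect_equal(riser$duration, 0.6, tolerance = 1e-9)

  # y-scaling leaves the duration unchanged
  big <- trace(ramp$samples * 10, dt = 0.01)
  pkb <- measure_peak(big, blr, region(1, 101), "up")
  expect_equal(measure_rise_time(big, blr, pkb)$duration, riser$duration)

  expect_error(measure_rise_time(ramp, blr, dplyr::mutate(pkr, value = 0)),
               class = "sweepkit_error_undefined")
})

test_that("half duration matches sine, triangle and Gaussian analytic widths", {
  sine <- test_sine()
  bl <- measure_baseline(sine, region(1, length(sine)))
  pk <- measure_peak(sine, bl, region(1, length(sine)), "up")
  half <- measure_half_duration(sine, bl, pk)
  expect_equal(half$width * 2, 2 / 3, tolerance = 1e-4)  # 0.66... pi rad
  expect_equal(round(half$width * 2, 2), 0.67)

  tri <- trace(c(seq(0, 1, length.out = 51), seq(1, 0, length.out = 51)[-1]),
               dt = 0.01)
  bl0 <- tibble::tibble(mean = 0, sd = 0)
  pkt <- measure_peak(tri, bl0, region(1, 101), "up")
  expect_equal(measure_half_duration(tri, bl0, pkt)$width, 0.5, tolerance = 1e-9)

  g <- gen_gaussian_pulse(A = 2, mu = 10, sigma = 1.5, n = 4000, dt = 0.005)
  pkg <- measure_peak(g, bl0, region(1, 4000), "up")
  expect_equal(measure_half_duration(g, bl0, pkg)$width,
               2 * 1.5 * sqrt(2 * log(2)), tolerance = 0.005)
})

test_that("max_slope uses the fixed window and reduces to adjacent differences", {
  ramp <- trace(2 * (0:200) * 0.01, dt = 0.01)
  for (w in c(0.01, 0.05, 0.2)) {
    expect_equal(measure_max_slope(ramp, region(1, 201), w, "rise")$value, 2)
  }
  set.seed(11)
  tr <- trace(rnorm(500), dt = 0.05)
  s <- measure_max_slope(tr, region(1, 500), window_ms = 0.05, sign = "rise")
  expect_equal(s$value, max(diff(tr$samples)) / 0.05)
  sd_ <- measure_max_slope(tr, region(1, 500), window_ms = 0.05, sign = "decay")
  expect_equal(sd_$value, min(diff(tr$samples)) / 0.05)
  # value-like: scales linearly with y
  tr2 <- trace(tr$samples * 3, dt = 0.05)
  expect_equal(measure_max_slope(tr2, region(1, 500), 0.05, "rise")$value,
               3 * s$value)
  expect_error(measure_max_slope(tr, region(1, 1), 0.05, "rise"),
               class = "sweepkit_error_range")
})

test_that("threshold crossing finds the first sample at the rate and errors when never reached", {
  ramp <- trace(2 * (0:100) * 0.05, dt = 0.05)
  cr <- threshold_crossing(ramp, region(1, 101), rate_threshold = 1, window_ms = 0.05)
  expect_equal(cr$index, 1L)
  expect_error(threshold_crossing(ramp, region(1, 101), rate_threshold = 3),
               class = "sweepkit_error_undefined")
  # exhaustive-scan oracle on an exponential rise
  y <- 5 * (1 - exp(-(0:400) * 0.01 / 1.5))
  tr <- trace(y, dt = 0.01)
  w <- 5L  # 0.05 ms
  slopes <- (y[(1 + w):401] - y[1:(401 - w)]) / (w * 0.01)
  oracle <- which(slopes >= 1.5)[1]
  got <- threshold_crossing(tr, region(1, 401), rate_threshold = 1.5)
  expect_equal(got$index, oracle)
})

test_that("foot time extrapolates the 20-80 line to the baseline", {
  # closed form: t_low = 0.2, t_high = 0.8 with fracs 0.2/0.8 => foot at 0
  rise <- tibble::tibble(t_low = 0.2, t_high = 0.8, duration = 0.6,
                         frac_low = 0.2, frac_high = 0.8)
  expect_equal(foot_time(rise), 0)
  # linear ramp from t = 0: foot = onset = 0
  ramp <- trace(pmax(0, ((0:200) - 50)) * 0.01, dt = 0.01)
  bl0 <- tibble::tibble(mean = 0, sd = 0)
  pk <- measure_peak(ramp, bl0, region(1, 201), "up")
  r <- measure_rise_time(ramp, bl0, pk)
  expect_equal(foot_time(r), 0.5, tolerance = 1e-9)  # ramp starts at t = 0.5
  # sigmoid: extrapolated foot precedes the 20% crossing
  sg <- trace(1 / (1 + exp(-((0:400) * 0.01 - 2) / 0.2)), dt = 0.01)
  pks <- measure_peak(sg, bl0, region(1, 401), "up")
  rs <- measure_rise_time(sg, bl0, pks)
  expect_lt(foot_time(rs), rs$t_low)
  expect_error(foot_time(tibble::tibble(t_low = 1, t_high = 1,
                                        frac_low = 0.2, frac_high = 0.8)),
               class = "sweepkit_error_undefined")
})

test_that("latency modes subtract the correct reference times", {
  g <- gen_gaussian_pulse(A = 5, mu = 6, sigma = 1, n = 3000, dt = 0.01)
  ms1 <- measure_all(g, region(1, 100), region(1, 3000), direction = "up")
  expect_equal(latency(ms1, ms1, "peak_to_peak"), 0)
  expect_equal(latency(ms1, ms1, "half_rise"), 0)
  shifted <- trace(gen_gaussian_pulse(A = 5, mu = 7.5, sigma = 1, n = 3000,
                                      dt = 0.01)$samples, dt = 0.01)
  ms2 <- measure_all(shifted, region(1, 100), region(1, 3000), direction = "up")
  expect_equal(latency(ms1, ms2, "peak_to_peak"), 1.5, tolerance = 1e-9)
  expect_equal(latency(ms1, ms2, "half_rise"), 1.5, tolerance = 1e-6)

  # synthetic AP + delayed PSC: synaptic latency = PSC foot - AP max-slope time
  ap <- measure_all(g, region(1, 100), region(1, 3000), direction = "up")
  psc <- measure_all(shifted, region(1, 100), region(1, 3000), direction = "up")
  lat <- latency(ap, psc, "max_slope_to_foot")
  expect_equal(lat, foot_time(psc$rise) - ap$slope_rise$at_time, tolerance = 1e-12)
  expect_error(latency(list(), ms1, "peak_to_peak"), class = "sweepkit_error_argument")
})

test_that("measure_all is internally consistent and names failing measurements", {
  sine <- test_sine()
  ms <- measure_all(sine, region(1, length(sine)), region(1, length(sine)),
                    direction = "up")
  td <- tidy(ms)
  expect_equal(round(td$rise_time * 2, 2), 0.23)
  expect_equal(round(td$half_width * 2, 2), 0.67)
  expect_equal(td$peak_value, 10, tolerance = 0.01)
  expect_equal(td$slope_rise, 2 * pi * 10, tolerance = 0.05)
  expect_equal(td$slope_decay, -2 * pi * 10, tolerance = 0.05)
  # constant trace: the failing measurement is named
  cst <- trace(rep(1, 100), dt = 0.1)
  err <- tryCatch(measure_all(cst, region(1, 10), region(1, 100)),
                  error = function(e) conditionMessage(e))
  expect_match(err, "rise_time|peak")
})

test_that("time-like measurements are y-scale and offset invariant", {
  set.seed(12)
  for (i in 1:5) {
    A <- runif(1, 1, 20)
    sine <- test_sine(A = A, n = 3000)
    scaled <- trace(sine$samples * 7 + 2, dt = sine$dt)
    n <- length(sine)
    ms1 <- measure_all(sine, region(1, n), region(1, n), direction = "up")
    ms2 <- measure_all(scaled, region(1, n), region(1, n), direction = "up")
    expect_equal(ms2$rise$duration, ms1$rise$duration, tolerance = 1e-9)
    expect_equal(ms2$half$width, ms1$half$width, tolerance = 1e-9)
    expect_equal(ms2$peak$value, 7 * ms1$peak$value, tolerance = 1e-9)
    expect_equal(ms2$slope_rise$value, 7 * ms1$slope_rise$value, tolerance = 1e-9)
  }
})

test_that("randomized analytic families pass at one-sampling-point accuracy", {
  res <- validate_measurement_grid(n_per_family = 100, seed = 7)
  expect_equal(res$pct_pass, rep(100, 3))
})
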