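test_that("analytic generators evaluate their formulas exactly", {
  s <- gen_sine(A = 10, f = 1, n = 1000, dt = 1e-3)
  expect_equal(max(s$samples), 10, tolerance = 1e-4)
  expect_equal(s$samples[1], 0)
  m <- gen_monoexp(A = 3, tau = 5, C = 1, n = 100, dt = 0.1)
  expect_equal(m$samples[1], 4)
  g <- gen_gaussian_pulse(A = 2, mu = 5, sigma = 1, n = 1001, dt = 0.01)
  i <- round(5 / 0.01) + 1
  expect_equal(g$samples[i], 2)
  expect_equal(g$samples[i - 100], g$samples[i + 100], tolerance = 1e-12)
  expect_error(gen_monoexp(1, tau = -1, 0, 100, 0.1), class = "sweepkit_error_argument")
  expect_error(gen_gaussian_pulse(1, 5, 0, 100, 0.1), class = "sweepkit_error_argument")
})

test_that("randomize_params draws multiplicative factors reproducibly", {
  ref <- c(A = 2, tau = 5)
  same <- randomize_params(ref, 0, 4)
  expect_true(all(purrr::map_lgl(same, function(p) identical(p, ref))))
  a <- randomize_params(ref, 0.3, 10, seed = 99)
  b <- randomize_params(ref, 0.3, 10, seed = 99)
  expect_identical(a, b)
  big <- randomize_params(c(x = 1), 0.3, 1e5, seed = 1)
  expect_equal(mean(unlist(big)), 1, tolerance = 0.01)
  low <- randomize_params(c(x = 1), 0.3, 500, lower = 0.5, seed = 2)
  expect_true(all(unlist(low) >= 0.5))
  expect_error(randomize_params(ref, -0.1, 5), class = "sweepkit_error_argument")
})

test_that("thermal noise follows sqrt(4 kB T B Z)", {
  expect_equal(thermal_noise_sd(0, 100), 0)
  expect_equal(thermal_noise_sd(100, 100, 298),
               sqrt(4 * 1.380649e-23 * 298 * 1e5 * 1e8))
  expect_equal(thermal_noise_sd(100, 100, 298), 4.06e-4, tolerance = 0.01)
  expect_equal(thermal_noise_sd(40, 50), 2 * thermal_noise_sd(10, 50))
})

test_that("add_noise_and_quantize rounds to the ADC grid and hits the target SD", {
  nm0 <- noise_model(0, 100)
  step <- 2 / 2^16
  expect_equal(step, 3.0517578125e-5)
  on_grid <- trace(c(0, step, -3 * step) * 1e3, dt = 0.01, y_unit = "mV")
  expect_equal(add_noise_and_quantize(on_grid, nm0)$samples, on_grid$samples)
  off_grid <- trace(rep(step * 0.4 * 1e3, 5), dt = 0.01, y_unit = "mV")
  expect_equal(add_noise_and_quantize(off_grid, nm0)$samples, rep(0, 5))
  nm <- noise_model(100, 100)
  sd_mv <- thermal_noise_sd(100, 100) * 1e3
  z <- trace(rep(0, 1e6), dt = 0.01, y_unit = "mV")
  noisy <- add_noise_and_quantize(z, nm, seed = 50)
  expect_equal(stats::sd(noisy$samples), sd_mv, tolerance = 0.01)
  expect_error(add_noise_and_quantize(trace(1:5, dt = 1, y_unit = "pA"), nm),
               class = "sweepkit_error_argument")
})

test_that("resample decimates without interpolation", {
  tr <- trace(rnorm(1000), dt = 0.005)   # 200 kHz
  expect_equal(resample_trace(tr, 200)$samples, tr$samples)
  dn <- resample_trace(tr, 20)
  expect_length(dn$samples, 100L)
  expect_equal(dn$dt, 0.05)
  expect_true(all(dn$samples %in% tr$samples))
  expect_error(resample_trace(dn, 200), class = "sweepkit_error_argument")
})

test_that("the interneuron simulation rests without input and spikes at 1 uA/cm2", {
  rest <- simulate_wang_buzsaki(i_inj_pa = 0, duration_ms = 40, dt = 0.01)
  expect_lt(max(abs(diff(rest$samples))) / 0.01, 1)   # < 1 V/s
  expect_lt(max(rest$samples), -50)
  ap <- simulate_wang_buzsaki(i_inj_pa = 100, duration_ms = 60, dt = 0.01,
                              area_cm2 = 1e-4)
  spikes <- sum(diff(ap$samples > 0) == 1)
  expect_gte(spikes, 2L)
  # step-halving convergence of the maximal slope
  a1 <- simulate_wang_buzsaki(duration_ms = 30, dt = 0.01)
  a2 <- simulate_wang_buzsaki(duration_ms = 30, dt = 0.005)
  s1 <- measure_max_slope(a1, region(1, length(a1$samples)), 0.05, "rise")$value
  s2 <- measure_max_slope(a2, region(1, length(a2$samples)), 0.05, "rise")$value
  expect_equal(s1, s2, tolerance = 0.01)
})

test_that("the EPSC train generator is seeded, Poisson and kernel-exact", {
  sim1 <- gen_epsc_train(duration_s = 3, seed = 60)
  sim2 <- gen_epsc_train(duration_s = 3, seed = 60)
  expect_identical(sim1$trace$samples, sim2$trace$samples)
  expect_identical(sim1$truth, sim2$truth)
  # expected counts: 5 Hz Poisson over 60 s has mean 300
  sim <- gen_epsc_train(duration_s = 60, noise_sd = 0, cv_tau = 0, cv_amp = 0,
                        seed = 61)
  expect_lt(abs(nrow(sim$truth) - 300), 4 * sqrt(300))
  # a single forced event equals the kernel
  one <- gen_epsc_train(duration_s = 0.5, rate_hz = 0.1, noise_sd = 0,
                        cv_tau = 0, cv_amp = 0, seed = 62)
  k <- test_kernel(0.2, 2.5, 0.05)
  if (nrow(one$truth) == 1L) {
    i0 <- floor(one$truth$onset_ms / 0.05) + 1
    got <- one$trace$samples[i0:(i0 + 50)]
    expect_equal(got, -k[1:51], tolerance = 1e-10)
  }
  # inter-event intervals look exponential: mean close to 200 ms
  expect_equal(mean(diff(sim$truth$onset_ms)), 200, tolerance = 0.2)
})

test_that("fixed-window slope estimates are tighter than adjacent-sample ones under noise", {
  base <- simulate_wang_buzsaki(i_inj_pa = 100, duration_ms = 30, dt = 0.005)
  spread <- function(x) diff(stats::quantile(x, c(0.05, 0.95)))
  for (rate in c(100, 200)) {
    dn <- resample_trace(base, rate)
    nm <- noise_model(100, rate / 2)
    est <- purrr::map(1:40, function(i) {
      tr <- add_noise_and_quantize(dn, nm, seed = 7000 + i)
      reg <- region(1, length(tr$samples))
      c(win = measure_max_slope(tr, reg, 0.05, "rise")$value,
        adj = measure_max_slope(tr, reg, tr$dt, "rise")$value)
    })
    win <- purrr::map_dbl(est, "win"); adj <- purrr::map_dbl(est, "adj")
    expect_lt(spread(win), spread(adj))
    # adjacent-sample estimates are biased upward at high rates
    expect_gt(stats::median(adj), stats::median(win))
  }
})
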