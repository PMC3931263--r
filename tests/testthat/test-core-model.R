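test_that("select_sweeps handles predicates, explicit indices and edge cases", {
  ch <- channel(purrr::map(c(1, -1, 2, -2, 3), function(a) {
    trace(a * sin(pi * seq(0, 1, by = 0.01)), dt = 0.01)  # single arch, sign of a
  }))
  peak_up <- function(tr) max(tr$samples) >= abs(min(tr$samples))
  expect_equal(select_sweeps(ch, predicate = peak_up), c(1L, 3L, 5L))
  expect_equal(select_sweeps(ch, indices = c(4, 2, 2)), c(2L, 4L))
  expect_equal(select_sweeps(ch, predicate = function(tr) TRUE), 1:5)
  expect_error(select_sweeps(ch, indices = 9), class = "sweepkit_error_range")
  # selection is always a subset
  expect_lte(length(select_sweeps(ch, predicate = function(tr) runif(1) > 0.5)), 5L)
})

test_that("concatenate_sweeps preserves order, length, and rejects mismatches", {
  a <- trace(rnorm(100), dt = 0.1)
  b <- trace(rnorm(50), dt = 0.1)
  cc <- concatenate_sweeps(list(a, b))
  expect_length(cc$samples, 150L)
  expect_equal(cc$samples, c(a$samples, b$samples))
  expect_equal(concatenate_sweeps(list(a))$samples, a$samples)
  expect_error(concatenate_sweeps(list(a, trace(1:5, dt = 0.2))),
               class = "sweepkit_error_incompatible")
})

test_that("concatenate after splitting is the identity for any split points", {
  set.seed(1)
  y <- rnorm(400)
  tr <- trace(y, dt = 0.05)
  for (cuts in list(c(100), c(37, 205), c(1, 399))) {
    bounds <- c(0, cuts, 400)
    parts <- purrr::map(seq_len(length(bounds) - 1L), function(i) {
      trace(y[(bounds[i] + 1):bounds[i + 1]], dt = 0.05)
    })
    expect_equal(concatenate_sweeps(parts)$samples, y)
  }
})

test_that("average_sweeps averages pointwise and peak-aligns shifted pulses", {
  t1 <- trace(c(0, 2, 4), dt = 1)
  t2 <- trace(c(4, 2, 0), dt = 1)
  expect_equal(average_sweeps(list(t1, t2))$samples, c(2, 2, 2))
  expect_equal(average_sweeps(list(t1, t1))$samples, t1$samples)
  expect_error(average_sweeps(list()), class = "sweepkit_error_argument")
  expect_error(average_sweeps(list(t1, trace(1:5, dt = 1))),
               class = "sweepkit_error_incompatible")

  # two copies of a pulse shifted by 3 samples: the peak-aligned average
  # must equal the pulse over the overlap (brute-force shift-and-mean oracle)
  pulse <- exp(-((1:80) - 30)^2 / 18)
  a <- trace(pulse, dt = 0.1)
  b <- trace(c(rep(0, 3), pulse[1:77]), dt = 0.1)
  avg <- average_sweeps(list(a, b), align = "peak", direction = "up")
  # brute force: shift b back by 3 samples, average over the overlap
  overlap <- 1:77
  oracle <- (pulse[overlap] + c(rep(0, 3), pulse[1:77])[overlap + 3]) / 2
  expect_equal(avg$samples, oracle)
})

test_that("subtract_baseline zeroes the region mean", {
  expect_equal(subtract_baseline(trace(rep(7, 10), dt = 1), region(2, 9))$samples,
               rep(0, 10))
  expect_equal(subtract_baseline(trace(1:4, dt = 1), region(1, 2))$samples,
               c(-0.5, 0.5, 1.5, 2.5))
  set.seed(2)
  tr <- trace(rnorm(500), dt = 0.1)
  out <- subtract_baseline(tr, region(100, 300))
  expect_equal(mean(out$samples[100:300]), 0, tolerance = 1e-12)
  expect_error(subtract_baseline(tr, region(400, 600)), class = "sweepkit_error_range")
})

test_that("averaging commutes with baseline subtraction over a shared region", {
  set.seed(3)
  traces <- purrr::map(1:4, function(i) trace(rnorm(200) + i, dt = 0.1))
  reg <- region(10, 50)
  a <- subtract_baseline(average_sweeps(traces), reg)
  b <- average_sweeps(purrr::map(traces, subtract_baseline, region = reg))
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("lowpass_filter has unit DC gain, attenuates above fc, preserves slow sines", {
  const <- trace(rep(3.2, 1000), dt = 0.02)
  expect_equal(lowpass_filter(const, 1)$samples, const$samples, tolerance = 1e-12)

  set.seed(4)
  wn <- trace(rnorm(2^15), dt = 0.02)          # 50 kHz sampling
  filt <- lowpass_filter(wn, 1)
  pw <- function(x) {
    sp <- Mod(stats::fft(x))^2
    f <- (seq_along(x) - 1) / (length(x) * 0.02)  # kHz
    mean(sp[f > 2 & f < 25])
  }
  expect_gt(pw(wn$samples) / pw(filt$samples), 10)

  # pure sine at fc/10: amplitude preserved within 5%
  tt <- (0:9999) * 0.02
  s <- trace(sin(2 * pi * 0.1 * tt), dt = 0.02)
  out <- lowpass_filter(s, 1)
  mid <- 2000:8000
  amp <- max(abs(out$samples[mid]))
  expect_equal(amp, 1, tolerance = 0.05)

  expect_error(lowpass_filter(s, 30), class = "sweepkit_error_argument")
})

test_that("traces and regions validate their invariants and coerce to/from tibbles", {
  expect_error(trace(numeric(0), dt = 0.1), class = "sweepkit_error_argument")
  expect_error(trace(1:3, dt = 0), class = "sweepkit_error_argument")
  expect_error(region(0, 5), class = "sweepkit_error_range")
  expect_error(region(5, 4), class = "sweepkit_error_range")
  tr <- trace(1:5, dt = 0.5, t0 = 1)
  expect_equal(trace_times(tr), c(1, 1.5, 2, 2.5, 3))
  tb <- as_tibble(tr)
  expect_equal(as_trace(tb)$samples, tr$samples)
  expect_equal(as_trace(tb)$dt, 0.5)
  expect_error(as_trace(data.frame(time = c(0, 1, 2.5), value = 1:3)),
               class = "sweepkit_error_format")
  # region_ms rounds cursor positions half-up
  expect_equal(region_ms(tr, 1.2, 2.8)$start, 1L)
  expect_equal(region_ms(tr, 1.8, 2.3)$start, 3L)
})
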