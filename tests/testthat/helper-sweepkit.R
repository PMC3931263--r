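# Shared fixtures, all generated in code.

# unit-peak difference-of-exponentials EPSC kernel (mirrors the generator's)
test_kernel <- function(tau_on = 0.2, tau_de = 2.5, dt = 0.05) {
  t_end <- tau_de * log(1e5) + 5 * tau_on
  t <- seq(0, t_end, by = dt)
  k <- (1 - exp(-t / tau_on)) * exp(-t / tau_de)
  k / max(k)
}

# dense unit-frequency sine over one period (f in cycles/ms)
test_sine <- function(A = 10, f = 1, n = 10000) {
  gen_sine(A = A, f = f, n = n, dt = 1 / (f * n))
}

# naive per-window regression criteria, the independent oracle for
# template_criterion
brute_criterion <- function(y, p, method) {
  n <- length(p)
  vapply(seq_len(length(y) - n + 1L), function(s) {
    w <- y[s:(s + n - 1L)]
    if (method == "correlation") return(stats::cor(w, p))
    f <- stats::lm(w ~ p)
    unname(stats::coef(f)[2]) / sqrt(sum(stats::resid(f)^2) / (n - 1))
  }, numeric(1))
}

# naive column extrema by explicit looping, oracle for column_extrema
brute_extrema <- function(x, w) {
  n <- length(x)
  bounds <- floor((0:w) * n / w)
  t(vapply(seq_len(w), function(k) {
    seg <- x[(bounds[k] + 1):bounds[k + 1]]
    c(min(seg), max(seg))
  }, numeric(2)))
}

small_recording <- function() {
  recording(list(
    channel(list(gen_sine(10, 1, 200, 0.1), gen_sine(5, 1, 200, 0.1),
                 gen_sine(2, 1, 200, 0.1)), "Vm"),
    channel(gen_monoexp(5, 10, 0, 200, 0.1, y_unit = "pA"), "Im")
  ), metadata = list(comment = "fixture"))
}
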