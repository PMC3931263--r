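# Parametric model library. Each model is a `sweep_model` carrying its
# formula, parameter names/bounds, a measurement-derived initial-estimate
# strategy, and the reference parameters + sampling used by the validation
# grids. Time is measured from the start of the fit region, in ms.

new_model <- function(name, param_names, fun, init_fun,
                      lower, upper, reference, val_dt, val_tmax) {
  structure(list(name = name, param_names = param_names, fun = fun,
                 init_fun = init_fun, lower = lower, upper = upper,
                 reference = reference, val_dt = val_dt, val_tmax = val_tmax),
            class = "sweep_model")
}

#' @export
print.sweep_model <- function(x, ...) {
  cat(sprintf("<sweep_model> %s(%s)\n", x$name, paste(x$param_names, collapse = ", ")))
  invisible(x)
}

# ---- measurement helpers shared by the init strategies -------------------

# Principal measurements on the fit window: baseline from the first few
# samples, extremum, interpolated 20-80% rise and FWHM. Any piece that is
# undefined for a given waveform comes back NA and the init strategy falls
# back to cruder moments.
init_measurements <- function(y, dt) {
  n <- length(y)
  tr <- trace(y, dt = dt, t0 = 0)
  # robust baseline for initialization: the median of the window, which sits
  # on the resting level both for onset-from-zero waveforms and for pulses
  # clipped by the window edge (most samples lie on the tail)
  bl <- tibble::tibble(mean = stats::median(y),
                       sd = stats::mad(y), start = 1L, end = n)
  dir <- if (y[which.max(abs(y - bl$mean))] >= bl$mean) "up" else "down"
  pk <- tryCatch(measure_peak(tr, bl, region(1L, n), direction = dir),
                 error = function(e) NULL)
  rise <- tryCatch(measure_rise_time(tr, bl, pk), error = function(e) NULL)
  half <- tryCatch(measure_half_duration(tr, bl, pk), error = function(e) NULL)
  list(baseline = bl, peak = pk, rise = rise, half = half, dt = dt, n = n)
}

# tau of the decay phase by linear regression on log-transformed data,
# restricted to samples after the peak where the offset-corrected signal
# exceeds 5% of the peak (keeps the log well-defined).
log_linear_decay <- function(y, dt, offset = 0, from = 1L) {
  z <- y - offset
  s <- sign(z[which.max(abs(z))])
  z <- z * s
  t <- (seq_along(y) - 1) * dt
  zmax <- max(z[seq_along(z) >= from])
  if (!is.finite(zmax) || zmax <= 0) return(NULL)
  keep <- seq_along(z) >= from & z > 0.05 * zmax
  if (sum(keep) < 3L) return(NULL)
  # amplitude-squared weights: the offset-subtraction bias near the tail is
  # relatively largest where z is smallest, so down-weight it
  fit <- stats::lm.wfit(cbind(1, t[keep]), log(z[keep]), w = z[keep]^2)
  tau <- -1 / unname(fit$coefficients[2])
  if (!is.finite(tau) || tau <= 0) return(NULL)
  list(tau = tau, amp = unname(s * exp(fit$coefficients[1])))
}

# Scale the amplitude parameter so the unit-amplitude model's extremum over
# the fit window matches the measured peak.
scale_to_peak <- function(fun, params, t, target_peak) {
  params[["A"]] <- 1
  v <- fun(params, t)
  vx <- v[which.max(abs(v))]
  if (!is.finite(vx) || vx == 0) return(abs(target_peak))
  target_peak / vx
}

clip_params <- function(p, model) {
  pmin(pmax(p, model$lower + 1e-12), model$upper)
}

# ---- the built-in models -------------------------------------------------

model_registry <- new.env(parent = emptyenv())

register_model <- function(m) assign(m$name, m, envir = model_registry)

#' List or fetch built-in fit models
#'
#' The registry holds the standard waveform models of cellular neuroscience:
#' mono-/bi-exponentials, a delayed bi-exponential (product form), the alpha
#' synapse function A (t/tau) exp(1 - t/tau), Hodgkin-Huxley style m^3 h and
#' m h sodium-conductance transients, and a Gaussian pulse.
#'
#' @param name Model identifier (see `list_models()`).
#' @return `get_model()` returns a `sweep_model`; `list_models()` a character
#'   vector of names.
#' @examples
#' list_models()
#' get_model("alpha_synapse")
#' @export
get_model <- function(name) {
  if (!exists(name, envir = model_registry, inherits = FALSE)) {
    rlang::abort(sprintf("Unknown model `%s`. Available: %s.", name,
                         paste(list_models(), collapse = ", ")),
                 class = "sweepkit_error_argument")
  }
  get(name, envir = model_registry, inherits = FALSE)
}

#' @rdname get_model
#' @export
list_models <- function() sort(ls(model_registry))

#' Evaluate a fit model at given times
#'
#' @param model A `sweep_model` from [get_model()].
#' @param params Named numeric vector of parameter values.
#' @param times Times in ms (measured from the start of the fit region).
#' @return Numeric vector of model values.
#' @examples
#' evaluate_model(get_model("alpha_synapse"), c(A = 13.7, tau = 3.4), 0:10)
#' @export
evaluate_model <- function(model, params, times) {
  stopifnot(inherits(model, "sweep_model"))
  params <- params[model$param_names]
  if (anyNA(params)) {
    rlang::abort(sprintf("Model %s needs parameters: %s.", model$name,
                         paste(model$param_names, collapse = ", ")),
                 class = "sweepkit_error_argument")
  }
  if (any(params < model$lower - 1e-9) || any(params > model$upper + 1e-9)) {
    rlang::abort("Parameters violate model constraints.",
                 class = "sweepkit_error_argument")
  }
  model$fun(as.list(params), times)
}

#' Measurement-derived initial estimates
#'
#' Returns a full starting parameter vector for `model`, derived from the
#' principal measurements of the fit window (peak, time of peak, 20--80%
#' rise time, half duration, extrapolated foot) or, for exponential decays,
#' from linear regression on logarithmically transformed data. Falls back to
#' cruder moment-based guesses where a measurement is undefined for the
#' given waveform.
#'
#' @param model A `sweep_model`.
#' @param trace A [trace()].
#' @param region Fit [region()] (defaults to the whole trace).
#' @return Named numeric vector of initial parameters (within constraints).
#' @export
init_params <- function(model, trace, region = NULL) {
  stopifnot(inherits(model, "sweep_model"), is_trace(trace))
  if (is.null(region)) region <- region(1L, length(trace$samples))
  check_region(region, trace, min_len = length(model$param_names) + 1L)
  y <- trace$samples[region_indices(region)]
  p <- model$init_fun(y, trace$dt)
  clip_params(p[model$param_names], model)
}

local({

  # monoexp: A exp(-t/tau) + C
  register_model(new_model(
    "monoexp", c("A", "tau", "C"),
    fun = function(p, t) p$A * exp(-t / p$tau) + p$C,
    init_fun = function(y, dt) {
      n <- length(y)
      C <- mean(y[max(1L, n - max(3L, n %/% 10L)):n])
      ll <- log_linear_decay(y, dt, offset = C)
      if (is.null(ll)) {
        tau <- n * dt / 3
        A <- y[1] - C
      } else {
        tau <- ll$tau; A <- ll$amp
      }
      c(A = A, tau = tau, C = C)
    },
    lower = c(-Inf, 1e-9, -Inf), upper = c(Inf, Inf, Inf),
    reference = c(A = 1, tau = 10, C = 0), val_dt = 0.05, val_tmax = 60
  ))

  # biexp: A1 exp(-t/tau1) + A2 exp(-t/tau2) + C, tau1 < tau2 by convention
  register_model(new_model(
    "biexp", c("A1", "tau1", "A2", "tau2", "C"),
    fun = function(p, t) p$A1 * exp(-t / p$tau1) + p$A2 * exp(-t / p$tau2) + p$C,
    init_fun = function(y, dt) {
      n <- length(y)
      t <- (seq_len(n) - 1) * dt
      # peel the slow component: full monoexp fit (offset included) on the
      # late half, where the fast component has died away
      half <- n %/% 2L
      slow_fit <- tryCatch({
        f <- fit_model(trace(y[half:n], dt = dt), get_model("monoexp"))
        p <- f$params
        list(tau = unname(p["tau"]),
             amp = unname(p["A"]) * exp((half - 1L) * dt / p[["tau"]]),
             C = unname(p["C"]))
      }, error = function(e) NULL)
      if (is.null(slow_fit)) {
        C <- mean(y[max(1L, n - max(3L, n %/% 10L)):n])
        ll <- log_linear_decay(y, dt, offset = C, from = half)
        slow_fit <- if (is.null(ll)) list(tau = n * dt / 3, amp = y[1] - C, C = C)
                    else c(ll, list(C = C))
      }
      resid <- y - slow_fit$C - slow_fit$amp * exp(-t / slow_fit$tau)
      fast <- log_linear_decay(resid, dt)
      if (is.null(fast)) fast <- list(tau = slow_fit$tau / 5, amp = resid[1])
      c(A1 = fast$amp, tau1 = min(fast$tau, slow_fit$tau),
        A2 = slow_fit$amp, tau2 = slow_fit$tau, C = slow_fit$C)
    },
    lower = c(-Inf, 1e-9, -Inf, 1e-9, -Inf), upper = rep(Inf, 5),
    reference = c(A1 = 1, tau1 = 2, A2 = 0.5, tau2 = 20, C = 0),
    val_dt = 0.05, val_tmax = 100
  ))

  # delayed bi-exponential (product form): 0 before delta, then
  # A (1 - exp(-(t-delta)/tau1)) exp(-(t-delta)/tau2)
  biexp_delay_fun <- function(p, t) {
    td <- t - p$delta
    ifelse(td < 0, 0, p$A * (1 - exp(-td / p$tau1)) * exp(-td / p$tau2))
  }
  register_model(new_model(
    "biexp_with_delay", c("A", "tau1", "tau2", "delta"),
    fun = biexp_delay_fun,
    init_fun = function(y, dt) {
      m <- init_measurements(y, dt)
      pk_t <- if (!is.null(m$peak)) m$peak$time else (which.max(abs(y)) - 1) * dt
      delta <- if (!is.null(m$rise)) max(foot_time(m$rise), 0) else pk_t / 4
      tau1 <- if (!is.null(m$rise)) m$rise$duration / 1.4 else pk_t / 4
      dec <- log_linear_decay(y, dt, from = if (!is.null(m$peak)) m$peak$index else 1L)
      tau2 <- if (!is.null(dec)) dec$tau else length(y) * dt / 4
      p <- list(A = 1, tau1 = tau1, tau2 = tau2, delta = delta)
      t <- (seq_along(y) - 1) * dt
      pkv <- if (!is.null(m$peak)) m$peak$value else y[which.max(abs(y))]
      A <- scale_to_peak(biexp_delay_fun, p, t, pkv)
      c(A = A, tau1 = tau1, tau2 = tau2, delta = delta)
    },
    lower = c(-Inf, 1e-9, 1e-9, 0), upper = rep(Inf, 4),
    reference = c(A = 1, tau1 = 1, tau2 = 10, delta = 1),
    val_dt = 0.02, val_tmax = 80
  ))

  # alpha synapse: A (t/tau) exp(1 - t/tau), peak A at t = tau
  register_model(new_model(
    "alpha_synapse", c("A", "tau"),
    fun = function(p, t) p$A * (t / p$tau) * exp(1 - t / p$tau),
    init_fun = function(y, dt) {
      m <- init_measurements(y, dt)
      if (!is.null(m$peak)) {
        c(A = m$peak$value, tau = max(m$peak$time, dt))
      } else {
        k <- which.max(abs(y))
        c(A = y[k], tau = max((k - 1) * dt, dt))
      }
    },
    lower = c(-Inf, 1e-9), upper = c(Inf, Inf),
    reference = c(A = 1, tau = 5), val_dt = 0.05, val_tmax = 60
  ))

  # HH-style sodium conductance transients
  hh_fun <- function(p, t) p$A * (1 - exp(-t / p$tau_m))^3 * exp(-t / p$tau_h)
  two_gate_fun <- function(p, t) p$A * (1 - exp(-t / p$tau_m)) * exp(-t / p$tau_h)
  gate_init <- function(fun, rise_div) function(y, dt) {
    m <- init_measurements(y, dt)
    pk_i <- if (!is.null(m$peak)) m$peak$index else which.max(abs(y))
    tau_m <- if (!is.null(m$rise)) m$rise$duration / rise_div else (pk_i - 1) * dt / 3
    dec <- log_linear_decay(y, dt, from = pk_i)
    tau_h <- if (!is.null(dec)) dec$tau else length(y) * dt / 4
    p <- list(A = 1, tau_m = max(tau_m, dt / 2), tau_h = tau_h)
    t <- (seq_along(y) - 1) * dt
    pkv <- if (!is.null(m$peak)) m$peak$value else y[which.max(abs(y))]
    A <- scale_to_peak(fun, p, t, pkv)
    c(A = A, tau_m = p$tau_m, tau_h = tau_h)
  }
  register_model(new_model(
    "hh_na_conductance", c("A", "tau_m", "tau_h"),
    fun = hh_fun, init_fun = gate_init(hh_fun, 1.4),
    lower = c(-Inf, 1e-9, 1e-9), upper = rep(Inf, 3),
    reference = c(A = 1, tau_m = 0.5, tau_h = 3),
    val_dt = 0.01, val_tmax = 25
  ))
  register_model(new_model(
    "two_gated_na", c("A", "tau_m", "tau_h"),
    fun = two_gate_fun, init_fun = gate_init(two_gate_fun, 1),
    lower = c(-Inf, 1e-9, 1e-9), upper = rep(Inf, 3),
    reference = c(A = 1, tau_m = 0.5, tau_h = 3),
    val_dt = 0.01, val_tmax = 25
  ))

  # gaussian pulse: A exp(-(t-mu)^2 / (2 sigma^2))
  register_model(new_model(
    "gaussian", c("A", "mu", "sigma"),
    fun = function(p, t) p$A * exp(-(t - p$mu)^2 / (2 * p$sigma^2)),
    init_fun = function(y, dt) {
      m <- init_measurements(y, dt)
      pk_t <- if (!is.null(m$peak)) m$peak$time else (which.max(abs(y)) - 1) * dt
      pk_v <- if (!is.null(m$peak)) m$peak$value else y[which.max(abs(y))]
      if (!is.null(m$half)) {
        sigma <- m$half$width / (2 * sqrt(2 * log(2)))
      } else {
        # moment fallback for pulses clipped by the window
        t <- (seq_along(y) - 1) * dt
        w <- abs(y) / sum(abs(y))
        sigma <- max(sqrt(sum(w * (t - pk_t)^2)), dt)
      }
      c(A = pk_v, mu = pk_t, sigma = sigma)
    },
    lower = c(-Inf, -Inf, 1e-9), upper = rep(Inf, 3),
    reference = c(A = 1, mu = 10, sigma = 2), val_dt = 0.02, val_tmax = 40
  ))
})
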