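# Single-compartment interneuron simulation (Wang & Buzsaki 1996 kinetics):
# fast sodium with instantaneous activation (m = m_inf) and gating rate
# scale phi = 5; used to produce a realistic action-potential waveform for
# the slope-estimator benchmarks.

wb_rates <- function(v) {
  # rate constants in 1/ms, v in mV; the 0/0 removable singularities are
  # handled by the analytic limit
  am <- ifelse(abs(v + 35) < 1e-9, 1, -0.1 * (v + 35) / (exp(-0.1 * (v + 35)) - 1))
  bm <- 4 * exp(-(v + 60) / 18)
  ah <- 0.07 * exp(-(v + 58) / 20)
  bh <- 1 / (exp(-0.1 * (v + 28)) + 1)
  an <- ifelse(abs(v + 34) < 1e-9, 0.1, -0.01 * (v + 34) / (exp(-0.1 * (v + 34)) - 1))
  bn <- 0.125 * exp(-(v + 44) / 80)
  list(am = am, bm = bm, ah = ah, bh = bh, an = an, bn = bn)
}

#' Simulate a single-compartment interneuron action-potential waveform
#'
#' Fast-spiking interneuron membrane model: leak, transient sodium (with
#' instantaneous activation gate m_inf^3 h) and delayed-rectifier potassium
#' (n^4) currents, gating kinetics accelerated by phi = 5, integrated with a
#' fixed-step 4th-order Runge-Kutta scheme. A constant current is injected
#' for the whole duration. With the default membrane area of 1e-4 cm^2, a
#' 100 pA injection corresponds to 1 uA/cm^2 and drives repetitive firing.
#'
#' @param i_inj_pa Injected current in pA.
#' @param duration_ms Simulated time in ms.
#' @param dt Integration and output step in ms (<= 0.01 recommended; larger
#'   values trigger a warning).
#' @param area_cm2 Membrane area in cm^2.
#' @param c_m Specific capacitance in uF/cm^2.
#' @param g_l,g_na,g_k Leak, sodium and potassium peak conductances in
#'   mS/cm^2.
#' @param v0 Initial membrane potential in mV.
#' @return A [trace()] of membrane potential in mV.
#' @examples
#' ap <- simulate_wang_buzsaki(duration_ms = 50, dt = 0.01)
#' @export
simulate_wang_buzsaki <- function(i_inj_pa = 100, duration_ms = 2000, dt = 0.01,
                                  area_cm2 = 1e-4, c_m = 1,
                                  g_l = 0.1, g_na = 35, g_k = 9, v0 = -64) {
  if (dt <= 0 || duration_ms <= 0 || area_cm2 <= 0) {
    rlang::abort("Need positive dt, duration and area.",
                 class = "sweepkit_error_argument")
  }
  if (dt > 0.01) {
    rlang::warn("dt > 0.01 ms may be numerically unstable for this model.")
  }
  e_na <- 55; e_k <- -90; e_l <- -65; phi <- 5
  i_app <- i_inj_pa * 1e-6 / area_cm2   # pA -> uA/cm^2

  deriv <- function(t, state, parms) {
    v <- state[1]; h <- state[2]; nn <- state[3]
    r <- wb_rates(v)
    minf <- r$am / (r$am + r$bm)
    i_na <- g_na * minf^3 * h * (v - e_na)
    i_k <- g_k * nn^4 * (v - e_k)
    i_l <- g_l * (v - e_l)
    list(c((-i_na - i_k - i_l + i_app) / c_m,
           phi * (r$ah * (1 - h) - r$bh * h),
           phi * (r$an * (1 - nn) - r$bn * nn)))
  }
  r0 <- wb_rates(v0)
  state0 <- c(v = v0,
              h = r0$ah / (r0$ah + r0$bh),
              n = r0$an / (r0$an + r0$bn))
  out <- deSolve::rk4(y = state0, times = seq(0, duration_ms, by = dt),
                      func = deriv, parms = NULL)
  v <- out[, "v"]
  if (any(!is.finite(v)) || max(abs(v)) > 500) {
    rlang::abort("Membrane-potential integration diverged; reduce dt.",
                 class = "sweepkit_error_integration")
  }
  trace(as.numeric(v), dt = dt, y_unit = "mV")
}
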