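#' Connor-Stevens neuron parameters
#'
#' The Connor-Stevens model extends Hodgkin-Huxley dynamics with a transient
#' A-type potassium current. Two parameterizations are provided: with the
#' A-current present (`type = 1`, g_a = 47.7 mS, E_l = -22 mV) the model shows
#' Type-I excitability (firing rate rises continuously from zero at the
#' rheobase, a saddle-node bifurcation); with the A-current removed
#' (`type = 2`, g_a = 0 mS, E_l = -72.8 mV) it shows Type-II excitability
#' (firing onset jumps discontinuously to a finite rate, an Andronov-Hopf
#' bifurcation). All conductances are for a 1 cm^2 soma, so currents are in uA
#' and conductances in mS.
#'
#' @param type 1 or 2, selecting the excitability class.
#' @return a list of class `cs_params` with fields `C` (uF), `g_na`, `g_k`,
#'   `g_a`, `g_l` (mS), `e_na`, `e_k`, `e_a`, `e_l` (mV) and `type`.
#' @export
cs_params <- function(type = 1) {
  if (!type %in% c(1, 2)) stop("type must be 1 or 2")
  p <- list(
    C = 1, g_na = 120, g_k = 20,
    e_na = 55, e_k = -72, e_a = -72,
    g_l = 0.3,
    g_a = if (type == 1) 47.7 else 0,
    e_l = if (type == 1) -22 else -72.8,
    type = as.integer(type)
  )
  stopifnot(p$g_na >= 0, p$g_k >= 0, p$g_a >= 0, p$g_l >= 0)
  structure(p, class = "cs_params")
}

#' @export
print.cs_params <- function(x, ...) {
  cat(sprintf("<cs_params> Type-%s: g_a = %g mS, e_l = %g mV (C = %g uF/cm^2)\n",
              if (x$type == 1) "I" else "II", x$g_a, x$e_l, x$C))
  invisible(x)
}

#' Resting equilibrium of the Connor-Stevens model
#'
#' Relaxes the model with zero external input from a subthreshold starting
#' point and returns the final state, used as the default initial condition so
#' that simulations start without an onset transient.
#'
#' @param params a `cs_params` object.
#' @param relax_ms relaxation time in ms.
#' @param step integration step in ms.
#' @return named numeric vector `c(v, m, h, n, a, b)`.
#' @export
cs_resting_state <- function(params, relax_ms = 500, step = 0.02) {
  v0 <- -68
  state0 <- c(v0, .cs_gating_inf_cpp(v0))
  n <- round(relax_ms / step)
  zeros <- numeric(n)
  sim <- .cs_integrate_cpp(unclass(params), state0, step, zeros, zeros)
  k <- length(sim$v)
  out <- c(sim$v[k], sim$gating[k, ])
  names(out) <- c("v", "m", "h", "n", "a", "b")
  out
}

#' Simulate the Connor-Stevens neuron
#'
#' Integrates the membrane equation
#' \deqn{C dV/dt = I_{Na} + I_K + I_A + I_l + I_{noise} + I_{inj}}
#' with fourth-order Runge-Kutta at a fixed step (default 0.02 ms). Input
#' currents are zero-order-held between their samples; they may be supplied on
#' the integration grid or any coarser grid whose period is an integer
#' multiple of `step`.
#'
#' @param params a `cs_params` object.
#' @param i_inj injected current: a `current_trace`, or `NULL` for zero.
#' @param i_noise synaptic noise current: a `current_trace`, or `NULL` for zero.
#' @param step integration step in ms.
#' @param duration simulation length in ms; defaults to the span of `i_inj`.
#' @param v0 initial voltage (mV); `NULL` starts at the resting equilibrium.
#' @param gating0 initial gating vector `c(m, h, n, a, b)`; `NULL` uses the
#'   steady-state values at `v0` (or the relaxed resting state when `v0` is
#'   also `NULL`).
#' @return a list with `voltage` (a `voltage_trace` on the integration grid,
#'   including the initial sample) and `gating` (matrix with columns
#'   m, h, n, a, b).
#' @export
simulate_cs <- function(params, i_inj = NULL, i_noise = NULL, step = 0.02,
                        duration = NULL, v0 = NULL, gating0 = NULL) {
  stopifnot(inherits(params, "cs_params"), step > 0)
  if (is.null(duration)) {
    if (is.null(i_inj)) stop("duration must be given when i_inj is NULL")
    duration <- (length(i_inj$values) - 1) * i_inj$dt
  }
  n_steps <- round(duration / step)
  inj <- expand_input(i_inj, step, n_steps, "i_inj")
  noi <- expand_input(i_noise, step, n_steps, "i_noise")

  if (is.null(v0)) {
    state0 <- if (is.null(gating0)) cs_resting_state(params, step = step)
              else stop("gating0 given without v0")
  } else {
    g <- if (is.null(gating0)) .cs_gating_inf_cpp(v0) else as.numeric(gating0)
    if (length(g) != 5 || any(g < 0 | g > 1))
      stop("gating0 must be 5 values in [0, 1]")
    state0 <- c(v0, g)
  }

  sim <- .cs_integrate_cpp(unclass(params), as.numeric(state0), step, inj, noi)
  colnames(sim$gating) <- c("m", "h", "n", "a", "b")
  list(voltage = voltage_trace(sim$v, dt = step), gating = sim$gating)
}

# hold an input trace on the integration grid (zero-order hold)
expand_input <- function(trace, step, n_steps, what) {
  if (is.null(trace)) return(numeric(n_steps))
  stopifnot(inherits(trace, "trace"))
  ratio <- trace$dt / step
  if (abs(ratio - round(ratio)) > 1e-8)
    stop(sprintf("%s sampling period must be an integer multiple of the integration step", what))
  ratio <- round(ratio)
  vals <- rep(trace$values, each = ratio)
  if (length(vals) < n_steps)
    stop(sprintf("%s does not cover the simulation duration", what))
  vals[seq_len(n_steps)]
}

#' Firing rate as a function of step-current amplitude
#'
#' Simulates the noiseless model from rest under a constant step current of
#' each amplitude and returns the steady firing rate. Spikes in an initial
#' settle window are discarded so that a single onset transient spike (common
#' near the Type-II threshold) does not register as sustained firing.
#'
#' @param params a `cs_params` object.
#' @param amplitudes step amplitudes in uA, sorted ascending.
#' @param step_duration step length in ms.
#' @param settle_ms initial window excluded from the rate computation.
#' @param threshold spike detection threshold (mV).
#' @return numeric vector of firing rates in Hz, one per amplitude.
#' @export
fi_curve <- function(params, amplitudes, step_duration = 500,
                     settle_ms = 100, threshold = 30) {
  stopifnot(!is.unsorted(amplitudes))
  rest <- cs_resting_state(params)
  vapply(amplitudes, function(a) {
    i <- current_trace(rep(a, round(step_duration / 0.02) + 1), dt = 0.02)
    sim <- simulate_cs(params, i_inj = i, duration = step_duration,
                       v0 = rest[1], gating0 = rest[-1])
    sp <- detect_spikes(sim$voltage, threshold)$times
    sum(sp >= settle_ms) / ((step_duration - settle_ms) / 1000)
  }, numeric(1))
}
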