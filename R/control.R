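#' Controller configuration for receding-horizon control
#'
#' @param horizon lookahead length T in control steps.
#' @param s terminal state-error weight.
#' @param q running state-error weight.
#' @param r input-change weight; keep small but positive (a zero value lets
#'   the optimizer chatter the input between bounds).
#' @param i_max symmetric input bound in uA (the applied current always
#'   satisfies `|I| <= i_max`).
#' @param dt control period in ms.
#' @param max_iter,tol solver iteration cap and stationarity tolerance.
#' @return list of class `mpc_config`.
#' @export
mpc_config <- function(horizon = 5, s = 1, q = 1, r = 0.01,
                       i_max = 100, dt = 0.1, max_iter = 300, tol = 1e-9) {
  stopifnot(horizon >= 1, s >= 0, q >= 0, r >= 0, i_max > 0, dt > 0)
  structure(list(horizon = as.integer(horizon), s = s, q = q, r = r,
                 i_max = i_max, dt = dt, max_iter = as.integer(max_iter),
                 tol = tol),
            class = "mpc_config")
}

#' One receding-horizon optimization step
#'
#' Minimizes the finite-horizon cost
#' \deqn{s\, e_T^2 + \sum_{n=0}^{T-1} \left[ q\, e_{n+1}^2 + r\, \Delta I_{n+1}^2 \right]}
#' over the next `T` injected-current values, subject to the RBFN forecaster
#' as the dynamics constraint and the box constraint `|I| <= i_max`, and
#' returns only the first optimized input (receding horizon). The optimized
#' sequence never costs more than holding the previous input; if the solver
#' fails to improve on that, the hold-previous sequence is returned and
#' `converged` is `FALSE`.
#'
#' @param model an `rbfn_model` used as the dynamics constraint.
#' @param v_history recent measured voltages (oldest first), at least
#'   `seed_length(model)` samples.
#' @param i_prev previously applied input I_0 (uA).
#' @param ref_window next `T` reference voltage values.
#' @param cfg an `mpc_config`.
#' @param warm_start optional length-`T` initial guess (typically the previous
#'   solution shifted by one step).
#' @return list with `i_next` (first optimized input), `sequence` (full
#'   optimized input), `cost`, `converged`, `iterations`.
#' @export
mpc_step <- function(model, v_history, i_prev, ref_window, cfg,
                     warm_start = NULL) {
  stopifnot(inherits(model, "rbfn_model"), inherits(cfg, "mpc_config"))
  L <- seed_length(model)
  v_history <- as.numeric(v_history)
  if (length(v_history) < L)
    stop("voltage history too short to form an embedded state")
  if (abs(i_prev) > cfg$i_max) stop("i_prev violates the input bound")
  ref_window <- as.numeric(ref_window)
  if (length(ref_window) != cfg$horizon)
    stop("ref_window must have exactly `horizon` values")
  warm <- if (is.null(warm_start)) rep(i_prev, cfg$horizon)
          else as.numeric(warm_start)
  sol <- .mpc_solve_cpp(model$centers, model$weights, model$alpha, model$R,
                        model$dim, model$tau,
                        v_history, i_prev, ref_window,
                        cfg$s, cfg$q, cfg$r, cfg$i_max,
                        warm, cfg$max_iter, cfg$tol)
  list(i_next = sol$input[1], sequence = sol$input, cost = sol$cost,
       converged = sol$converged, iterations = sol$iterations)
}

#' Plant interface for closed-loop control
#'
#' A plant is a list with fields `measure()` (current membrane voltage, mV),
#' `step(i)` (apply injected current `i` uA, zero-order-held for one control
#' period, advance, and return the new measured voltage), `dt` (control period
#' in ms) and optionally `substeps` (integration substeps per control period;
#' plants that support it accept a vector of per-substep currents in `step`).
#' `cs_plant()` wraps the Connor-Stevens integrator; arbitrary simulators can
#' be wrapped the same way.
#'
#' @param params a `cs_params` object.
#' @param i_noise a `current_trace` on the integration grid covering the run,
#'   or `NULL` for a noiseless plant.
#' @param dt control period in ms.
#' @param h integration step in ms (`dt` must be an integer multiple).
#' @param state0 initial state `c(v, m, h, n, a, b)`; `NULL` starts at rest.
#' @return a plant object (list of closures) of class `plant`.
#' @export
cs_plant <- function(params, i_noise = NULL, dt = 0.1, h = 0.02,
                     state0 = NULL) {
  stopifnot(inherits(params, "cs_params"))
  substeps <- dt / h
  if (abs(substeps - round(substeps)) > 1e-8)
    stop("control period must be an integer multiple of the integration step")
  substeps <- as.integer(round(substeps))
  if (is.null(state0)) state0 <- cs_resting_state(params, step = h)
  ptr <- .cs_plant_new_cpp(unclass(params), as.numeric(state0), h)
  noise_vals <- if (is.null(i_noise)) NULL else {
    if (abs(i_noise$dt - h) > 1e-10)
      stop("plant noise must be sampled on the integration grid")
    i_noise$values
  }
  pos <- 0L  # substeps consumed so far
  step <- function(i) {
    noise <- if (is.null(noise_vals)) numeric(substeps) else {
      if (pos + substeps > length(noise_vals))
        stop("noise current does not cover the requested run length")
      noise_vals[(pos + 1L):(pos + substeps)]
    }
    pos <<- pos + substeps
    if (length(i) == 1L) {
      .cs_plant_step_cpp(ptr, i, noise)
    } else {
      if (length(i) != substeps) stop("per-substep input has the wrong length")
      v <- NA_real_
      for (k in seq_len(substeps))
        v <- .cs_plant_step_cpp(ptr, i[k], noise[k])
      v
    }
  }
  structure(list(measure = function() .cs_plant_voltage_cpp(ptr),
                 step = step, dt = dt, substeps = substeps,
                 state = function() .cs_plant_state_cpp(ptr)),
            class = "plant")
}

#' Wrap a trained forecaster as a plant (model-matched control)
#'
#' Useful for testing: when the controlled system is the forecaster itself,
#' MPC tracking of any reachable reference should be near-exact.
#'
#' @param model an `rbfn_model`.
#' @param v_init initial voltage history (at least `seed_length(model)`
#'   samples, oldest first).
#' @param i0 input assumed before the first step.
#' @param dt nominal control period in ms (one model step per plant step).
#' @return a plant object.
#' @export
ddf_plant <- function(model, v_init, i0 = 0, dt = 0.1) {
  hist <- as.numeric(v_init)
  L <- seed_length(model)
  stopifnot(length(hist) >= L)
  hist <- hist[(length(hist) - L + 1):length(hist)]
  i_prev <- i0
  step <- function(i) {
    s <- hist[length(hist) - (0:(model$dim - 1)) * model$tau]
    v_next <- predict_step(model, s, i_prev, i)
    hist <<- c(hist[-1], v_next)
    i_prev <<- i
    v_next
  }
  structure(list(measure = function() hist[length(hist)],
                 step = step, dt = dt, substeps = NULL),
            class = "plant")
}

#' Result of a control run
#'
#' Pairs the realized voltage with the applied input and the reference, and
#' computes the per-trial metrics (voltage MSE, ISI-distance, SPIKE-distance
#' on threshold-detected spikes).
#'
#' @param voltage realized `voltage_trace` (control grid).
#' @param input applied `current_trace` (same grid and length).
#' @param reference reference `voltage_trace` (same grid and length), or
#'   `NULL` when no reference applies.
#' @param threshold spike detection threshold (mV).
#' @param extra named list merged into the result (solver logs etc.).
#' @return list of class `control_result` with fields `voltage`, `input`,
#'   `reference`, `metrics`.
#' @export
control_result <- function(voltage, input, reference = NULL, threshold = 30,
                           extra = list()) {
  stopifnot(inherits(voltage, "voltage_trace"), inherits(input, "current_trace"))
  if (length(voltage$values) != length(input$values))
    stop("voltage and input traces must have equal length")
  metrics <- if (is.null(reference) || length(voltage$values) == 0) NULL else
    trial_metrics(voltage, reference, threshold = threshold)
  structure(c(list(voltage = voltage, input = input, reference = reference,
                   metrics = metrics), extra),
            class = "control_result")
}

#' @export
print.control_result <- function(x, ...) {
  cat(sprintf("<control_result> %d samples at dt = %g ms; max |I| = %.2f uA\n",
              length(x$voltage$values), x$voltage$dt, max(abs(x$input$values))))
  if (!is.null(x$metrics))
    cat(sprintf("  mse = %.4g mV^2, isi_distance = %.4g, spike_distance = %.4g\n",
                x$metrics$mse, x$metrics$isi_distance, x$metrics$spike_distance))
  invisible(x)
}

#' Run closed-loop model predictive control
#'
#' At every control period the plant voltage is measured, the embedding
#' history is refreshed with the measurement (never with the model's own
#' prediction), one receding-horizon problem is solved, and only its first
#' input is applied to the plant. The first `seed_length(model) - 1` periods
#' apply zero input while the measurement history fills.
#'
#' @param plant a plant object (see [cs_plant()]).
#' @param model an `rbfn_model`.
#' @param ref reference `voltage_trace` on the control grid; the run covers
#'   its full length.
#' @param cfg an `mpc_config`.
#' @param i0 input assumed applied before the first step (uA).
#' @return a `control_result`; `n_fallback` counts steps where the solver
#'   returned the hold-previous fallback.
#' @export
run_mpc <- function(plant, model, ref, cfg = mpc_config(), i0 = 0) {
  stopifnot(inherits(ref, "voltage_trace"))
  n <- length(ref$values)
  if (n == 0) {  # degenerate: nothing to track, no solver calls
    return(control_result(voltage_trace(numeric(0), dt = ref$dt),
                          current_trace(numeric(0), dt = ref$dt), ref))
  }
  if (n == 1) {
    return(control_result(voltage_trace(plant$measure(), dt = ref$dt),
                          current_trace(i0, dt = ref$dt), ref))
  }
  Th <- cfg$horizon
  L <- seed_length(model)
  v <- numeric(n); inp <- numeric(n)
  v[1] <- plant$measure(); inp[1] <- i0
  k <- 1L
  while (k < L && k < n) {            # fill the embedding history
    v[k + 1] <- plant$step(0)
    inp[k + 1] <- 0
    k <- k + 1L
  }
  i_prev <- inp[k]
  warm <- rep(i_prev, Th)
  n_fallback <- 0L
  refv <- ref$values
  while (k < n) {
    idx <- pmin(k + seq_len(Th), n)   # pad the window with the last reference
    sol <- mpc_step(model, v[max(1, k - (L - 1)):k], i_prev, refv[idx], cfg,
                    warm_start = warm)
    if (!sol$converged) n_fallback <- n_fallback + 1L
    i_apply <- sol$i_next
    v[k + 1] <- plant$step(i_apply)
    inp[k + 1] <- i_apply
    i_prev <- i_apply
    warm <- c(sol$sequence[-1], sol$sequence[Th])
    k <- k + 1L
  }
  control_result(voltage_trace(v, dt = ref$dt, t0 = ref$t0),
                 current_trace(inp, dt = ref$dt, t0 = ref$t0), ref,
                 extra = list(n_fallback = n_fallback))
}

#' Proportional feedback control (voltage-clamp style baseline)
#'
#' At each control period the state error is scaled by the gain and clamped:
#' `I = clamp(Kp * (V - Vref), +/- clamp)`.
#'
#' @param plant a plant object.
#' @param ref reference `voltage_trace` on the control grid.
#' @param kp proportional gain (the default -2 pushes the voltage toward the
#'   reference since errors enter as V - Vref).
#' @param clamp symmetric input bound in uA.
#' @return a `control_result`.
#' @export
proportional_control <- function(plant, ref, kp = -2, clamp = 100) {
  stopifnot(inherits(ref, "voltage_trace"))
  n <- length(ref$values)
  v <- numeric(n); inp <- numeric(n)
  v[1] <- plant$measure(); inp[1] <- 0
  for (k in seq_len(n - 1)) {
    i <- kp * (v[k] - ref$values[k])
    i <- min(clamp, max(-clamp, i))
    v[k + 1] <- plant$step(i)
    inp[k + 1] <- i
  }
  control_result(voltage_trace(v, dt = ref$dt, t0 = ref$t0),
                 current_trace(inp, dt = ref$dt, t0 = ref$t0), ref)
}

#' Open-loop replay of a stored current
#'
#' Applies a previously recorded injected current with no feedback. On a
#' noiseless, deterministic plant this reproduces the original trajectory; on
#' a noisy plant the spread across noise instantiations is the baseline level
#' of trial-to-trial variability that feedback control competes against.
#'
#' @param plant a plant object.
#' @param i_stored `current_trace`, sampled either at the plant control period
#'   or at its integration substep grid.
#' @param reference optional reference `voltage_trace` for metric computation.
#' @return a `control_result`.
#' @export
open_loop_replay <- function(plant, i_stored, reference = NULL) {
  stopifnot(inherits(i_stored, "current_trace"))
  dt <- plant$dt
  ratio <- dt / i_stored$dt
  fine <- !is.null(plant$substeps) && abs(ratio - plant$substeps) < 1e-8
  coarse <- abs(ratio - 1) < 1e-8
  if (!fine && !coarse)
    stop("stored current must be sampled at the control period or the substep grid")
  n <- if (!is.null(reference)) length(reference$values)
       else if (coarse) length(i_stored$values)
       else floor((length(i_stored$values) - 1) / plant$substeps) + 1
  v <- numeric(n); inp <- numeric(n)
  v[1] <- plant$measure(); inp[1] <- i_stored$values[1]
  for (k in seq_len(n - 1)) {
    if (coarse) {
      i <- i_stored$values[k]
    } else {
      i <- i_stored$values[((k - 1) * plant$substeps + 1):(k * plant$substeps)]
    }
    v[k + 1] <- plant$step(i)
    inp[k + 1] <- if (coarse) i else i[length(i)]
  }
  control_result(voltage_trace(v, dt = dt), current_trace(inp, dt = dt),
                 reference)
}

#' Open-loop pulse control of spike timing
#'
#' Injects a rectangular current pulse of the given width starting at each
#' requested spike time. The amplitude is a per-neuron-type value found by
#' [calibrate_pulse_amplitude()] so that each pulse elicits exactly one spike
#' on the noiseless plant.
#'
#' @param plant a plant object.
#' @param spike_times requested spike times in ms, sorted.
#' @param width pulse width in ms.
#' @param amplitude pulse amplitude in uA.
#' @param duration run length in ms; defaults to the reference span.
#' @param reference optional reference `voltage_trace` for metric computation.
#' @return a `control_result`.
#' @export
pulse_control <- function(plant, spike_times, width = 2, amplitude,
                          duration = NULL, reference = NULL) {
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) > 1 && any(diff(spike_times) <= width))
    stop("pulses overlap: spike times closer than the pulse width")
  if (is.null(duration)) {
    if (is.null(reference)) stop("give either duration or reference")
    duration <- (length(reference$values) - 1) * reference$dt
  }
  dt <- plant$dt
  n <- round(duration / dt) + 1
  i_vals <- numeric(n)
  for (s in spike_times) {
    j0 <- floor(s / dt) + 1
    j1 <- min(n, floor((s + width) / dt))
    if (j0 > n) stop("requested spike time outside the run")
    i_vals[j0:j1] <- amplitude
  }
  open_loop_replay(plant, current_trace(i_vals, dt = dt), reference)
}

#' Calibrate the pulse amplitude for a neuron type
#'
#' Sweeps a grid of amplitudes on the noiseless plant with a single pulse and
#' returns the smallest amplitude for which the pulse elicits exactly one
#' spike (no failures, no doublets).
#'
#' @param params a `cs_params` object.
#' @param width pulse width in ms.
#' @param grid candidate amplitudes in uA, ascending.
#' @param window trial length in ms for each probe.
#' @return the calibrated amplitude in uA.
#' @export
calibrate_pulse_amplitude <- function(params, width = 2,
                                      grid = seq(5, 95, by = 2.5),
                                      window = 120) {
  for (a in grid) {
    plant <- cs_plant(params)
    res <- pulse_control(plant, spike_times = 40, width = width,
                         amplitude = a, duration = window)
    n_sp <- length(detect_spikes(res$voltage)$times)
    if (n_sp == 1) return(a)
    if (n_sp > 1) break
  }
  stop("no amplitude in the grid produced exactly one spike per pulse")
}

#' Convert a requested spike train into a voltage reference
#'
#' Pastes a spike waveform into a constant subthreshold baseline so that each
#' waveform peak lands on a requested spike time, turning a point process into
#' a trajectory the voltage controllers can track.
#'
#' @param spike_times requested spike times in ms.
#' @param waveform a waveform as returned by [extract_mean_waveform()].
#' @param baseline subthreshold constant level in mV.
#' @param duration reference length in ms.
#' @param dt sampling period in ms (must match the waveform's).
#' @return a `voltage_trace` of class `ReferenceTrajectory` semantics.
#' @export
spikes_to_reference <- function(spike_times, waveform, baseline = -65,
                                duration, dt) {
  w <- as.numeric(waveform)
  wdt <- attr(waveform, "dt")
  if (!is.null(wdt) && abs(wdt - dt) > 1e-10)
    stop("waveform sampling period does not match the reference grid")
  peak <- which.max(w)
  spike_times <- sort(as.numeric(spike_times))
  if (length(spike_times) > 1 &&
      any(diff(spike_times) <= (length(w) - 1) * dt))
    stop("spikes closer than the waveform support would overlap")
  n <- round(duration / dt) + 1
  v <- rep(baseline, n)
  for (s in spike_times) {
    p <- round(s / dt) + 1          # sample index of the requested peak
    j0 <- p - (peak - 1)
    j1 <- j0 + length(w) - 1
    if (j0 < 1 || j1 > n)
      stop("waveform around a requested spike does not fit in the trace")
    v[j0:j1] <- w
  }
  voltage_trace(v, dt = dt)
}

#' Mean spike waveform from a recorded trace
#'
#' Averages spike-aligned snippets (aligned on the detected threshold-crossing
#' sample) over a window around each spike. Spikes whose window extends past
#' the trace are skipped.
#'
#' @param v a `voltage_trace`.
#' @param spikes a `spike_train` detected on `v`.
#' @param window numeric `c(before, after)` in ms around the detection sample.
#' @return numeric waveform with attributes `dt` and `align` (index of the
#'   detection sample within the waveform).
#' @export
extract_mean_waveform <- function(v, spikes, window = c(2, 5)) {
  stopifnot(inherits(v, "voltage_trace"), inherits(spikes, "spike_train"))
  if (length(spikes$times) < 1) stop("no spikes to average")
  nb <- round(window[1] / v$dt); na <- round(window[2] / v$dt)
  snippets <- list()
  for (s in spikes$times) {
    k <- round((s - v$t0) / v$dt) + 1
    if (k - nb < 1 || k + na > length(v$values)) next
    snippets[[length(snippets) + 1]] <- v$values[(k - nb):(k + na)]
  }
  if (length(snippets) == 0) stop("no spike window fits within the trace")
  w <- Reduce(`+`, snippets) / length(snippets)
  attr(w, "dt") <- v$dt
  attr(w, "align") <- nb + 1L
  w
}
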