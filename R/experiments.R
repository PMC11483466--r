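#' Configuration for a control experiment
#'
#' Bundles the study conditions: plant and reference neuron types, number of
#' trials, trial duration, stimulus and noise settings, controller settings
#' and the master seed. Per-trial seeds are derived deterministically from the
#' master seed so every stochastic component is reproducible.
#'
#' @param plant_type neuron type being controlled (1 or 2).
#' @param ref_type neuron type that generates the reference trajectory
#'   (defaults to `plant_type`; set differently for heterogeneous control).
#' @param n_trials number of trials.
#' @param duration trial length in ms.
#' @param lorenz_tau Lorenz time-scale factor.
#' @param amplitudes named amplitudes (uA per unit x) of the chaotic stimulus
#'   for each type.
#' @param snr signal-to-noise ratio sd(stimulus)/sd(noise); `Inf` disables the
#'   noise current.
#' @param noise_rate excitatory and inhibitory Poisson rate in Hz.
#' @param mpc an `mpc_config`.
#' @param kp proportional-controller gain.
#' @param pulse_width pulse width in ms for pulse control.
#' @param h integration step in ms.
#' @param control_dt control period in ms.
#' @param seed master seed.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(plant_type = 1, ref_type = plant_type,
                              n_trials = 10, duration = 500,
                              lorenz_tau = 20,
                              amplitudes = c(`1` = 1.8, `2` = 0.5),
                              snr = 5, noise_rate = 20,
                              mpc = mpc_config(), kp = -2, pulse_width = 2,
                              h = 0.02, control_dt = 0.1, seed = 42) {
  structure(list(plant_type = plant_type, ref_type = ref_type,
                 n_trials = n_trials, duration = duration,
                 lorenz_tau = lorenz_tau, amplitudes = amplitudes,
                 snr = snr, noise_rate = noise_rate, mpc = mpc, kp = kp,
                 pulse_width = pulse_width, h = h, control_dt = control_dt,
                 seed = seed),
            class = "experiment_config")
}

# deterministic per-trial sub-seeds, kept well below 2^31
trial_seed <- function(cfg, trial, component) {
  (cfg$seed %% 100000L) * 10000L + trial * 10L + component
}

# Lorenz initial condition drawn deterministically from a seed; the burn-in
# inside make_lorenz_current lands the trajectory on the attractor.
lorenz_ic <- function(seed) {
  set.seed(seed)
  stats::runif(3, min = c(-15, -20, 5), max = c(15, 20, 40))
}

# chaotic stimulus + matched noise for one trial, on the integration grid
make_trial_inputs <- function(cfg, type, seed_stim, seed_noise) {
  ic <- lorenz_ic(seed_stim)
  inj <- make_lorenz_current(tau = cfg$lorenz_tau,
                             amplitude = cfg$amplitudes[[as.character(type)]],
                             duration = cfg$duration, dt = cfg$h,
                             x0 = ic[1], y0 = ic[2], z0 = ic[3])
  noise <- if (is.infinite(cfg$snr)) NULL else
    make_noise_current(rate_exc = cfg$noise_rate, rate_inh = cfg$noise_rate,
                       duration = cfg$duration, dt = cfg$h,
                       reference = inj, target_snr = cfg$snr,
                       seed = seed_noise)
  list(inj = inj, noise = noise)
}

# simulate a reference response and return it on the control grid
make_reference <- function(cfg, type, inj, noise) {
  sim <- simulate_cs(cs_params(type), i_inj = inj, i_noise = noise,
                     step = cfg$h, duration = cfg$duration)
  downsample(sim$voltage, round(cfg$control_dt / cfg$h))
}

metrics_row <- function(cfg, trial, arm, res, seed_ref, seed_ctl) {
  data.frame(trial = trial, arm = arm,
             plant_type = cfg$plant_type, ref_type = cfg$ref_type,
             mse = res$metrics$mse,
             isi_distance = res$metrics$isi_distance,
             spike_distance = res$metrics$spike_distance,
             max_abs_input = max(abs(res$input$values)),
             n_spikes = length(detect_spikes(res$voltage)$times),
             seed_ref = seed_ref, seed_ctl = seed_ctl)
}

#' Homogeneous control experiment
#'
#' Each trial: a reference trajectory is generated by driving the reference
#' neuron with a chaotic current plus synaptic noise; then (a) MPC steers a
#' fresh noise-instantiated plant to that reference and (b) the generating
#' current is replayed open-loop into another fresh noise-instantiated plant.
#' With `ref_type == plant_type` this is homogeneous control (a neuron tracks
#' a trajectory it previously produced); with different types it is the
#' heterogeneous task, where the open-loop arm injects the other type's
#' generating current.
#'
#' @param model trained `rbfn_model` for the plant type.
#' @param cfg an `experiment_config`.
#' @param results_env optional environment; if given, the per-trial
#'   `control_result` objects are stored there (fields `mpc`, `openloop`).
#' @return data.frame with one row per trial and arm (`mpc` / `openloop`),
#'   carrying the metrics and the seeds that produced them.
#' @export
run_homogeneous <- function(model, cfg = experiment_config(),
                            results_env = NULL) {
  stopifnot(inherits(model, "rbfn_model"), inherits(cfg, "experiment_config"))
  rows <- list()
  keep <- if (is.null(results_env)) NULL else
    list(mpc = list(), openloop = list())
  for (trial in seq_len(cfg$n_trials)) {
    s_stim <- trial_seed(cfg, trial, 1)
    s_ref <- trial_seed(cfg, trial, 2)
    s_mpc <- trial_seed(cfg, trial, 3)
    s_ol <- trial_seed(cfg, trial, 4)
    io <- make_trial_inputs(cfg, cfg$ref_type, s_stim, s_ref)
    ref <- make_reference(cfg, cfg$ref_type, io$inj, io$noise)

    noise_mpc <- if (is.infinite(cfg$snr)) NULL else
      make_noise_current(rate_exc = cfg$noise_rate, rate_inh = cfg$noise_rate,
                         duration = cfg$duration, dt = cfg$h,
                         reference = io$inj, target_snr = cfg$snr, seed = s_mpc)
    plant <- cs_plant(cs_params(cfg$plant_type), i_noise = noise_mpc,
                      dt = cfg$control_dt, h = cfg$h)
    res_mpc <- run_mpc(plant, model, ref, cfg$mpc)

    noise_ol <- if (is.infinite(cfg$snr)) NULL else
      make_noise_current(rate_exc = cfg$noise_rate, rate_inh = cfg$noise_rate,
                         duration = cfg$duration, dt = cfg$h,
                         reference = io$inj, target_snr = cfg$snr, seed = s_ol)
    plant_ol <- cs_plant(cs_params(cfg$plant_type), i_noise = noise_ol,
                         dt = cfg$control_dt, h = cfg$h)
    res_ol <- open_loop_replay(plant_ol, io$inj, reference = ref)

    rows[[length(rows) + 1]] <- metrics_row(cfg, trial, "mpc", res_mpc, s_ref, s_mpc)
    rows[[length(rows) + 1]] <- metrics_row(cfg, trial, "openloop", res_ol, s_ref, s_ol)
    if (!is.null(keep)) {
      keep$mpc[[trial]] <- res_mpc
      keep$openloop[[trial]] <- res_ol
    }
  }
  if (!is.null(results_env)) {
    results_env$mpc <- keep$mpc
    results_env$openloop <- keep$openloop
  }
  out <- do.call(rbind, rows)
  attr(out, "config") <- cfg
  out
}

#' Heterogeneous control experiment (one direction)
#'
#' The reference comes from one neuron type, the plant is the other type.
#' MPC uses the plant type's forecaster; the open-loop arm injects the
#' reference-generating current into the plant.
#'
#' @param model trained `rbfn_model` for the plant type.
#' @param cfg an `experiment_config` with `ref_type != plant_type`.
#' @param results_env optional environment to receive raw results.
#' @return metrics data.frame as in [run_homogeneous()].
#' @export
run_heterogeneous <- function(model, cfg, results_env = NULL) {
  if (cfg$ref_type == cfg$plant_type)
    stop("heterogeneous control needs ref_type != plant_type")
  run_homogeneous(model, cfg, results_env)
}

#' Spike-train control experiment
#'
#' Converts a requested spike train into a voltage reference (mean spike
#' waveform pasted into a subthreshold baseline) and imposes it with three
#' controllers: MPC, proportional feedback and open-loop calibrated pulses.
#'
#' @param model trained `rbfn_model` for the plant type.
#' @param waveform mean spike waveform from [extract_mean_waveform()].
#' @param spike_times requested spike times in ms.
#' @param cfg an `experiment_config` (`snr = Inf` runs the noiseless plant).
#' @param pulse_amplitude pulse amplitude in uA; `NULL` calibrates it with
#'   [calibrate_pulse_amplitude()].
#' @param results_env optional environment to receive raw results.
#' @return data.frame with one row per controller.
#' @export
run_spike_train <- function(model, waveform, spike_times,
                            cfg = experiment_config(snr = Inf),
                            pulse_amplitude = NULL, results_env = NULL) {
  params <- cs_params(cfg$plant_type)
  ref <- spikes_to_reference(spike_times, waveform, baseline = -65,
                             duration = cfg$duration, dt = cfg$control_dt)
  make_noise <- function(component) {
    if (is.infinite(cfg$snr)) return(NULL)
    probe <- make_trial_inputs(cfg, cfg$plant_type,
                               trial_seed(cfg, 1, 1),
                               trial_seed(cfg, 1, component))
    probe$noise
  }
  mk_plant <- function(component) cs_plant(params, i_noise = make_noise(component),
                                           dt = cfg$control_dt, h = cfg$h)

  res_mpc <- run_mpc(mk_plant(5), model, ref, cfg$mpc)
  res_prop <- proportional_control(mk_plant(6), ref, kp = cfg$kp,
                                   clamp = cfg$mpc$i_max)
  if (is.null(pulse_amplitude))
    pulse_amplitude <- calibrate_pulse_amplitude(params, width = cfg$pulse_width)
  res_pulse <- pulse_control(mk_plant(7), spike_times, width = cfg$pulse_width,
                             amplitude = pulse_amplitude, reference = ref)

  if (!is.null(results_env)) {
    results_env$mpc <- res_mpc
    results_env$proportional <- res_prop
    results_env$pulse <- res_pulse
  }
  out <- rbind(
    metrics_row(cfg, 1, "mpc", res_mpc, NA, NA),
    metrics_row(cfg, 1, "proportional", res_prop, NA, NA),
    metrics_row(cfg, 1, "pulse", res_pulse, NA, NA))
  out$pulse_amplitude <- c(NA, NA, pulse_amplitude)
  attr(out, "config") <- cfg
  out
}

#' Train a forecaster for one neuron type
#'
#' The full training pipeline: simulate 5 s of the Connor-Stevens model at a
#' 0.02 ms step driven by the chaotic Lorenz stimulus (amplitude 1.8 uA for
#' Type I, 0.5 uA for Type II) plus SNR-5 synaptic noise; downsample voltage
#' and current to 10 kHz; choose the embedding dimension by simplex projection
#' (delay 1) unless given; fit 50 RBF centers by k-means; train the weights by
#' ridge regression with the penalty chosen by 10-fold blocked
#' cross-validation.
#'
#' @param type neuron type (1 or 2).
#' @param duration training data length in ms.
#' @param n_centers number of RBF centers.
#' @param R RBF length scale (1/mV^2).
#' @param tau embedding delay in samples.
#' @param embedding_dim fixed embedding dimension, or `NULL` to select it by
#'   simplex projection.
#' @param folds cross-validation folds.
#' @param lambda_grid candidate ridge penalties.
#' @param snr stimulus-to-noise ratio of the training data.
#' @param seed seed for the noise draw, the Lorenz initial condition and the
#'   k-means initialization.
#' @param h integration step in ms.
#' @param ds_factor downsampling factor from the integration grid to the
#'   model grid.
#' @return a trained `rbfn_model`; training data are kept in
#'   `meta$training` (voltage and current traces on the model grid).
#' @export
train_pipeline <- function(type = 1, duration = 5000, n_centers = 50,
                           R = 0.01, tau = 1, embedding_dim = NULL,
                           folds = 10,
                           lambda_grid = 10^seq(-8, 2, length.out = 11),
                           snr = 5, seed = 1, h = 0.02, ds_factor = 5) {
  amplitude <- if (type == 1) 1.8 else 0.5
  ic <- lorenz_ic(seed * 7L + 1L)
  inj <- make_lorenz_current(tau = 20, amplitude = amplitude,
                             duration = duration, dt = h,
                             x0 = ic[1], y0 = ic[2], z0 = ic[3])
  noise <- if (is.infinite(snr)) NULL else
    make_noise_current(duration = duration, dt = h, reference = inj,
                       target_snr = snr, seed = seed)
  sim <- simulate_cs(cs_params(type), i_inj = inj, i_noise = noise,
                     step = h, duration = duration)
  v <- downsample(sim$voltage, ds_factor)
  i <- downsample(inj, ds_factor)

  simplex_skill <- NULL
  if (is.null(embedding_dim)) {
    embedding_dim <- select_embedding_dim(v, candidate_dims = 1:10, tau = tau)
    simplex_skill <- attr(embedding_dim, "skill")
  }

  states <- embed_voltage(v, embedding_dim, tau)
  centers <- fit_centers(states, n_centers = n_centers, seed = seed)
  design <- build_design(v, i, centers, R, embedding_dim, tau)
  lambda <- cross_validate_lambda(design, folds = folds, grid = lambda_grid)
  w <- ridge_fit(design, lambda)

  rbfn_model(centers = centers, weights = w[-length(w)],
             alpha = w[length(w)], R = R, dim = embedding_dim, tau = tau,
             lambda = as.numeric(lambda),
             meta = list(type = type, seed = seed, snr = snr,
                         duration = duration, amplitude = amplitude,
                         cv_error = attr(lambda, "cv_error"),
                         simplex_skill = simplex_skill,
                         n_train_spikes = length(detect_spikes(v)$times),
                         training = list(voltage = v, current = i)))
}
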