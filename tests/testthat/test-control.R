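# small forecaster used as a synthetic, fully known dynamics model
toy_model <- function(alpha = 0.05, weights = c(0, 0)) {
  ctr <- rbind(c(-60, -60), c(-70, -70))
  rbfn_model(ctr, weights = weights, alpha = alpha, R = 0.01, dim = 2)
}

test_that("a one-step horizon reproduces the hand-derived clamped optimum", {
  m <- toy_model(alpha = 0.05)
  cfg <- mpc_config(horizon = 1, s = 0, q = 1, r = 0)
  # weights are zero so V1 = V0 + alpha (I1 + I0); the unique minimizer of
  # q e1^2 is I1 = (ref - V0)/alpha - I0, clamped to the box
  for (case in list(list(v0 = -65, i0 = 10, ref = -60),
                    list(v0 = -65, i0 = 0, ref = -64.5),
                    list(v0 = -70, i0 = -20, ref = -66))) {
    sol <- mpc_step(m, c(case$v0, case$v0), case$i0, case$ref, cfg)
    closed <- min(100, max(-100, (case$ref - case$v0) / 0.05 - case$i0))
    expect_equal(sol$i_next, closed, tolerance = 1e-6)
  }
  # unreachable reference saturates at the bound
  sol <- mpc_step(m, c(-65, -65), 0, 40, cfg)
  expect_equal(sol$i_next, 100, tolerance = 1e-9)
})

test_that("optimized inputs respect the box constraint and cost dominance", {
  set.seed(9)
  ctr <- matrix(rnorm(20, -65, 8), 10, 2)
  m <- rbfn_model(ctr, weights = rnorm(10, 0, 0.5), alpha = 0.04, R = 0.01,
                  dim = 2)
  cfg <- mpc_config(horizon = 5)
  for (rep in 1:10) {
    v0 <- runif(1, -75, -55)
    i_prev <- runif(1, -100, 100)
    ref <- v0 + cumsum(rnorm(5, 0, 2))
    sol <- mpc_step(m, c(v0 + rnorm(1), v0), i_prev, ref, cfg)
    expect_true(all(abs(sol$sequence) <= 100 + 1e-9))
    # never worse than holding the previous input
    hold <- mpc_step(m, c(v0 + rnorm(1), v0), i_prev, ref,
                     mpc_config(horizon = 5, max_iter = 0),
                     warm_start = rep(i_prev, 5))
    expect_lte(sol$cost, hold$cost + 1e-9)
  }
  # holding position: constant reference at the current voltage with r > 0
  # favors winding the input change down, never increasing cost
  solh <- mpc_step(toy_model(0.05), c(-65, -65), 50, rep(-65, 5),
                   mpc_config(horizon = 5, r = 0.1))
  expect_lte(solh$cost, mpc_step(toy_model(0.05), c(-65, -65), 50, rep(-65, 5),
                                 mpc_config(horizon = 5, r = 0.1,
                                            max_iter = 0))$cost)
})

test_that("model-matched receding-horizon control tracks near-exactly", {
  set.seed(14)
  ctr <- matrix(runif(30, -75, -55), 15, 2)
  m <- rbfn_model(ctr, weights = rnorm(15, 0, 0.1), alpha = 0.05, R = 0.01,
                  dim = 2)
  # reachable reference: the model's own response to a known bounded input
  gen <- ddf_plant(m, c(-65, -65))
  u_star <- 20 * sin(2 * pi * seq_len(300) / 80)
  ref_v <- c(-65, vapply(u_star, gen$step, numeric(1)))
  ref <- voltage_trace(ref_v, dt = 0.1)

  plant <- ddf_plant(m, c(-65, -65))
  res <- run_mpc(plant, m, ref, mpc_config(horizon = 5, r = 1e-4))
  err <- res$voltage$values - ref$values
  expect_lt(mean(err[-(1:20)]^2), 1)
  expect_true(all(abs(res$input$values) <= 100 + 1e-9))
})

test_that("degenerate references produce empty results without solving", {
  m <- toy_model()
  plant <- ddf_plant(m, c(-65, -65))
  res <- run_mpc(plant, m, voltage_trace(numeric(0), dt = 0.1))
  expect_s3_class(res, "control_result")
  expect_length(res$voltage$values, 0)
  expect_length(res$input$values, 0)
})

test_that("proportional control scales, negates and clamps the state error", {
  m <- toy_model(alpha = 0.05)
  # plant glued to the reference -> zero error -> zero input
  plant <- ddf_plant(toy_model(alpha = 0), c(-65, -65))
  ref <- voltage_trace(rep(-65, 40), dt = 0.1)
  res <- proportional_control(plant, ref, kp = -2)
  expect_true(all(res$input$values == 0))
  # +100 mV error with Kp = -2 exceeds the clamp
  plant2 <- ddf_plant(toy_model(alpha = 0), c(35, 35))
  ref2 <- voltage_trace(rep(-65, 3), dt = 0.1)
  res2 <- proportional_control(plant2, ref2, kp = -2, clamp = 100)
  expect_equal(res2$input$values[2], -100)
})

test_that("open-loop replay of the generating current is exact when noiseless", {
  p <- cs_params(1)
  inj <- make_lorenz_current(tau = 20, amplitude = 1.8, duration = 100,
                             dt = 0.02, x0 = 1, y0 = 1, z0 = 1)
  sim <- simulate_cs(p, i_inj = inj, duration = 100)
  ref <- downsample(sim$voltage, 5)
  plant <- cs_plant(p, dt = 0.1, h = 0.02)
  res <- open_loop_replay(plant, inj, reference = ref)
  expect_lt(res$metrics$mse, 1e-12)
})

test_that("requested spike trains convert to references and back", {
  m1 <- trained_model(1)
  tr <- m1$meta$training
  sp <- detect_spikes(tr$voltage)
  w <- extract_mean_waveform(tr$voltage, sp, window = c(2, 5))
  expect_gte(max(w), 30)
  expect_equal(which.max(w) - attr(w, "align") <= 1, TRUE)

  req <- c(50, 160, 270)
  ref <- spikes_to_reference(req, w, duration = 400, dt = 0.1)
  expect_equal(trace_times(ref)[which.max(ref$values)], 50)
  det <- detect_spikes(ref)$times
  expect_equal(length(det), 3)
  expect_true(all(abs(det - req) <= 0.1 + 1e-9))   # within one sample
  none <- spikes_to_reference(numeric(0), w, duration = 100, dt = 0.1)
  expect_true(all(none$values == -65))
  expect_error(spikes_to_reference(c(50, 51), w, duration = 100, dt = 0.1),
               "overlap")

  # single spike: the mean waveform is that snippet
  v1 <- voltage_trace(c(rep(-65, 30), 20, 45, 10, rep(-65, 30)), dt = 0.1)
  s1 <- detect_spikes(v1)
  w1 <- extract_mean_waveform(v1, s1, window = c(1, 1))
  k <- round(s1$times[1] / 0.1) + 1
  expect_equal(as.numeric(w1), v1$values[(k - 10):(k + 10)])
  expect_error(extract_mean_waveform(v1, spike_train(numeric(0))), "no spikes")
})

test_that("calibrated pulses elicit exactly one spike each, none when absent", {
  p <- cs_params(1)
  amp <- cached("pulse_amp_1", calibrate_pulse_amplitude(p))
  plant <- cs_plant(p)
  res <- pulse_control(plant, spike_times = c(60, 150, 240, 330, 420),
                       width = 2, amplitude = amp, duration = 500)
  expect_equal(length(detect_spikes(res$voltage)$times), 5)
  # no requested spikes -> silent
  res0 <- pulse_control(cs_plant(p), numeric(0), width = 2, amplitude = amp,
                        duration = 200)
  expect_length(detect_spikes(res0$voltage)$times, 0)
  # subthreshold amplitude fails to fire
  res_sub <- pulse_control(cs_plant(p), spike_times = 60, width = 2,
                           amplitude = 1, duration = 200)
  expect_length(detect_spikes(res_sub$voltage)$times, 0)
  expect_error(pulse_control(cs_plant(p), c(10, 11), width = 2,
                             amplitude = amp, duration = 50), "overlap")
})
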