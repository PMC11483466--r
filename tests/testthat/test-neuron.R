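test_that("parameter sets encode the two excitability classes", {
  p1 <- cs_params(1)
  expect_equal(p1$g_a, 47.7)
  expect_equal(p1$e_l, -22)
  p2 <- cs_params(2)
  expect_equal(p2$g_a, 0)
  expect_equal(p2$e_l, -72.8)
  expect_error(cs_params(3), "type")
})

test_that("resting equilibrium is stationary under zero input", {
  for (ty in 1:2) {
    sim <- simulate_cs(cs_params(ty), duration = 500)
    expect_lt(max(abs(sim$voltage$values - sim$voltage$values[1])), 1)
    expect_length(detect_spikes(sim$voltage)$times, 0)
  }
})

test_that("gating variables stay within [0, 1] during 1 s noisy simulations", {
  for (ty in 1:2) {
    amp <- if (ty == 1) 1.8 else 0.5
    inj <- make_lorenz_current(tau = 20, amplitude = amp, duration = 1000,
                               dt = 0.02, x0 = 3, y0 = -2, z0 = 15)
    noise <- make_noise_current(duration = 1000, dt = 0.02, reference = inj,
                                target_snr = 5, seed = ty)
    sim <- simulate_cs(cs_params(ty), i_inj = inj, i_noise = noise,
                       duration = 1000)
    expect_true(all(sim$gating >= 0 & sim$gating <= 1))
    expect_true(all(is.finite(sim$voltage$values)))
  }
})

test_that("a 9 uA, 300 ms step elicits repetitive spiking", {
  i <- current_trace(rep(9, 300 / 0.02 + 1), dt = 0.02)
  for (ty in 1:2) {
    sim <- simulate_cs(cs_params(ty), i_inj = i, duration = 300)
    expect_gt(length(detect_spikes(sim$voltage)$times), 1)
  }
})

test_that("integration failure reports the blow-up time", {
  i <- current_trace(rep(1e12, 6), dt = 0.02)
  expect_error(simulate_cs(cs_params(1), i_inj = i, duration = 0.1),
               "integration failure.*t = ")
})

test_that("f-I curve is zero below threshold and type onsets differ", {
  amps <- c(0, 6)
  for (ty in 1:2) {
    fi <- fi_curve(cs_params(ty), amps, step_duration = 300)
    expect_equal(fi[1], 0)
  }
})

test_that("coarser input grids are zero-order-held onto the integration grid", {
  # a constant current expressed at two different sampling periods must give
  # identical trajectories
  i_fine <- current_trace(rep(9, 100 / 0.02 + 1), dt = 0.02)
  i_coarse <- current_trace(rep(9, 100 / 0.1 + 1), dt = 0.1)
  s1 <- simulate_cs(cs_params(1), i_inj = i_fine, duration = 100)
  s2 <- simulate_cs(cs_params(1), i_inj = i_coarse, duration = 100)
  expect_equal(s1$voltage$values, s2$voltage$values)
})
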