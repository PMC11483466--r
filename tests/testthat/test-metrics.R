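test_that("trajectory MSE matches a loop-computed oracle", {
  v1 <- voltage_trace(rep(-65, 50), dt = 0.1)
  expect_equal(mse_trace(v1, v1), 0)
  v2 <- voltage_trace(v1$values + 2, dt = 0.1)
  expect_equal(mse_trace(v1, v2), 4)
  set.seed(3)
  a <- voltage_trace(rnorm(200), dt = 0.1)
  b <- voltage_trace(rnorm(200), dt = 0.1)
  acc <- 0
  for (k in seq_along(a$values)) acc <- acc + (a$values[k] - b$values[k])^2
  expect_equal(mse_trace(a, b), acc / 200, tolerance = 1e-12)
  expect_error(mse_trace(a, voltage_trace(rnorm(100), dt = 0.1)), "length")
})

test_that("identical spike trains have exactly zero distance", {
  a <- spike_train(seq(100, 1000, by = 100))
  b <- spike_train(a$times)
  expect_identical(isi_distance(a, b, 0, 1000), 0)
  expect_identical(spike_distance(a, b, 0, 1000), 0)
})

test_that("periodic trains with 2:1 interval ratio give ISI-distance 1/2", {
  a <- spike_train(seq(10, 9990, by = 10))
  b <- spike_train(seq(20, 9980, by = 20))
  expect_equal(isi_distance(a, b, 0, 10000), 0.5, tolerance = 1e-12)
})

test_that("distances are symmetric, bounded and shift-invariant", {
  set.seed(11)
  for (rep in 1:10) {
    a <- spike_train(sort(stats::runif(stats::rpois(1, 15) + 2, 0, 1000)))
    b <- spike_train(sort(stats::runif(stats::rpois(1, 15) + 2, 0, 1000)))
    di <- isi_distance(a, b, 0, 1000)
    ds <- spike_distance(a, b, 0, 1000)
    expect_equal(di, isi_distance(b, a, 0, 1000), tolerance = 1e-12)
    expect_equal(ds, spike_distance(b, a, 0, 1000), tolerance = 1e-12)
    expect_true(di >= 0 && di <= 1)
    expect_true(ds >= 0 && ds <= 1)
    sh <- 137.5
    a2 <- spike_train(a$times + sh); b2 <- spike_train(b$times + sh)
    expect_equal(isi_distance(a2, b2, sh, 1000 + sh), di, tolerance = 1e-12)
    expect_equal(spike_distance(a2, b2, sh, 1000 + sh), ds, tolerance = 1e-12)
  }
})

test_that("both distances match the independent profile-quadrature oracle", {
  set.seed(21)
  for (rep in 1:10) {
    a <- sort(stats::runif(12, 0, 500))
    b <- sort(stats::runif(9, 0, 500))
    expect_equal(isi_distance(spike_train(a), spike_train(b), 0, 500),
                 oracle_isi_distance(a, b, 0, 500), tolerance = 1e-6)
    expect_equal(spike_distance(spike_train(a), spike_train(b), 0, 500),
                 oracle_spike_distance(a, b, 0, 500), tolerance = 1e-6)
  }
  # single spike each, far apart: small but strictly positive dissimilarity
  ds <- spike_distance(spike_train(100), spike_train(900), 0, 1000)
  expect_true(ds > 0 && ds <= 1)
})

test_that("spike-distance degrades monotonically under timing jitter", {
  base <- seq(50, 950, by = 50)
  sigmas <- c(0.5, 2, 8)
  med <- vapply(sigmas, function(sg) {
    d <- vapply(1:20, function(s) {
      set.seed(1000 + s)
      jit <- sort(base + stats::rnorm(length(base), sd = sg))
      spike_distance(spike_train(base), spike_train(jit), 0, 1000)
    }, numeric(1))
    stats::median(d)
  }, numeric(1))
  expect_true(all(diff(med) >= 0))
  expect_gt(med[3], med[1])
})

test_that("empty trains return the documented sentinels", {
  a <- spike_train(c(100, 200))
  none <- spike_train(numeric(0))
  expect_warning(d <- isi_distance(a, none, 0, 1000), "no spikes")
  expect_identical(d, 1)
  expect_identical(suppressWarnings(spike_distance(none, a, 0, 1000)), 1)
  expect_identical(isi_distance(none, none, 0, 1000), 0)
  expect_error(isi_distance(a, a, 500, 500), "window")
})
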