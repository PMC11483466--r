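test_that("time-delay embedding enumerates lagged states correctly", {
  s <- embed_voltage(c(10, 20, 30), dim = 2, tau = 1)
  expect_equal(unname(s[1, ]), c(20, 10))
  expect_equal(unname(s[2, ]), c(30, 20))

  s1 <- embed_voltage(c(5, 6, 7), dim = 1, tau = 1)
  expect_equal(as.numeric(s1), c(5, 6, 7))

  ramp <- 1:10
  s3 <- embed_voltage(ramp, dim = 3, tau = 2)
  expect_equal(nrow(s3), 6)
  expect_equal(unname(s3[1, ]), c(5, 3, 1))
  expect_equal(unname(s3[6, ]), c(10, 8, 6))
  expect_error(embed_voltage(1:3, dim = 4, tau = 1), "too short")
})

test_that("rbf activation evaluates the Gaussian kernel", {
  expect_equal(rbf_activation(c(1, 2), c(1, 2), R = 0.01), 1)
  expect_equal(rbf_activation(c(10, 0), c(0, 0), R = 0.01), exp(-1))
  a1 <- rbf_activation(c(5, 0), c(0, 0), R = 0.01)
  a2 <- rbf_activation(c(6, 0), c(0, 0), R = 0.01)
  expect_gt(a1, a2)   # monotone decreasing in distance
  expect_true(a1 > 0 && a1 <= 1)
})

test_that("design matrices follow the increment-map layout", {
  v <- voltage_trace(c(-65, -64, -62, -60), dt = 0.1)
  i <- current_trace(c(1, 2, 3, 4), dt = 0.1)
  ctr <- matrix(c(-64, -65), nrow = 1)
  d <- build_design(v, i, ctr, R = 0.01, dim = 2, tau = 1)
  expect_equal(dim(d$X), c(2, 2))
  # hand-evaluated activations and current sums
  expect_equal(d$X[1, 1], exp(-0.01 * ((-64 + 64)^2 + (-65 + 65)^2)))
  expect_equal(d$X[2, 1], exp(-0.01 * ((-62 + 64)^2 + (-64 + 65)^2)))
  expect_equal(d$X[, 2], c(2 + 3, 3 + 4))
  expect_equal(d$Y, c(-62 - (-64), -60 - (-62)))

  # constant voltage, zero current -> zero increments
  vc <- voltage_trace(rep(-65, 6), dt = 0.1)
  ic <- current_trace(rep(0, 6), dt = 0.1)
  dc <- build_design(vc, ic, ctr, R = 0.01, dim = 2, tau = 1)
  expect_true(all(dc$Y == 0))
  expect_error(build_design(vc, current_trace(rep(0, 5), dt = 0.1), ctr,
                            0.01, 2, 1), "length")
})

test_that("ridge solutions match the closed form and shrink with lambda", {
  set.seed(42)
  for (rep in 1:5) {
    X <- matrix(rnorm(100), 20, 5)
    Y <- rnorm(20)
    d <- list(X = X, Y = Y)
    expect_equal(ridge_fit(d, 0.1), oracle_ridge(X, Y, 0.1), tolerance = 1e-8)
  }
  # square invertible system with lambda = 0 interpolates exactly
  Xs <- matrix(rnorm(25), 5, 5) + diag(5)
  Ys <- rnorm(5)
  w0 <- ridge_fit(list(X = Xs, Y = Ys), 0)
  expect_equal(drop(Xs %*% w0), Ys, tolerance = 1e-8)
  # enormous penalty shrinks the weights toward zero
  wl <- ridge_fit(list(X = Xs, Y = Ys), 1e12)
  expect_lt(sqrt(sum(wl^2)), 1e-6)
  # rank-deficient design with lambda = 0 is an error
  Xr <- cbind(1:6, 1:6)
  expect_error(ridge_fit(list(X = Xr, Y = rnorm(6)), 0), "rank-deficient")
})

test_that("blocked cross-validation picks the penalty deterministically", {
  set.seed(7)
  X <- matrix(rnorm(600), 100, 6)
  w_true <- rnorm(6)
  d <- list(X = X, Y = drop(X %*% w_true))       # noiseless, realizable
  grid <- 10^seq(-8, 2, length.out = 11)
  lam <- cross_validate_lambda(d, folds = 10, grid = grid)
  expect_equal(as.numeric(lam), min(grid))       # no noise -> least shrinkage
  lam2 <- cross_validate_lambda(d, folds = 10, grid = grid)
  expect_identical(as.numeric(lam), as.numeric(lam2))
  expect_equal(as.numeric(cross_validate_lambda(d, folds = 10, grid = 0.5)), 0.5)
  expect_error(cross_validate_lambda(list(X = X[1:5, ], Y = d$Y[1:5]),
                                     folds = 10), "folds")
})

test_that("one-step prediction implements the voltage-increment map", {
  ctr <- rbind(c(-60, -62), c(-70, -71))
  m <- rbfn_model(ctr, weights = c(0.5, -0.2), alpha = 0.05, R = 0.01, dim = 2)
  s <- c(-64, -66)
  by_hand <- -64 +
    0.5 * exp(-0.01 * sum((s - ctr[1, ])^2)) +
    -0.2 * exp(-0.01 * sum((s - ctr[2, ])^2)) +
    0.05 * (3 + 1)
  expect_equal(predict_step(m, s, i_n = 1, i_next = 3), by_hand,
               tolerance = 1e-12)

  m0 <- rbfn_model(ctr, weights = c(0, 0), alpha = 0, R = 0.01, dim = 2)
  expect_equal(predict_step(m0, s, 5, -3), -64)   # identity dynamics
  mi <- rbfn_model(ctr, weights = c(0, 0), alpha = 0.5, R = 0.01, dim = 2)
  expect_equal(predict_step(mi, s, 1, 1), -63)    # input-only
  expect_error(predict_step(m, c(-64, -66, -67), 0, 0), "dimension")
})

test_that("one-step prediction is affine in the current sum with slope alpha", {
  set.seed(1)
  ctr <- matrix(rnorm(10, -65, 5), 5, 2)
  m <- rbfn_model(ctr, weights = rnorm(5), alpha = 0.07, R = 0.01, dim = 2)
  s <- c(-63, -64)
  base <- predict_step(m, s, 0, 0)
  for (u in c(-10, 1, 25)) {
    expect_equal(predict_step(m, s, u, 0) - base, 0.07 * u, tolerance = 1e-12)
    expect_equal(predict_step(m, s, u, u) - base, 0.07 * 2 * u,
                 tolerance = 1e-12)
  }
})

test_that("open-loop forecasting feeds predictions back and guards divergence", {
  ctr <- rbind(c(-60, -60))
  m0 <- rbfn_model(ctr, weights = 0, alpha = 0, R = 0.01, dim = 2)
  i <- current_trace(rnorm(50), dt = 0.1)
  fc <- forecast_open_loop(m0, c(-70, -65), i)
  expect_true(all(fc$values[-1] == -65))  # identity model holds the seed
  expect_false(attr(fc, "diverged"))
  expect_error(forecast_open_loop(m0, c(-70, -65, -60), i), "seed")

  mexp <- rbfn_model(ctr, weights = 0, alpha = 10, R = 0.01, dim = 2)
  iexp <- current_trace(rep(40, 50), dt = 0.1)
  fcexp <- forecast_open_loop(mexp, c(-65, -65), iexp)
  expect_true(attr(fcexp, "diverged"))
  expect_lt(length(fcexp$values), 50)
})

test_that("k-means++ centers are deterministic and land inside clusters", {
  set.seed(10)
  states <- rbind(matrix(rnorm(200, 0, 1), ncol = 2),
                  matrix(rnorm(200, 100, 1), ncol = 2))
  c1 <- fit_centers(states, n_centers = 2, seed = 3)
  c2 <- fit_centers(states, n_centers = 2, seed = 3)
  expect_identical(c1, c2)
  mins <- apply(c1, 1, function(x) max(abs(x - 0)) < 5 || max(abs(x - 100)) < 5)
  expect_true(all(mins))
  expect_equal(sum(apply(c1, 1, function(x) max(abs(x)) < 5)), 1)

  one <- fit_centers(states, n_centers = 1, seed = 1)
  expect_equal(drop(one), colMeans(states), tolerance = 1e-8)
  expect_error(fit_centers(states[1:3, ], n_centers = 5), "fewer states")
})

test_that("simplex selection matches a brute-force oracle and breaks ties low", {
  # lag-1 autoregression: one lag suffices, skill saturates at small dimension
  set.seed(5)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 400))
  sel <- select_embedding_dim(x, candidate_dims = 1:4, tau = 1)
  skill <- attr(sel, "skill")
  oracle <- vapply(1:4, function(E) oracle_simplex_skill(x, E, 1), numeric(1))
  expect_equal(unname(skill), oracle, tolerance = 1e-8)
  expect_equal(as.integer(sel), which.max(oracle))
  expect_error(select_embedding_dim(rep(1, 100), 1:3), "constant")
})

test_that("forecaster JSON serialization round-trips", {
  set.seed(2)
  m <- rbfn_model(matrix(rnorm(20, -65, 8), 10, 2), weights = rnorm(10),
                  alpha = 0.03, R = 0.01, dim = 2, tau = 1, lambda = 1e-4,
                  meta = list(type = 1))
  path <- withr::local_tempfile(fileext = ".json")
  write_rbfn_json(m, path)
  m2 <- read_rbfn_json(path)
  expect_equal(m2$centers, m$centers)
  expect_equal(m2$weights, m$weights)
  expect_equal(m2$alpha, m$alpha)
  expect_equal(m2$dim, m$dim)
  s <- c(-64, -66)
  expect_equal(predict_step(m2, s, 1, 2), predict_step(m, s, 1, 2))
})
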