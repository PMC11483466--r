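#' Time-delay embedding of a voltage series
#'
#' Reconstructs a `D_e`-dimensional state from lagged copies of the voltage:
#' \eqn{S_n = (V_n, V_{n-\tau}, \ldots, V_{n-(D_e-1)\tau})}. Row `k` of the
#' returned matrix is the state at sample index `(D_e - 1) * tau + k` of the
#' input (1-based); the first column is the undelayed voltage.
#'
#' @param v a `voltage_trace` or numeric vector.
#' @param dim embedding dimension `D_e` (>= 1).
#' @param tau delay in samples (>= 1).
#' @return numeric matrix with `length(v) - (dim - 1) * tau` rows and `dim`
#'   columns, with attribute `first_index` giving the sample index of the
#'   first row.
#' @export
embed_voltage <- function(v, dim, tau = 1) {
  x <- if (inherits(v, "trace")) v$values else as.numeric(v)
  stopifnot(dim >= 1, tau >= 1)
  span <- (dim - 1) * tau
  if (length(x) <= span) stop("trace too short for the requested embedding")
  n_states <- length(x) - span
  out <- vapply(seq_len(dim) - 1L,
                function(j) x[(span + 1 - j * tau):(length(x) - j * tau)],
                numeric(n_states))
  out <- matrix(out, nrow = n_states, ncol = dim)
  attr(out, "first_index") <- span + 1L
  out
}

#' Select the embedding dimension by simplex projection
#'
#' One-step nearest-neighbor forecasting (simplex projection): for each
#' candidate dimension `E`, states from the library segment predict states in
#' a held-out prediction segment using the `E + 1` nearest neighbors with
#' exponential distance weights; skill is the Pearson correlation between
#' predicted and observed next samples. Returns the candidate with the highest
#' skill; ties break toward the smallest dimension.
#'
#' @param v a `voltage_trace` or numeric vector.
#' @param candidate_dims integer vector of dimensions to evaluate.
#' @param tau delay in samples.
#' @param lib_frac fraction of the series used as the neighbor library (the
#'   remainder is the prediction set).
#' @param max_pred cap on the number of prediction points (evenly subsampled)
#'   to bound the cost of the brute-force neighbor search.
#' @param max_lib optional cap on the number of library states (evenly
#'   strided). The default uses the full library: the per-dimension skills on
#'   smooth, densely sampled voltage data differ only in the fourth decimal,
#'   and approximating the neighbor library can flip which dimension wins.
#' @return the selected dimension (integer), with the per-candidate skill in
#'   attribute `skill`.
#' @export
select_embedding_dim <- function(v, candidate_dims = 1:10, tau = 1,
                                 lib_frac = 0.75, max_pred = 2000,
                                 max_lib = Inf) {
  x <- if (inherits(v, "trace")) v$values else as.numeric(v)
  stopifnot(length(candidate_dims) >= 1, all(candidate_dims >= 1))
  if (stats::sd(x) == 0) stop("cannot select an embedding for a constant series")
  n <- length(x)
  lib_end <- floor(n * lib_frac)
  subsample <- function(idx, cap) {
    if (length(idx) > cap) idx[unique(round(seq(1, length(idx), length.out = cap)))]
    else idx
  }
  lib_all <- subsample(seq.int(0L, lib_end - 1L), max_lib)
  pred_all <- subsample(seq.int(lib_end, n - 2L), max_pred)  # 0-based
  skill <- vapply(candidate_dims, function(E) {
    .simplex_skill_cpp(x, as.integer(E), as.integer(tau),
                       as.integer(lib_all), as.integer(pred_all))
  }, numeric(1))
  names(skill) <- candidate_dims
  best <- candidate_dims[which.max(skill)]  # NA skills never win; ties -> first
  structure(as.integer(best), skill = skill)
}

#' Fit RBF centers by k-means clustering in embedding space
#'
#' k-means++ seeding followed by Lloyd iterations. The ++ initialization
#' (new seeds drawn with probability proportional to squared distance from
#' the chosen ones) matters here: the embedded states are dominated by a
#' dense subthreshold cloud, and random seeding leaves the sparse but
#' dynamically critical spike arc without centers, which cripples the
#' forecaster at exactly the samples that define a spike. Deterministic
#' given `seed`.
#'
#' @param states matrix of embedded states (rows = states).
#' @param n_centers number of centers N.
#' @param seed integer seed.
#' @param iter_max Lloyd iteration cap passed to [stats::kmeans()].
#' @return matrix of `n_centers` center vectors.
#' @export
fit_centers <- function(states, n_centers = 50, seed = 1, iter_max = 100) {
  states <- as.matrix(states)
  if (nrow(states) < n_centers)
    stop("fewer states than requested centers")
  set.seed(seed)
  init <- kmeanspp_init(states, n_centers)
  km <- suppressWarnings(
    stats::kmeans(states, centers = init, iter.max = iter_max)
  )
  unname(km$centers)
}

# k-means++ seeding (Arthur & Vassilvitskii 2007)
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums((x - matrix(centers[1, ], n, ncol(x), byrow = TRUE))^2)
  for (j in seq_len(k - 1) + 1) {
    pick <- if (sum(d2) == 0) sample.int(n, 1)
            else sample.int(n, 1, prob = d2)
    centers[j, ] <- x[pick, ]
    d2_new <- rowSums((x - matrix(centers[j, ], n, ncol(x), byrow = TRUE))^2)
    d2 <- pmin(d2, d2_new)
  }
  # k-means requires distinct initial centers
  if (anyDuplicated(centers)) {
    dup <- which(duplicated(centers))
    centers[dup, ] <- centers[dup, , drop = FALSE] +
      stats::rnorm(length(dup) * ncol(x), sd = 1e-6)
  }
  centers
}

#' Gaussian radial basis function activation
#'
#' \eqn{\psi_c(S) = \exp(-R \|S - \mu_c\|^2)}, a value in (0, 1].
#'
#' @param s state vector.
#' @param mu center vector of the same length.
#' @param R length-scale parameter in 1/mV^2 (> 0).
#' @return scalar activation.
#' @export
rbf_activation <- function(s, mu, R) {
  stopifnot(R > 0, length(s) == length(mu))
  exp(-R * sum((s - mu)^2))
}

#' Assemble the regression design for the voltage-increment map
#'
#' Builds the linear system whose solution gives the RBFN weights and the
#' input coefficient: row k of `X` holds the N center activations at state
#' `S_k` followed by the current sum `I_{k+1} + I_k`; row k of `Y` is the
#' voltage increment `V_{k+1} - V_k`. Rows run over all samples where the
#' embedded state and the successor sample both exist.
#'
#' @param v a `voltage_trace`.
#' @param i a `current_trace` aligned with `v` (same dt and length).
#' @param centers matrix of RBF centers.
#' @param R length-scale parameter.
#' @param dim,tau embedding specification.
#' @return list with matrix `X` (rows x (N + 1)) and vector `Y`.
#' @export
build_design <- function(v, i, centers, R, dim, tau = 1) {
  stopifnot(inherits(v, "voltage_trace"), inherits(i, "current_trace"))
  if (length(v$values) != length(i$values) || abs(v$dt - i$dt) > 1e-12)
    stop("voltage and current traces must share length and sampling period")
  centers <- as.matrix(centers)
  states <- embed_voltage(v, dim, tau)
  n0 <- attr(states, "first_index")          # sample index of first state
  n_rows <- nrow(states) - 1L                # last state has no successor
  if (n_rows < 1) stop("trace too short to form any transition")
  psi <- .rbf_design_cpp(states[seq_len(n_rows), , drop = FALSE], centers, R)
  idx <- n0 + seq_len(n_rows) - 1L
  X <- cbind(psi, i$values[idx + 1L] + i$values[idx])
  Y <- v$values[idx + 1L] - v$values[idx]
  list(X = X, Y = Y)
}

#' Ridge (Tikhonov) regression fit of the RBFN weights
#'
#' Solves \eqn{W = (X^T X + \lambda I)^{-1} X^T Y}. The last element of `W` is
#' the input coefficient alpha; the rest are the RBF output weights.
#'
#' @param design a list with `X` and `Y` as returned by [build_design()].
#' @param lambda regularization parameter (>= 0).
#' @return numeric weight vector of length `ncol(X)`.
#' @export
ridge_fit <- function(design, lambda) {
  stopifnot(lambda >= 0)
  X <- design$X; Y <- design$Y
  G <- crossprod(X) + diag(lambda, ncol(X))
  b <- crossprod(X, Y)
  w <- tryCatch(drop(solve(G, b)), error = function(e) {
    if (lambda == 0)
      stop("design matrix is rank-deficient with lambda = 0; use lambda > 0")
    stop(e)
  })
  w
}

#' Choose the ridge penalty by blocked cross-validation
#'
#' Splits the rows into `folds` contiguous blocks (the data are a time series,
#' so shuffled folds would leak information between adjacent samples), fits on
#' the remaining blocks for each grid value, and returns the grid value with
#' the lowest mean held-out squared error. Ties break toward the larger
#' penalty.
#'
#' @param design a list with `X` and `Y`.
#' @param folds number of contiguous folds.
#' @param grid candidate lambda values.
#' @return the selected lambda, with per-grid CV errors in attribute
#'   `cv_error`.
#' @export
cross_validate_lambda <- function(design, folds = 10,
                                  grid = 10^seq(-8, 2, length.out = 11)) {
  X <- design$X; Y <- design$Y
  n <- nrow(X)
  stopifnot(length(grid) >= 1)
  if (n < folds) stop("fewer rows than folds")
  fold_id <- rep(seq_len(folds), each = ceiling(n / folds))[seq_len(n)]

  G_all <- crossprod(X)
  b_all <- crossprod(X, Y)
  G_fold <- lapply(seq_len(folds), function(f) crossprod(X[fold_id == f, , drop = FALSE]))
  b_fold <- lapply(seq_len(folds), function(f)
    crossprod(X[fold_id == f, , drop = FALSE], Y[fold_id == f]))

  cv <- vapply(grid, function(lambda) {
    err <- 0
    for (f in seq_len(folds)) {
      G <- G_all - G_fold[[f]] + diag(lambda, ncol(X))
      w <- tryCatch(drop(solve(G, b_all - b_fold[[f]])),
                    error = function(e) rep(NA_real_, ncol(X)))
      if (anyNA(w)) return(Inf)
      res <- X[fold_id == f, , drop = FALSE] %*% w - Y[fold_id == f]
      err <- err + mean(res^2)
    }
    err / folds
  }, numeric(1))
  names(cv) <- signif(grid, 6)
  # ties -> larger lambda
  ord <- order(cv, -grid)
  structure(grid[ord[1]], cv_error = cv)
}

#' Construct a trained forecaster object
#'
#' @param centers matrix of RBF centers (N x D_e).
#' @param weights RBF output weights (length N).
#' @param alpha input-scaling coefficient.
#' @param R RBF length-scale (1/mV^2).
#' @param dim,tau embedding specification.
#' @param lambda ridge penalty used in training.
#' @param meta optional named list of training metadata.
#' @return object of class `rbfn_model`.
#' @export
rbfn_model <- function(centers, weights, alpha, R, dim, tau = 1,
                       lambda = NA_real_, meta = list()) {
  centers <- as.matrix(centers)
  stopifnot(nrow(centers) >= 1, ncol(centers) == dim,
            length(weights) == nrow(centers), R > 0,
            all(is.finite(centers)), all(is.finite(weights)),
            is.finite(alpha))
  structure(list(centers = centers, weights = as.numeric(weights),
                 alpha = alpha, R = R, dim = as.integer(dim),
                 tau = as.integer(tau), lambda = lambda, meta = meta),
            class = "rbfn_model")
}

#' @export
print.rbfn_model <- function(x, ...) {
  cat(sprintf("<rbfn_model> %d centers, D_e = %d, tau = %d, R = %g, alpha = %.4g, lambda = %.3g\n",
              nrow(x$centers), x$dim, x$tau, x$R, x$alpha, x$lambda))
  invisible(x)
}

#' Embedding seed length of a model
#' @param model an `rbfn_model`.
#' @return number of voltage samples needed to form one embedded state.
#' @export
seed_length <- function(model) (model$dim - 1L) * model$tau + 1L

#' One-step voltage prediction
#'
#' \eqn{V_{n+1} = V_n + \sum_c w_c \psi_c(S_n) + \alpha (I_{n+1} + I_n)}.
#' The first element of `s` is the current voltage `V_n`.
#'
#' @param model an `rbfn_model`.
#' @param s embedded state vector of length `model$dim`.
#' @param i_n,i_next injected current at the current and next sample (uA).
#' @return predicted voltage `V_{n+1}` (mV).
#' @export
predict_step <- function(model, s, i_n, i_next) {
  if (length(s) != model$dim) stop("state dimension does not match the model embedding")
  d2 <- colSums((t(model$centers) - s)^2)
  s[1] + sum(model$weights * exp(-model$R * d2)) + model$alpha * (i_next + i_n)
}

#' Open-loop voltage forecast
#'
#' Iterates [predict_step()] forward, feeding predictions back into the
#' embedding; after the seed the true voltage is never read. If the forecast
#' exceeds `guard` mV in magnitude it is truncated and flagged as diverged.
#'
#' @param model an `rbfn_model`.
#' @param v_seed numeric vector of exactly `seed_length(model)` voltage
#'   samples (oldest first).
#' @param i a `current_trace`; the forecast covers its full length, with the
#'   seed occupying the first samples.
#' @param guard divergence guard in mV.
#' @return a `voltage_trace` the length of `i`, with attributes `diverged`
#'   and `n_valid`.
#' @export
forecast_open_loop <- function(model, v_seed, i, guard = 500) {
  stopifnot(inherits(model, "rbfn_model"), inherits(i, "current_trace"))
  v_seed <- as.numeric(v_seed)
  if (length(v_seed) != seed_length(model))
    stop(sprintf("seed must have exactly %d samples", seed_length(model)))
  out <- .ddf_forecast_cpp(model$centers, model$weights, model$alpha,
                           model$R, model$dim, model$tau,
                           v_seed, i$values, guard)
  v <- voltage_trace(out$v[seq_len(out$n_valid)], dt = i$dt, t0 = i$t0)
  attr(v, "diverged") <- out$diverged
  attr(v, "n_valid") <- out$n_valid
  v
}

#' Serialize and restore a trained forecaster as JSON
#'
#' @param model an `rbfn_model`.
#' @param path file path.
#' @export
write_rbfn_json <- function(model, path) {
  obj <- list(centers = unname(as.matrix(model$centers)),
              weights = model$weights, alpha = model$alpha, R = model$R,
              dim = model$dim, tau = model$tau, lambda = model$lambda,
              meta = model$meta)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_rbfn_json
#' @export
read_rbfn_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rbfn_model(centers = as.matrix(obj$centers),
             weights = obj$weights, alpha = obj$alpha, R = obj$R,
             dim = obj$dim, tau = obj$tau, lambda = obj$lambda,
             meta = as.list(obj$meta))
}
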