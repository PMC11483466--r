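# Independent oracles used to cross-check the package implementations.

# Ridge regression by the explicit closed-form matrix inverse.
oracle_ridge <- function(X, Y, lambda) {
  drop(solve(t(X) %*% X + lambda * diag(ncol(X))) %*% t(X) %*% Y)
}

# Pointwise spike-train dissimilarity profiles evaluated from the definitions,
# integrated with two-point Gauss-Legendre quadrature per pooled-spike segment
# (exact for the piecewise-constant ISI profile and piecewise-linear SPIKE
# profile). Independent of the package's segment-accumulation code path.
oracle_augment <- function(times, t0, t1) unique(sort(c(t0, times[times >= t0 & times <= t1], t1)))

oracle_isi_at <- function(t, ta, tb) {
  ia <- findInterval(t, ta, rightmost.closed = FALSE)
  ib <- findInterval(t, tb, rightmost.closed = FALSE)
  xa <- ta[ia + 1] - ta[ia]
  xb <- tb[ib + 1] - tb[ib]
  abs(xa - xb) / pmax(xa, xb)
}

oracle_spike_at <- function(t, ta, tb) {
  ia <- findInterval(t, ta); ib <- findInterval(t, tb)
  tpa <- ta[ia]; tfa <- ta[ia + 1]; xa <- tfa - tpa
  tpb <- tb[ib]; tfb <- tb[ib + 1]; xb <- tfb - tpb
  dpa <- min(abs(tpa - tb)); dfa <- min(abs(tfa - tb))
  dpb <- min(abs(tpb - ta)); dfb <- min(abs(tfb - ta))
  Sa <- (dpa * (tfa - t) + dfa * (t - tpa)) / xa
  Sb <- (dpb * (tfb - t) + dfb * (t - tpb)) / xb
  (Sa * xb + Sb * xa) / (2 * ((xa + xb) / 2)^2)
}

oracle_distance <- function(a, b, t0, t1, profile) {
  ta <- oracle_augment(a, t0, t1)
  tb <- oracle_augment(b, t0, t1)
  brk <- sort(unique(c(ta, tb)))
  gl <- 1 / (2 * sqrt(3))
  total <- 0
  for (k in seq_len(length(brk) - 1)) {
    u <- brk[k]; v <- brk[k + 1]
    if (v <= u) next
    nodes <- u + (v - u) * c(0.5 - gl, 0.5 + gl)
    total <- total + (v - u) * mean(vapply(nodes, profile, numeric(1),
                                           ta = ta, tb = tb))
  }
  total / (t1 - t0)
}

oracle_isi_distance <- function(a, b, t0, t1)
  oracle_distance(a, b, t0, t1, oracle_isi_at)
oracle_spike_distance <- function(a, b, t0, t1)
  oracle_distance(a, b, t0, t1, oracle_spike_at)

# Brute-force one-step simplex projection forecaster (nearest neighbors with
# exponential weights), used to cross-check embedding-dimension selection.
oracle_simplex_skill <- function(x, E, tau, lib_frac = 0.75) {
  n <- length(x)
  lib_end <- floor(n * lib_frac)
  span <- (E - 1) * tau
  lib <- seq.int(span + 1, lib_end)            # 1-based state indices
  lib <- lib[lib + 1 <= n]
  emb <- function(m) x[m - (0:(E - 1)) * tau]
  pred_idx <- seq.int(lib_end + 1, n - 1)
  pred_idx <- pred_idx[pred_idx - span >= 1]
  preds <- obs <- numeric(0)
  for (m in pred_idx) {
    target <- emb(m)
    d <- vapply(lib, function(j) sqrt(sum((emb(j) - target)^2)), numeric(1))
    ord <- order(d)[seq_len(E + 1)]
    dmin <- d[ord[1]]
    w <- if (dmin > 0) exp(-d[ord] / dmin) else as.numeric(d[ord] == 0)
    preds <- c(preds, sum(w * x[lib[ord] + 1]) / sum(w))
    obs <- c(obs, x[m + 1])
  }
  stats::cor(preds, obs)
}
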