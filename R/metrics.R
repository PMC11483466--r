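#' Mean squared error between two voltage traces
#'
#' @param v,v_ref `voltage_trace` objects of equal length and sampling period.
#' @return mean of squared pointwise differences in mV^2.
#' @export
mse_trace <- function(v, v_ref) {
  stopifnot(inherits(v, "voltage_trace"), inherits(v_ref, "voltage_trace"))
  if (length(v$values) != length(v_ref$values))
    stop("traces differ in length")
  if (abs(v$dt - v_ref$dt) > 1e-12)
    stop("traces differ in sampling period")
  mean((v$values - v_ref$values)^2)
}

# Shared preparation for the bivariate spike-train distances: restrict both
# trains to the window and add auxiliary spikes at the window edges (the
# standard edge-correction convention). Trains with no spike in the window are
# scored as maximally dissimilar (1) against a non-empty train; two empty
# trains are identical (0).
prepare_trains <- function(a, b, t_start, t_end) {
  stopifnot(inherits(a, "spike_train"), inherits(b, "spike_train"))
  if (t_end <= t_start) stop("empty observation window")
  ta <- a$times[a$times >= t_start & a$times <= t_end]
  tb <- b$times[b$times >= t_start & b$times <= t_end]
  if (length(ta) == 0 || length(tb) == 0) {
    if (length(ta) == length(tb)) return(list(degenerate = 0))
    warning("a spike train has no spikes in the window; returning maximal dissimilarity")
    return(list(degenerate = 1))
  }
  list(degenerate = NULL,
       a = unique(c(t_start, ta, t_end)),
       b = unique(c(t_start, tb, t_end)))
}

#' ISI-distance between two spike trains
#'
#' Bivariate Kreuz ISI-distance: the time average of the instantaneous
#' inter-spike-interval dissimilarity profile
#' \eqn{I(t) = |x_a(t) - x_b(t)| / \max(x_a(t), x_b(t))}, where \eqn{x(t)} is
#' the length of the inter-spike interval containing `t` (auxiliary spikes at
#' the window edges define the edge intervals). The profile is piecewise
#' constant between the pooled spike times, so the average is computed
#' exactly. The result is symmetric, lies in \[0, 1\], and is 0 exactly for
#' identical trains.
#'
#' @param a,b `spike_train` objects.
#' @param t_start,t_end observation window in ms; defaults cover both trains.
#' @return dissimilarity in `[0, 1]`.
#' @export
isi_distance <- function(a, b,
                         t_start = min(a$times, b$times),
                         t_end = max(a$times, b$times)) {
  pp <- prepare_trains(a, b, t_start, t_end)
  if (!is.null(pp$degenerate)) return(pp$degenerate)
  brk <- sort(unique(c(pp$a, pp$b)))
  mid <- (brk[-1] + brk[-length(brk)]) / 2
  len <- diff(brk)
  ia <- findInterval(mid, pp$a)
  ib <- findInterval(mid, pp$b)
  xa <- pp$a[ia + 1] - pp$a[ia]
  xb <- pp$b[ib + 1] - pp$b[ib]
  prof <- abs(xa - xb) / pmax(xa, xb)
  sum(prof * len) / (t_end - t_start)
}

#' SPIKE-distance between two spike trains
#'
#' Bivariate Kreuz SPIKE-distance: the time average of the spike-timing
#' dissimilarity profile S(t) built from the distances between each train's
#' surrounding spikes and their nearest counterparts in the other train,
#' interpolated across the local inter-spike intervals and normalized by the
#' mean local interval:
#' \deqn{S(t) = \frac{S_a(t)\, x_b(t) + S_b(t)\, x_a(t)}
#'                   {2 \langle x(t) \rangle^2},\qquad
#'       S_a(t) = \frac{\Delta t_p^a\, (t_f^a - t) + \Delta t_f^a\, (t - t_p^a)}
#'                     {x_a(t)}}
#' Auxiliary spikes at the window edges provide the edge correction. S(t) is
#' piecewise linear between pooled spike times, so the time average is
#' computed exactly (trapezoid on each segment). Symmetric, in \[0, 1\], and 0
#' exactly for identical trains.
#'
#' @inheritParams isi_distance
#' @return dissimilarity in `[0, 1]`.
#' @export
spike_distance <- function(a, b,
                           t_start = min(a$times, b$times),
                           t_end = max(a$times, b$times)) {
  pp <- prepare_trains(a, b, t_start, t_end)
  if (!is.null(pp$degenerate)) return(pp$degenerate)
  ta <- pp$a; tb <- pp$b
  brk <- sort(unique(c(ta, tb)))
  total <- 0
  for (k in seq_len(length(brk) - 1)) {
    u <- brk[k]; vv <- brk[k + 1]
    if (vv - u <= 0) next
    # surrounding spikes of each train for this segment
    ja <- findInterval(u, ta); tpa <- ta[ja]; tfa <- ta[ja + 1]
    jb <- findInterval(u, tb); tpb <- tb[jb]; tfb <- tb[jb + 1]
    xa <- tfa - tpa; xb <- tfb - tpb
    dpa <- min(abs(tpa - tb)); dfa <- min(abs(tfa - tb))
    dpb <- min(abs(tpb - ta)); dfb <- min(abs(tfb - ta))
    s_at <- function(t) {
      Sa <- (dpa * (tfa - t) + dfa * (t - tpa)) / xa
      Sb <- (dpb * (tfb - t) + dfb * (t - tpb)) / xb
      (Sa * xb + Sb * xa) / (2 * ((xa + xb) / 2)^2)
    }
    total <- total + (s_at(u) + s_at(vv)) / 2 * (vv - u)
  }
  total / (t_end - t_start)
}

#' Per-trial fit metrics for a controlled trajectory
#'
#' @param v realized `voltage_trace`.
#' @param ref reference `voltage_trace` (same grid).
#' @param threshold spike detection threshold in mV.
#' @return list with `mse` (mV^2), `isi_distance` and `spike_distance` (both
#'   dimensionless in `[0, 1]`).
#' @export
trial_metrics <- function(v, ref, threshold = 30) {
  t0 <- v$t0
  t1 <- v$t0 + (length(v$values) - 1) * v$dt
  sp_v <- detect_spikes(v, threshold)
  sp_r <- detect_spikes(ref, threshold)
  list(mse = mse_trace(v, ref),
       isi_distance = suppressWarnings(isi_distance(sp_v, sp_r, t0, t1)),
       spike_distance = suppressWarnings(spike_distance(sp_v, sp_r, t0, t1)))
}
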