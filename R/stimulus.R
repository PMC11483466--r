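#' Chaotic stimulus current from the Lorenz-63 system
#'
#' Integrates the time-scaled Lorenz-63 system
#' \deqn{\tau \dot x = \sigma (y - x),\quad
#'       \tau \dot y = x (\rho - z) - y,\quad
#'       \tau \dot z = x y - \beta z}
#' and returns the injected current \eqn{I_{inj}(t) = A\, x(t)} sampled every
#' `dt` ms. The chaotic x(t) trajectory is broadband and drives the neuron
#' across a wide extent of its state space, which is what makes it suitable as
#' a training stimulus. A burn-in segment is integrated and discarded before
#' sampling so that the returned trajectory lies on the attractor (unless the
#' initial condition is the origin, a fixed point, in which case the output is
#' identically zero).
#'
#' @param tau dimensionless time-scale factor applied to the Lorenz clock;
#'   `tau = 20` stretches the attractor dynamics to neural time scales when
#'   t is in ms.
#' @param amplitude output scaling A in uA per unit x.
#' @param duration length of the returned current in ms.
#' @param dt sampling period in ms.
#' @param x0,y0,z0 initial condition.
#' @param sigma,rho,beta Lorenz parameters; defaults are the canonical chaotic
#'   set (10, 28, 8/3).
#' @param burn_in trajectory time (ms, on the scaled clock) integrated and
#'   discarded before sampling.
#' @return a `current_trace` with `duration/dt + 1` samples.
#' @export
make_lorenz_current <- function(tau = 20, amplitude = 1, duration, dt,
                                x0 = 1, y0 = 1, z0 = 1,
                                sigma = 10, rho = 28, beta = 8 / 3,
                                burn_in = 1000) {
  stopifnot(duration > 0, dt > 0, tau > 0)
  deriv <- function(t, state, parms) {
    x <- state[1]; y <- state[2]; z <- state[3]
    list(c(sigma * (y - x) / tau,
           (x * (rho - z) - y) / tau,
           (x * y - beta * z) / tau))
  }
  state <- c(x = x0, y = y0, z = z0)
  if (burn_in > 0) {
    warm <- deSolve::ode(state, c(0, burn_in), deriv, parms = NULL,
                         method = "lsoda", rtol = 1e-9, atol = 1e-9,
                         maxsteps = 500000)
    state <- warm[nrow(warm), -1]
  }
  times <- seq(0, duration, by = dt)
  sol <- deSolve::ode(state, times, deriv, parms = NULL,
                      method = "lsoda", rtol = 1e-9, atol = 1e-9,
                      maxsteps = 500000)
  current_trace(amplitude * sol[, "x"], dt = dt)
}

#' Synaptic noise current from Poisson inputs
#'
#' Models the unknown, trial-varying synaptic bombardment a neuron receives in
#' vivo: one excitatory and one inhibitory Poisson spike train (20 Hz each by
#' default) are convolved with a peak-normalized alpha kernel
#' \eqn{\alpha(t) = (t/\tau_s) e^{1 - t/\tau_s}} (decay \eqn{\tau_s} = 10 ms,
#' truncated at \eqn{10 \tau_s}), the inhibitory contribution is negated, and
#' the sum is rescaled so that the ratio of standard deviations
#' sd(reference)/sd(noise) equals `target_snr`. The result is deterministic
#' given `seed`.
#'
#' @param rate_exc,rate_inh Poisson rates in Hz.
#' @param alpha_decay alpha-kernel decay time in ms.
#' @param duration length in ms.
#' @param dt sampling period in ms.
#' @param reference a `current_trace` the noise amplitude is scaled against
#'   (typically the injected stimulus); must be non-constant.
#' @param target_snr desired sd(reference)/sd(noise) ratio (> 0).
#' @param seed integer seed.
#' @return a `current_trace` with `duration/dt + 1` samples.
#' @export
make_noise_current <- function(rate_exc = 20, rate_inh = 20, alpha_decay = 10,
                               duration, dt, reference, target_snr = 5,
                               seed = 1) {
  stopifnot(rate_exc >= 0, rate_inh >= 0, target_snr > 0, duration > 0, dt > 0)
  n <- round(duration / dt) + 1
  if (rate_exc == 0 && rate_inh == 0)
    return(current_trace(numeric(n), dt = dt))
  stopifnot(inherits(reference, "trace"))
  s_ref <- stats::sd(reference$values)
  if (s_ref == 0) stop("reference current has zero variance; cannot scale noise")

  set.seed(seed)
  kern_t <- seq(0, 10 * alpha_decay, by = dt)
  kern <- (kern_t / alpha_decay) * exp(1 - kern_t / alpha_decay)

  add_train <- function(acc, rate, sign) {
    n_ev <- stats::rpois(1, rate * duration / 1000)
    if (n_ev == 0) return(acc)
    ev_idx <- floor(sort(stats::runif(n_ev, 0, duration)) / dt) + 1
    for (i in ev_idx) {
      j <- i:min(n, i + length(kern) - 1)
      acc[j] <- acc[j] + sign * kern[seq_along(j)]
    }
    acc
  }
  noise <- add_train(numeric(n), rate_exc, +1)
  noise <- add_train(noise, rate_inh, -1)

  s_noise <- stats::sd(noise)
  if (s_noise == 0) {
    warning("no synaptic events drawn; returning zero noise current")
    return(current_trace(noise, dt = dt))
  }
  current_trace(noise * s_ref / (target_snr * s_noise), dt = dt)
}
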