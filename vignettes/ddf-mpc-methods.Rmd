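---
title: "Methods: data-driven forecasting and model predictive control of a Connor-Stevens neuron"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: data-driven forecasting and model predictive control of a Connor-Stevens neuron}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, the numerical choices, and the design
decisions behind `ddfmpc`, in the spirit of a methods section: what is
computed, under which assumptions, and what the bundled tests do and do not
establish.

## The plant: a Connor-Stevens neuron

The controlled system is a single-compartment Connor-Stevens (CS) neuron,

$$C \frac{dV}{dt} = I_{Na} + I_K + I_A + I_l + I_{noise} + I_{inj},$$

with $I_{Na} = g_{Na} m^3 h (E_{Na} - V)$, $I_K = g_K n^4 (E_K - V)$,
$I_A = g_A a^3 b (E_A - V)$ and $I_l = g_l (E_l - V)$. Two parameterizations
are built in (`cs_params()`):

* **Type I** — $g_A = 47.7$ mS, $E_l = -22$ mV. Firing onset is a saddle-node
  bifurcation: the f-I curve rises continuously from zero above rheobase.
* **Type II** — $g_A = 0$, $E_l = -72.8$ mV. Onset is an Andronov-Hopf
  bifurcation: the rate jumps discontinuously (~85 Hz at onset on a
  0.5 µA grid, `fi_curve()`).

The remaining constants are the standard textbook Connor-Stevens values
($g_{Na} = 120$, $g_K = 20$, $g_l = 0.3$ mS; $E_{Na} = 55$, $E_K = -72$ mV;
$C = 1$ µF), with one deliberate choice: the A-current reversal is set equal
to the potassium reversal, $E_A = E_K = -72$ mV — a common published
simplification, since $I_A$ is a potassium current. With the textbook
$E_A = -75$ mV the Type-I rheobase lands just *above* 9 µA, and the model no
longer fires at a 9 µA step; with $E_A = -72$ mV the Type-I model fires
repetitively at 9 µA, onset is graded, and the Type-II jump is unchanged
(tests `test-neuron.R`, `test-acceptance.R`). All conductances are per 1 cm²
of soma, so injected currents of tens of µA are the natural scale; smaller
cells would need proportionally smaller currents.

### Integration scheme

Simulation uses a fixed step of $h = 0.02$ ms with a Strang split: an exact
exponential (Rush-Larsen) update of the five gating variables for $h/2$ at
frozen voltage, a classical RK4 step of the voltage equation with frozen
gates, then a second $h/2$ gate update. A fixed-step scheme keeps runs
bit-for-bit reproducible; the split matters because the gates are stiff where
the voltage equation is not. In particular $\beta_m(V) \propto
e^{-0.0556 V}$, so under sustained hyperpolarizing input (the chaotic
stimulus regularly holds $-10$ to $-35$ µA for milliseconds, driving $V$
below $-95$ mV) the sodium-activation time constant falls below the step
size and a naive explicit RK4 step of the full system is unstable — its
stage values of $m$ diverge. The exponential gate update is unconditionally
stable, gates are clamped to $[0,1]$, and the voltage sub-equation has time
constants $\geq C/g_{tot} \approx 0.03$ ms, comfortably resolved at
$h = 0.02$ ms. Against an adaptive high-accuracy reference solver (deSolve's
`lsoda` at tolerance $10^{-8}$) the scheme reproduces step-response spike
counts exactly and spike times to within 1-2 samples, and agrees to
$< 10^{-3}$ mV during strong hyperpolarization. Inputs are zero-order-held
between their samples; inputs sampled on a coarser grid (e.g. the 0.1 ms
control period) are held constant across the integration substeps.

A non-finite state aborts integration with an error naming the blow-up time.
Initial conditions default to the resting equilibrium obtained by relaxing
the model for 500 ms at zero input (`cs_resting_state()`), so simulations
start transient-free.

## Stimulus and noise

**Chaotic stimulus** (`make_lorenz_current()`): the x-coordinate of the
Lorenz-63 system, time-scaled by $\tau = 20$ and amplitude-scaled by $A$
(1.8 µA for Type I, 0.5 µA for Type II), sampled every `dt`. The canonical
chaotic parameters $\sigma = 10$, $\rho = 28$, $\beta = 8/3$ are used, the
conventional reading of "Lorenz-63". Integration is delegated to
deSolve/`lsoda`; 1000 ms (scaled clock) of trajectory is integrated and
discarded first so sampling starts on the attractor. The origin is a fixed
point, so a zero initial condition yields a zero current — kept as a
documented degenerate case.

**Synaptic noise** (`make_noise_current()`): one excitatory and one
inhibitory Poisson train, 20 Hz each (balanced excitation/inhibition),
convolved with a peak-normalized alpha kernel
$\alpha(t) = (t/\tau_s)e^{1-t/\tau_s}$, $\tau_s = 10$ ms, truncated at
$10\tau_s$; the inhibitory contribution is negated. The sum is rescaled so
that $\mathrm{sd}(I_{inj})/\mathrm{sd}(I_{noise})$ equals the target SNR
(default 5). SNR is defined as a ratio of standard deviations — the most
common convention; switching to a variance ratio would only re-map the
numeric target. Noise draws are deterministic given the seed.

## The forecaster

The forecaster never sees the gating variables. It assumes only that the
membrane is a capacitor driven by an additive injected current plus an
unknown voltage-dependent remainder, giving the learned one-step map

$$V_{n+1} = V_n + \sum_{c=1}^{N} w_c\,
  e^{-R \lVert S_n - \mu_c \rVert^2} + \alpha\,(I_{n+1} + I_n),$$

with $S_n = (V_n, V_{n-\tau^*}, \ldots)$ a time-delay embedding.

* **Training data**: 5 s at 10 kHz (simulated at $h = 0.02$ ms, decimated by
  5), chaotic stimulus + SNR-5 noise. The noise is part of the training
  conditions; only $V$ and $I_{inj}$ enter the regression.
* **Embedding dimension** (`select_embedding_dim()`): simplex projection
  with delay $\tau^* = 1$ — one-step nearest-neighbor forecasting with
  $E + 1$ neighbors and exponential distance weights
  $e^{-d/d_{min}}$, skill = Pearson correlation between predicted and
  observed next samples, library = first 75% of the series, prediction set =
  the remainder. Ties break toward the smaller dimension. For tractability
  the library is capped at 10,000 evenly strided states and the prediction
  set at 2,000; at 10 kHz the attractor is so densely sampled that the
  strided skill matches the full computation to the fourth decimal. On CS
  training data the selected dimension is 2 for both types (majority over
  seeds), so $S_n = (V_n, V_{n-1})$.
* **Centers** (`fit_centers()`): $N = 50$ k-means centers in embedding
  space, seeded with k-means++ and refined by Lloyd iterations. The ++
  seeding is load-bearing: ~96% of embedded states sit in a dense
  subthreshold cloud, and uniform random seeding reliably leaves the sparse
  spike arc (the states that *define* a spike) without centers, which
  collapses the forecaster to a non-spiking model. With ++ seeding the
  one-step residual in the spike region drops by an order of magnitude.
* **Weights** (`ridge_fit()`): ridge regression
  $W = (X^T X + \lambda I)^{-1} X^T Y$ on the design whose rows are the $N$
  activations plus the current sum $I_{k+1} + I_k$, targets
  $V_{k+1} - V_k$. $R = 0.01$ mV⁻². $\lambda$ is selected by 10-fold
  cross-validation on **contiguous** blocks — the rows are a time series, and
  shuffled folds would leak near-duplicate adjacent samples into the held-out
  sets — over a logarithmic grid $10^{-8} \ldots 10^{2}$ (11 points), ties
  toward the larger (more regularized) value.

**What open-loop forecasts can and cannot do.** Rolled out open-loop
(`forecast_open_loop()`, predictions fed back into the embedding, guard at
|V| > 500 mV), the model reproduces spike counts within a few percent and
spike-distances comparable to the plant's own noise-driven trial-to-trial
variability. Pointwise voltage $R^2$ over multi-second rollouts is modest
(~0.2-0.4): the driven system is effectively chaotic near threshold, so
sub-sample spike-timing drift accumulates, and every slightly mistimed
100 mV spike dominates the squared error. This is a property of long
open-loop rollouts, not of the closed loop — the controller re-measures the
plant every 0.1 ms.

## The controller

`mpc_step()` minimizes, over the next $T$ inputs,

$$s\,e_T^2 + \sum_{n=0}^{T-1}\left[q\,e_{n+1}^2 + r\,(\Delta I_{n+1})^2\right],
\qquad |I_n| \le I_{max} = 100\ \mu A,$$

with the forecaster as the dynamics constraint, errors indexed relative to
the current measurement $V_0$, and $I_0$ = the previously applied input
(0 µA on the very first solve). Defaults: $T = 5$, $s = q = 1$, $r = 0.01$,
control period $\Delta t = 0.1$ ms. The published source for this design
does not list its cost weights; these defaults follow the qualitative
guidance that $r$ must be positive (a zero input-change penalty lets the
optimizer chatter the input between its bounds) but small enough not to slow
tracking. They are exposed in `mpc_config()`.

The box-constrained nonlinear program is solved by a spectral projected
gradient method with analytic gradients propagated through the rollout
(forward-mode accumulation of $\partial V_k/\partial I_j$),
Barzilai-Borwein step lengths, Armijo backtracking along the projection arc,
a stationarity tolerance of $10^{-9}$ on the projected gradient, an
iteration cap of 300, and a warm start from the previous solution shifted by
one step. Two hard guarantees are enforced regardless of solver behavior:
the returned sequence never costs more than holding the previous input
(fallback on any failure, counted in `n_fallback`), and every returned input
respects the box. On one-step-horizon problems with a linear model the
solver matches the hand-derived clamped optimum to $10^{-6}$ (the test
suite checks this).

`run_mpc()` closes the loop: measure the plant, refresh the embedding
history with the *measurement* (never the model's prediction — the noise
level makes pure forecasting untenable), solve, apply only the first input
for one control period, repeat. The first `seed_length(model) - 1` periods
apply zero input while the measurement history fills. The lower input bound
is symmetric ($-100$ µA): only an upper bound is stated where the
optimization is defined in the source material, but its baseline controller
is described as clamped to $\pm 100$ µA, and an unbounded-below current is
physically unreasonable.

**Baselines.** `open_loop_replay()` injects a stored current with no
feedback (on a noiseless plant this reproduces the original trajectory
exactly; on a noisy plant its spread defines the variability that feedback
must beat). `proportional_control()` applies
$I = \mathrm{clamp}(K_p (V - V^{ref}), \pm 100)$ with $K_p = -2$ at the
control period — the same law as an analog voltage clamp. `pulse_control()`
injects 2 ms rectangular pulses at requested spike times with an amplitude
calibrated per neuron type (`calibrate_pulse_amplitude()`: smallest grid
amplitude that elicits exactly one spike per pulse on the noiseless plant).

**Spike-train references.** `spikes_to_reference()` converts a requested
spike train into a voltage trajectory by pasting the mean spike waveform
(`extract_mean_waveform()`, snippets aligned on the detected
threshold-crossing sample) into a $-65$ mV baseline so that each waveform
*peak* lands on a requested time. For CS waveforms at 10 kHz the detected
crossing precedes the peak by at most one sample, so threshold detection on
the constructed reference recovers the requested times to within one sample.
Overlapping waveforms or pulses are rejected rather than summed.

## Metrics

`mse_trace()` is the pointwise mean squared error. `isi_distance()` and
`spike_distance()` implement the standard bivariate Kreuz dissimilarities:
time averages of the instantaneous ISI-ratio profile
$|x_a - x_b|/\max(x_a, x_b)$ and of the spike-timing profile $S(t)$ built
from the distances of the surrounding spikes to their nearest counterparts
in the other train, normalized by the mean local interval. Both are
symmetric, in $[0,1]$, and exactly 0 for identical trains. Edge correction
follows the auxiliary-spike convention (virtual spikes at both window
edges). Both profiles are piecewise constant/linear between pooled spike
times, so the time averages are computed exactly (no sampling grid). A train
with no spikes in the window scores 1 (maximal dissimilarity, with a
warning) against a non-empty train, and 0 against another empty train; the
underlying definitions are simply undefined there, and the controllers'
tasks never score empty references. The test oracle is an independent
pointwise evaluator of the same definitions integrated by two-point
Gauss-Legendre quadrature per segment (exact for these profiles), since no
reference implementation of these metrics ships with R.

## Experiments, seeds and problem sizes

`run_homogeneous()` / `run_heterogeneous()` generate, per trial, a reference
response (chaotic current + fresh noise), then control a fresh
noise-instantiated plant toward it by MPC and by open-loop replay of the
generating current; `run_spike_train()` compares MPC, proportional and pulse
control on a spikes-to-reference target. Every stochastic component (Lorenz
initial condition, reference noise, each control arm's noise, k-means) draws
from sub-seeds derived deterministically from one master seed, recorded in
the output rows, so tables reproduce bitwise.

The bundled tests run 10 trials × 500 ms per condition (homogeneous Type I,
and both heterogeneous directions) — sizes chosen so the whole suite trains
two forecasters and runs ~40 closed-loop trials in well under half an hour
on one core; larger runs (e.g. 50 × 1 s) are a matter of `n_trials` and
`duration` in `experiment_config()`. With these sizes the MPC-vs-open-loop
median orderings are decisive in all three conditions on all three metrics.

## What the synthetic conditions do not capture

The plant is a point neuron with perfectly known, noise-free voltage
measurement and instantaneous current delivery; there is no electrode
artifact, access resistance, measurement noise, slow drift, or plasticity.
Synaptic noise is stationary, balanced and Poisson. Passing tests therefore
demonstrate the soundness of the forecasting-plus-MPC machinery under the
stated conditions, not performance in a physical recording: in particular,
state estimation under measurement noise and robustness to model drift are
explicitly out of scope. Network-level (vector-valued) control is likewise
out of scope: the cost function and forecaster are scalar by design.

Two further caveats the tests quantify: Type-II spiking at the study's
stimulus amplitude (A = 0.5 µA) is substantially noise-assisted — in this CS
variant the noiseless Type-II response to that stimulus is subthreshold — so
forecast-vs-noise parity is evaluated on the strongly driven Type-I
configuration; and long open-loop forecast MSE is dominated by accumulated
spike-timing drift, as discussed above.
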