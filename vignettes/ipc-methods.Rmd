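---
title: "Estimating intermittent postural control models from sway series"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating intermittent postural control models from sway series}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ipcfit)
```

## The model

Quiet standing is modeled as a single inverted pendulum pivoting at the
ankle. Gravity applies a toppling torque proportional to the tilt angle
$\theta$; the body resists it with two mechanisms:

* **passive** resistance — instantaneous stiffness cancelling a fraction
  $K$ of the gravitational stiffness $mgh$, plus joint friction $B$;
* **active** resistance — a delayed corrective torque with proportional
  gain $P$ (as a fraction of $mgh$) and derivative gain $D$, driven by the
  state sensed a feedback delay $\tau$ (about 200 ms) earlier.

The active channel is *intermittent*: it engages only when the lagged phase
point $(\theta_{t-\tau},\, s\,\dot\theta_{t-\tau})$ (with the seconds
constant $s = 1$ s, so both coordinates share units) lies strictly on the
far side of a switching line through the origin with slope
$\alpha = \tan(a\pi)$, and strictly outside an insensitivity disk of radius
$r$ (a sensory dead zone):

$$\theta_{t-\tau}\big(s\dot\theta_{t-\tau} - \alpha\,\theta_{t-\tau}\big) > 0
\quad\text{and}\quad
\theta_{t-\tau}^2 + \big(s\dot\theta_{t-\tau}\big)^2 > r^2 .$$

The passive subsystem alone is a saddle: trajectories near its stable
manifold drift back toward upright on their own, which is exactly where the
active channel can afford to stay off. Acceleration-level white noise of
intensity $\sigma$ drives the sway; observations add a sway origin $\mu$
and Gaussian measurement error of variance $\epsilon$.

Three nested variants are supported: the full intermittent delayed model
(**ISDDE**), the same dynamics with the active channel always on
(**SDDE**), and the delay-free continuous PID reduction (**SDE**).

### The singular vertical switching line

$a = 0.5$ makes the switching line vertical and $\tan(a\pi)$ undefined.
`alpha_from_a(0.5)` therefore signals an error, while the filter and the
simulator represent the geometry as the limit from above
($\alpha \to -\infty$): active feedback everywhere outside the disk. The
limit from below would instead disable the active channel entirely; the
published recovery results for the configuration that uses $a = 0.5$
(sharp estimates of $P$, $D$ and $r$, and noisy-recovery means slightly
*above* 0.5) are only consistent with the upper limit, so that is the
convention implemented.

## The likelihood

`ipc_minus2_loglik()` evaluates $-2\log L$ by the prediction-error
decomposition of a continuous-discrete Kalman filter with three
delay-specific devices:

1. **Lag interpolation.** Lagged inputs are linear interpolations of the
   ring of *corrected* (posterior) state means at offset
   $\lambda = \tau/\Delta t$ steps. The printed form of the interpolation
   weight in the source material extrapolates away from the older sample;
   the package defaults to the standard interpolant and preserves the
   printed sign behind `compat_lag = TRUE` (the two agree at integer
   $\lambda$, which is where the delay estimate lands in the noiseless
   checks).
2. **Backward extrapolation.** Queries before the first observation use a
   quadratic through the trial's fitted initial values,
   $x_0 + \dot x_0 (t-\tau) + \ddot x_0 (t-\tau)^2$ — note the fitted
   coefficient convention: no $\tfrac12$ on the quadratic term.
3. **Two-step prediction across switching events.** When consecutive
   lagged points straddle an activation boundary, the crossing point is
   interpolated (exactly on the switching line; by a first-order
   linearization around the destination point on the circle; at the
   position axis otherwise), the sampling interval is split in proportion
   to the Euclidean distances to the crossing, and the prediction is taken
   in two pieces with the delayed transition active on the correct side.
   The lagged covariance is approximated by the current corrected
   covariance throughout, as in the source method.

Discretization uses augmented matrix exponentials only — `Ad = expm(A dt)`,
the delayed map via $\int_0^{\Delta t} e^{As}\,ds\,A_\tau$, and the noise
covariance by the Van Loan construction — so the $K = 1$ singular stiffness
case needs no matrix inverse. The compiled path uses a fixed-size Padé(6)
exponential with scaling and squaring; it agrees with `Matrix::expm` to
machine precision over the whole optimization box (tested).

### Numerical choices

* **Initial covariance** is zero: the initial state is itself estimated, so
  prior uncertainty would be absorbed by the fitted $x_0,\dot x_0$. A
  diffuse override (`p0`) exists for sensitivity checks; it measurably
  *hurts* optimizer reliability here and is off by default.
* **Conditioning on the first observation.** With $P_0 = 0$ the first
  innovation only measures $y_0 - x_0 - \mu$; as $\epsilon \to 0$ its
  likelihood term degenerates into a hard constraint that ties two fitted
  parameters to the first sample at machine precision, a needle no global
  optimizer should be asked to thread. The decomposition therefore starts
  at the first *prediction*; the first innovation is still reported.
* **Degenerate geometry.** A zero-length lagged segment keeps the shared
  point with `dt_minus = 0`; a segment parallel to the switching line falls
  back to the midpoint; crossings nudged outside the segment by the circle
  linearization are clamped so the split times stay non-negative and sum
  exactly to the sampling interval.
* **Divergence.** Any non-finite state, covariance or innovation variance
  (floored at 1e-30) makes the objective `+Inf`, which differential
  evolution treats as infeasible.

## Simulation

`ipc_simulate()` integrates the SDDE by Euler–Maruyama at a fine step
(default $10^{-5}$ s) with a ring delay buffer; the activation condition is
re-evaluated every fine step from the buffered lagged state, the
pre-history holds the initial state constant, and noise enters at the
acceleration level with intensity $\sigma$ — the *same* convention as the
filter's process-noise matrix, so simulator and estimator are mutually
consistent and parameter recovery is meaningful. `downsample()` decimates
without anti-aliasing, mirroring how an analogue process maps onto discrete
measurements; `observe()` applies the measurement equation.

The six named presets (`ipc_presets()`) span a replication of the classic
intermittent configuration, low- and high-noise variants, passively and
actively dominated regimes, and a heavily damped random-walk regime.

### Physical constants: a documented reproducibility gap

The source material never states the pendulum constants behind its
simulation studies, and the qualitative regime depends on them strongly
through the ratios $mgh/I$, $B/I$ and $D/I$. The package default is the
classic single-link convention $m = 60$ kg, $h = 1$ m, $I = mh^2$. Under
this (and under every alternative we probed: $h = 0.51$ m, normalized
$mgh/I = 1$, current-state switching, and several alternative switching
wedges), not all six presets are simultaneously stationary: with $I = 60$
the delayed damping $D/I$ of the replication set is too weak to stabilize
the always-on dynamics, and its long noisy series exhibit slowly growing
oscillations, while the actively dominated set is bounded and threads its
insensitivity disk. Parameter recovery remains internally consistent
(simulator and filter share every convention), but parameters whose
phase-space regions are never visited — notably $r$ when the trajectory
stays outside the disk — are empirically unidentified, and recovery of the
weakly identified velocity coefficients $B, D$ carries the documented
biases. The decision and its evidence trail are part of the package's
records; the acceptance machinery reports whatever the stated world
actually produces.

## Estimation

The likelihood surface is multimodal and non-smooth at switching events;
local optimizers reliably fail. `ipc_fit()` minimizes the joint
$-2\log L$ (shared structural parameters, per-trial nuisance parameters
$x_0, \dot x_0, \ddot x_0, \mu$) by bounded differential evolution:
DE/rand/1/bin, per-vector dither $F_i \sim U(F, 1)$ with $F = 0.15$,
crossover probability $0.95$, population 30, iteration cap 15000, and a
no-improvement stopping window (500 iterations at relative tolerance
$10^{-10}$). Out-of-bounds coordinates are clipped; random
reinitialization was measured to *reduce* the capture rate of the deep
basins on this surface.

Even so, single runs are frequently captured by a characteristic family of
local optima — intrinsic stiffness pinned at its upper bound, a nearly
inactive switching geometry, and inflated process noise — that can sit
thousands of $-2\log L$ units above the data-generating basin.
`ipc_fit(n_starts = k)` therefore runs $k$ independently seeded searches
and keeps the best likelihood (optionally as cheap screening runs whose
best populations are then refined under the full budget,
`start_iterations`). The delay axis adds comb-like structure of its own —
a delay error can be partially traded against the other gains, so searches
park at a delay bound; `profile_tau = TRUE` re-optimizes the refined
solution within each quarter of the delay bounds and keeps the best
likelihood, the standard profile device for delay estimation. The
noiseless specification check enables both by default. These are
fitting-protocol choices layered *on top of* the published optimizer
settings, which are honored within each component run; the contract is the
optimum reached, not the search path.

Bounds come from `default_bounds()`: one box for simulation studies
(delay constrained to physiologically plausible 150–250 ms) and
variant-specific boxes for empirical series. Model variants are compared
by AIC ($-2\log\hat L + 2k$, every estimated coordinate counted in $k$),
ties resolved toward the simpler model.

## Recovery studies

`run_noiseless_check()` is the specification check: simulate a preset
deterministically from $x_0 = 1,\ \dot x_0 = 0$ for 20 s, downsample to
100 Hz, and fit the full ISDDE. With a correctly specified estimator the
strongly identified parameters ($K$, $P$, $a$, $\tau$ where switching is
expressed in the trajectory) are recovered almost exactly; residual bias
loads on $B$ and $D$, whose influence on the solution is weakest — the
expected signature, which the acceptance suite checks quantitatively.

`run_noisy_recovery()` simulates individuals (several trials each, shared
structural parameters), fits them jointly, and summarizes estimates across
replicates, including the trimmed standard deviation that drops the
largest values. All randomness fans out from one master seed through
`seed_stream()`, so studies are bit-reproducible. Desk-scale defaults (10
individuals, reduced DE iterations) keep a run in minutes; full-scale
reproduction (100 individuals, 60 s trials, full DE budget) is a matter of
passing larger arguments.

### What a green test does and does not establish

The generator reproduces the *stated* world of the recovery studies:
preset parameters, trial lengths, sampling rates, noise levels, fine-step
integration. It does not emulate features of real sway data such as
non-Gaussian disturbances, drifts of the sway origin within a trial,
filtering artifacts of force-plate pipelines, or multi-segment dynamics.
A green recovery test therefore establishes internal consistency of
simulator, likelihood and optimizer — not correctness of the model for
any particular measured series.

## Known limitations

* The lagged covariance approximation and linear lag interpolation bias
  the velocity coefficients; the source material reports the same effect.
* Empirical identification is regime-dependent: parameters are reliable
  only when the trajectory spends time where they act.
* The exact likelihood of the switching diffusion is approximated by a
  per-interval linear-Gaussian filter with interpolated switching times;
  no smoothing pass or exact delayed-covariance propagation is attempted.
* Global optimization on this surface is genuinely hard; all reliability
  statements are per-protocol (multistart) and seeded.
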