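---
title: "The comparator-based timing model: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The comparator-based timing model: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cdtime)
```

## The model

The package treats subjective time as objective time multiplied by a
time-dependent gain factor $\kappa(t)$: an objective interval $\Delta t$ is
experienced as $\kappa \Delta t$, and the period of the internal clock
scales the same way. Deviations from veridical timing are carried by the
relative deviation $D_r = \kappa - 1$ and summarised by the precision
$P = 1/|D_r|$, which diverges at perfect timing. The regulatory assumption
is that deviations are transient: the brain restores $\kappa \to 1$ through
a linear second-order law

$$D_r'' = -a\,D_r - b\,D_r'$$

with a restoring coefficient $a$ (units $1/\mathrm{s}^2$) and a damping
coefficient $b$ ($1/\mathrm{s}$), both positive. The damping term exists to
keep restoration smooth; $b^2 \ge 4a$ (critically damped or overdamped) is
the intended regime, and the package flags underdamped parameterisations
with a warning rather than refusing them. Only the ratios of $a$, $b$
matter under a rescaling of time; we fix time in seconds throughout. The
gain obeys the same equation shifted by one ($\kappa'' = -a(\kappa - 1) -
b\kappa'$), which the solvers exploit as an exact change of variables. The
absolute deviation is proportional to $D_r$ when the objective period is
constant, so it is exposed only as the product $D_a = \tau_p D_r$ rather
than solved separately.

We treat $a$ and $b$ as free parameters of every scenario rather than
per-individual constants: nothing in the model fixes them, and the
inference module exists precisely to estimate them from data.

## Multi-system composition

The total gain is composed from cerebellar, basal-ganglia and cortical
component gains,

$$\kappa = \kappa_{BG}^{w_{BG}} \cdot \kappa_{CTX}^{w_{CTX}} \cdot
C(\kappa_{CBL}, \kappa_{BG+CTX}),$$

equivalently a weighted sum in log space. Three design gaps had to be
closed here, and each choice is deliberate:

* **The combined background gain** $\kappa_{BG+CTX}$ entering the
  comparator is defined as the weight-normalised geometric mean
  $\kappa_{BG}^{w_{BG}} \kappa_{CTX}^{w_{CTX}}$ — the unique dimensionless
  definition under which the multiplicative and log-linear compositions
  are exactly `exp`/`log` images of each other.
* **The comparator form.** The default is
  $C = \kappa_{CBL}^{w_{CBL}} \cdot \kappa_{BG+CTX}^{-g}$ with strength
  $g \in [0, 1]$: at $g = 0$ the comparator contributes only the weighted
  cerebellar gain (the composition degenerates to a three-way weighted
  geometric mean), and at $g = 1$ with a neutral cerebellar signal it
  cancels the cortico-basal-ganglia deviation entirely, which is the
  error-checking role the comparator is meant to play. This is the
  simplest form satisfying the contract we impose on any comparator:
  $C(1,1) = 1$, and $|\ln \kappa|$ non-increasing in $g$ when
  $\kappa_{CBL} = 1$. Alternative forms can be registered
  (`register_comparator()`); registration checks the identity contract on
  a small grid.
* **The weights.** $w_{CBL}, w_{BG}, w_{CTX}$ depend on the interval
  duration $\tau$ being timed: a complementary logistic pair in
  $\log_{10}\tau$ for CBL/BG crossing at `tau_cross` (default 1 s, the
  sub-/supra-second transition), plus a log-Gaussian cortical bump
  (default centre $\log_{10}\tau = 0$, width 0.5, height 0.6), all divided
  by their sum so the three weights add to 1 exactly rather than
  approximately. Five parameters reproduce every qualitative constraint:
  monotone CBL decrease, monotone BG increase, interior cortical peak,
  exact normalisation, and a crossover exactly at `tau_cross` (the
  logistic pair is symmetric, so renormalisation cannot move it). The
  default slope (4 per decade) keeps the transition visibly confined to
  roughly 0.3–3 s. Whether the composition exponents should be constants
  or these $\tau$-dependent functions is genuinely open; the package
  evaluates them at the task's interval duration and accepts an explicit
  constant-weight override in every composing function.

## Disorder presets and scenarios

Disorder regimes are encoded as signs of $\ln\kappa$ per system, with a
single magnitude parameter $\delta$ (default 0.2 on $\ln\kappa$, i.e.
roughly ±20% gain) that is explicitly a user choice — the regime mapping
specifies directions only. Systems marked *unstable* (schizophrenia's
cerebellar and cortical gains, all three in ASD) get a seeded mean-zero
Ornstein–Uhlenbeck process on $\ln\kappa$ with a 2 s correlation time and
stationary sd 0.5: instability is temporal jitter, not a fixed bias, and
mean zero keeps it distinct from dilation or compression. The sd is chosen
once as the package's operational definition of *marked* instability
(gains swinging roughly 0.6–1.65); substantially smaller values leave the
weighted total deviation shallow enough to be indistinguishable from
normal precision at the default weights. The anxiety/PTSD bias is
threat-locked: by default the whole run counts as one threat epoch, and a
`threat_epochs` schedule confines the bias to given windows. Bipolar
mania and depression are separate presets; alternation between them is a
user-supplied schedule of scenario runs, not a built-in oscillation, since
no switching timescale is specified by the theory.

A scenario composes the preset's per-system gain series pointwise into an
equilibrium total gain and adds the response to an optional external
challenge. Because the restoring law is linear, the total deviation is
exactly the equilibrium deviation plus the challenge response integrated
from zero initial conditions; this superposition is the package's
interpretation of how the empirically composed gain and the restoring
dynamics coexist — the composed $\kappa$ is the operating point the
dynamics relax toward, and challenges move the system off it transiently.
A challenge is additive forcing $u(t)$ in the deviation equation: a step
holds $u = a \cdot \mathrm{amplitude}$ over its epoch (so `amplitude` is
the steady-state deviation a sustained challenge would produce), a ramp
reaches that value linearly, and an impulse is an instantaneous velocity
kick. With no challenge the equation is exactly the homogeneous law.

Classification back from a simulated trajectory uses a deviation threshold
$\theta = 0.05$ (time-averaged $D_r$ beyond $\pm\theta$ is dilated or
compressed), at least 3 sign changes with excursions beyond $\theta$ for
*unstable*, and a summary precision $1/\overline{|D_r|} < 8$ for *low*
precision. The summary precision deliberately averages $|D_r|$ before
inverting: the pointwise mean of $1/|D_r|$ is dominated by samples near
zero crossings and does not converge for jittering regimes. For unstable
regimes the precision level is structural — *unstable* when all three
component systems jitter, *low* when only some do — because any pointwise
precision statistic of a mean-zero process is itself too noisy to
threshold reliably. The default scenario window is 30 s (601 samples at
20 Hz), long enough for ~15 correlation lengths of the OU process so the
instability classifications are stable across seeds. Interventions are
parameter edits taking effect at the grid point nearest their onset
(comparator strength, dynamics coefficients, or a shift of one system's
log-gain); modelling neuromodulation as anything richer than a parameter
change is out of scope.

## Task forward models

The synthetic generators emulate the four behavioral/physiological
readouts at trial level, each with the minimal noise model that keeps
durations positive:

* **Interval reproduction.** The gain is applied at encoding and a
  separate gain at readout, giving mean $(\kappa_{enc}/\kappa_{rep})
  \Delta t$. Applying one gain to both stages would cancel exactly and
  predict no bias, so the default readout gain is 1 (a veridical
  comparison stage); both gains are explicit so the convention can be
  inverted. Trial noise is multiplicative lognormal with a given CV,
  mean-corrected so the sample mean converges to the model mean.
* **Temporal bisection.** The judgment criterion is the geometric mean of
  the anchors in subjective units — the standard, parameter-free choice in
  the timing literature — giving $P(\mathrm{long}\mid\Delta t) =
  \Phi\!\big((\ln(\kappa\Delta t) - \ln B)/\sigma_{\ln}\big)$ and an
  objective bisection point $B/\kappa$. A dilated state therefore says
  "long" more often at every probe, which places its 50% point at a
  *shorter* objective duration; the package implements the
  "longer judged durations" semantics and notes that calling this a
  rightward shift conflicts with the usual convention for psychometric
  functions plotted against objective duration.
* **Rhythmic tapping.** Continuation-phase inter-tap intervals have mean
  $(\kappa_{enc}/\kappa_{rep}) \cdot$ period and CV
  $= \mathrm{cv}_0 + c\,|D_r|$: precision alone would predict zero
  variability at $\kappa = 1$, so a motor floor $\mathrm{cv}_0$ (default
  0.05) keeps the model physical, with the precision coupling $c$
  (default 0.5) raising variability as precision falls.
* **EEG spectral peak.** Periods scale by $\kappa$, so frequencies scale
  by $1/\kappa$; the synthetic spectrum is a Gaussian bump on a $1/f$
  background with additive Gaussian noise, and the peak is located by a
  9-bin moving average followed by quadratic interpolation around the
  argmax (deterministic given the data, accurate to a fraction of the
  0.1 Hz default grid step; the interpolation offset is clamped to half a
  bin so a noisy neighbour cannot throw the estimate).

These generators reproduce the direction and magnitude structure of the
model's predictions, not real data: there are no attentional lapses, no
sequential effects, no scalar-timing growth of variability with duration
beyond the CV law, and the EEG readout is a caricature of a resting PSD.
Passing tests therefore show internal consistency of model, generators and
estimators — not that the model fits any empirical dataset.

## Inference

`fit_dynamics()` fits the closed-form solution of the restoring law to
noisy deviation samples by least squares. For fixed $(a, b)$ the solution
is linear in the two basis coefficients of the active damping branch, so
the initial state is profiled out by linear least squares and the
optimisation runs over $(\ln a, \ln b)$ only — a 2-D bounded problem with
16 Latin-hypercube starts (the objective has branch-dependent local
optima), polished by Nelder–Mead to machine precision. The objective is
continuous across the branch boundary (the branches are limits of each
other), so the optimiser can cross it freely. Standard errors come from a
Gauss–Newton covariance at the optimum. Trajectories with maximal
deviation below $10^{-6}$ solve the dynamics for every $(a, b)$ and are
flagged degenerate instead of fitted. The gain estimators invert their
forward models directly: the geometric mean of response/stimulus ratios
(the lognormal MLE; its $-\sigma^2_{\ln}/2$ bias is ~0.1% at the default
noise and ignored) with a seeded 1000-resample percentile bootstrap CI,
and $\hat\kappa = f_{base}/f_{peak}$ for the spectral readout.
`recovery_study()` is a generic seeded harness tabulating bias, relative
error and RMSE per parameter, using population variance so
$\mathrm{RMSE}^2 = \mathrm{bias}^2 + \mathrm{variance}$ holds as an
identity.

## Numerical choices

The closed-form solver selects the damping branch by the sign of
$b^2 - 4a$, with a relative tolerance of $10^{-12}$ around the critical
boundary. The numerical integrator is fixed-step classical RK4 with step
$\le \min(0.005, 0.05/\sqrt{a})$ s: the system is linear and non-stiff at
intended parameters, a fixed step makes runs bit-reproducible, and this
step keeps the global error against the analytic solution below
$10^{-8}$ over a 10 s window across all damping regimes exercised.
Integration spans are split at grid points, at forcing discontinuities and
at an impulse, and stage evaluations at a span's right edge take the left
limit of the forcing, so RK4 never straddles a jump; the impulse state
jump is applied exactly once at its onset. Precision at veridical samples
is the exact `Inf`, written as the literal `inf` in CSV output; a
regularised variant $1/\max(|D_r|, 10^{-6})$ is available for plotting and
fitting. Solvers warn (rather than clip) if a trajectory crosses
$\kappa \le 0$, since a nonpositive subjective-time rate is outside the
model's domain.

Determinism is end-to-end: every stochastic operation derives its stream
from a master seed through named child streams (hash of the stream name
mixed into the seed), so adding a new consumer never perturbs existing
streams, and rerunning any pipeline with the same config and seed
reproduces its CSV artifacts byte-for-byte (timestamps are confined to
the run manifest).

## Problem sizes

The shipped tests run Monte-Carlo checks at $10^4$ trials for the task
direction suite, 20 replicates of 200 samples for noisy dynamics
recovery, 100 seeds for spectral-peak calibration, and 1000 random draws
for the composition equivalence — sizes at which every calibrated
tolerance (1% on reproduction means, 5% on tapping CV, 2% on recovered
gains, 10% median relative error on noisy $(a, b)$) holds with margin
while the whole suite stays under half a minute.

## Limitations

The restoring law is linear and deterministic; stochastic or nonlinear
extensions are out of scope, as are spiking or oscillator-level
physiology, real EEG ingestion, a trial-level eyeblink-conditioning
simulator, and any claim of diagnostic validity for the disorder presets.
The presets encode hypothesised directions, not fitted patient
parameters; the magnitude $\delta$, instability sd and classification
thresholds are package defaults exposed in configuration, not empirical
values.
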