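---
title: "Particle filtering when the measurement times are uncertain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Particle filtering when the measurement times are uncertain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mtupf)
```

## The problem

In clinical and metabolic studies, measurements come from blood or tissue
samples drawn by hand.  The *intended* sampling times $\hat t_j$ are recorded,
but the sample is in fact drawn at a nearby random time $T_j$ that is never
observed.  Where concentrations change quickly — right after a bolus, say —
even small timing errors translate into large value errors.  The standard
work-around is to "lump" the timing error into the measurement noise by
inflating its variance, which distorts the shape of the observation model:
the true predictive spread of a measurement is wide where the state moves fast
and narrow where it moves slowly, while a lumped variance is constant.

`mtupf` implements a sequential Monte Carlo method that keeps the timing
error in the model.  The state follows an Itô SDE
$dX_t = a(X_t, t)\,dt + B(X_t, t)\,dW_t$ (Euler–Maruyama discretization;
times in hours throughout), each measurement $j$ has a value density
$g_j(y_j \mid x_t, t)$ and a *time density* $\gamma_j$ with cdf
$\bar\gamma_{j,t}$ and finite support.  Marginalizing the unknown time
turns the usual point-in-time weight update into a weight *process*: each
particle carries, per observation,

$$w_{j,t} \;=\; 1 - \bar\gamma_{j,t} + \bar w_{j,t}, \qquad
\bar w_{j,t} = \int_{t_0}^t g_j(y_j \mid x_s, s)\,\gamma_j(s)\,ds,$$

and its weight is the product $\prod_j w_{j,t}$, corrected for past
resampling events by the cumulative selection-weight product $\bar v$.
Before any support is entered every factor is exactly 1; after a support
closes the factor freezes at $\int g_j \gamma_j$, which collapses to the
familiar $g_j(y_j \mid x_{\hat t_j})$ update as the time density approaches a
point mass.  The split form above (cdf minus accumulator) is used instead of
accumulating $(g-1)\gamma$ directly because $g$ is often astronomically small
and fixed-precision accumulation of $(g-1)$ would drift; the cdf term is
taken from the analytic antiderivative whenever the density provides one.

The marginal data likelihood is estimated by the mean of the corrected
weights with one multiplicative correction $\tfrac1N\sum_i v^i_{s_\lambda}$
per resampling event, maintained in log space.

## Adaptive stepsize

Because weights change *continuously*, the effective sample size
$n_{ESS} = 1/\sum_i \tilde w_i^2$ moves between measurement supports, and the
discretization step can react to it.  Each step starts from a linear
interpolation between `dt_max` (no ESS change over the last accepted step)
and `dt_min` (a drop of $N-1$, the largest possible), is capped so that
support boundaries and the horizon are always grid points, and is then halved
while the *predicted* ESS falls more than `rel_drop` (default 10%) below the
current one.  The prediction applies the candidate weight update to a copy of
the accumulators; when sampling from the model kernel itself (the package's
default), the update depends only on the left-endpoint states, so the
prediction equals the realized ESS exactly and no states need to be re-drawn
during the search.  The linear form of the initial guess is this package's
concrete choice — the interpolation is only constrained qualitatively by the
method's description — with the drop clamped to $[0, N-1]$ and measured
between the two most recent accepted steps (post-resampling values, since
those describe the weights the next step actually starts from).

The trace records the *pre*-resampling ESS at every accepted step: that is
the quantity that diagnoses degeneracy, and it is what the package's
regression guards compare (the MTU filter's minimum stays near the
resampling threshold where the standard filter's collapses to a few dozen).

## Parameter estimation by augmentation

Static parameters are estimated in a Bayesian way by appending them to the
state with small "artificial" dynamics whose diffusion decays as
$\sigma_\theta(t) = a_\theta/(t-b_\theta)^2$.  The coefficients come from two
interpolation points $(t_0,\sigma_0)$, $(t_1,\sigma_1)$; writing
$r=\sqrt{\sigma_0/\sigma_1}$ gives $b = t_0 + (t_1-t_0)/(1-r) < t_0$ and
$a = \sigma_0 (t_0-b)^2$.  (Derived from the two defining equations; the
one-state example's default schedule $5.43/(t+3.29)^2$ starts at
$\sigma(0) \approx 0.5$, consistent with the same recipe.)  Positive
parameters use the *exact* geometric increment
$\theta \exp(\sigma\sqrt{\Delta t}\,z - \sigma^2\Delta t/2)$ rather than an
Euler step, which preserves positivity for every draw; real-valued random
effects use additive increments.  Estimates are reported as weighted
empirical medians of the final cloud with (0.025, 0.25, 0.75, 0.975)
quantile boxes.

Parameters that matter, with defaults:

* `n_particles` — 10,000 (the estimation-study convention); desk-scale tests
  use 500–2,000.
* `resample_threshold` — $N/2$ (systematic resampling; the leucine study
  convention of $0.75N$ can be passed explicitly).
* `dt_max`/`dt_min` — $10^{-2}$/$10^{-6}$ h for the one-state example,
  $10^{-3}$/$10^{-7}$ h for the leucine model (whose time densities are three
  orders of magnitude narrower).
* `rel_drop` — 0.10; the tolerated predicted per-step relative ESS drop.

## The two built-in applications

**One-state example.**  $dq = (-\alpha q + \beta)dt + \sigma dW$, true
$(\alpha, \beta) = (1, 3)$, $\sigma = 0.05$, $q(0) \sim \text{LogN}(0, 0.1^2)$,
$y_j \sim N(q(T_j), 0.005^2)$, and $T_j$ truncated-normal around intended
times $(0.5, 1, 2, 4)$ with sd $0.3$ truncated at $\hat t_j \pm 1$ and at
$t_0$.  The package bundles the four reference measurements used throughout
its tests and priors $\alpha \sim \text{LogN}(\log 2, 1)$,
$\beta \sim \text{LogN}(\log 6, 1)$ with the geometric artificial-noise
schedule above.  The linear structure of this example is what makes it a
good test bed: conditioned on the initial state it is exactly
Gaussian-linear, so the Kalman filter, closed-form Ornstein–Uhlenbeck
moments and joint-Gaussian density evaluations serve as independent oracles
for the particle filters throughout the test suite.

**Plasma-leucine model.**  Four tracer compartments per patient (plasma,
intra-hepatic, two protein pools) with mass-conserving noise: every
inter-compartment flux perturbs the donor as $q_i\,dt + \sigma_i\,dW_i$, so
the drift is $Kq$ and the diffusion matrix $K\,\mathrm{diag}(\sigma)$ — noise
leaves the system only through the two output channels.  The tracee is in
steady state, solved analytically for the plasma compartment
($Q_1 = (k_{11,2}+k_{1,2})U_1 / (k_{0,1}(k_{11,2}+k_{1,2}) +
k_{11,2}k_{1,2})$), and the measured tracer/tracee ratio carries log-normal
noise ($\sigma_{y_1} = 0.5$).  Mixed effects: group-level degradation rates
$k_{0,1}^c$, $k_{0,1}^d$ and per-patient factors $\zeta_p = e^{\eta_p}$,
$\eta_p \sim N(0, 0.5^2)$.  Fixed constants: $k_{11,2} = 0.01$ (for
identifiability), $p_1 = 0.65$ (not jointly identifiable with $U_1$),
$\sigma_i = 3$.  The package estimates all seven shared parameters and the
$\eta_p$'s jointly on an augmented state of dimension $4P + 7 + P$.
Euler noise can push a tracer mass negative; such particles get observation
log-density $-\infty$ and die through weighting — no clipping is applied, so
the SDE is left untouched.  The tracee side is never integrated (only $Q_1$
is needed, and only it is analytically determined by the printed model).

## What the synthetic generator emulates — and what it does not

`generate_leucine_population()` emulates the study design: a tracer bolus at
$t=0$ (default 50 mg), per-patient random effects on the group rate,
ratio measurements at an early-dense nominal schedule (8 points in
$[0.05, 0.95]$ h, so every measurement-time support fits inside the 1 h
estimation horizon), jittered by the narrow leucine time density (sd
$10^{-3}$ h, truncated at $\pm 10^{-2}$ h).  Generator truths are fixed
once: group rates $0.577$/$0.346$ h$^{-1}$ (the magnitudes the estimation
study reports), remaining rates near the prior medians ($k_{1,2}=0.5$,
$k_{1,3}=0.2$, $k_{3,1}=0.3$, $k_{4,3}=0.1$, $U_1=100$).  It does *not*
emulate the real study's 8-hour sampling tail, its patient-specific boluses,
or any model misspecification — so passing recovery tests show that the
filter inverts its own generative model at realistic noise levels, not that
the leucine model is correct for real patients.  With only two patients per
group, the group-mean random effect has sampling sd comparable to the true
group separation ($\log(0.577/0.346) \approx 0.51$), so recovery tests keep
the population fixed and vary the filter seed; fresh-population replication
at this size would be limited by design power, not by the filter.

## Numerical choices

* All weight arithmetic in log space; products of per-observation factors
  with an exact zero short-circuit to $-\infty$ without contaminating the
  other factors.
* $\bar\gamma$ from the analytic cdf; $\bar w$ follows the
  basic left-endpoint Euler rule $g(t)\,\gamma(t)\,\Delta t$ for densities the
  step grid can resolve, and switches per observation to the exact
  mass-increment form $g(t)\,[\Gamma(t+\Delta t)-\Gamma(t)]$ when a
  density's support spans fewer than 50 maximal steps (a left-Riemann sum
  over a near-point-mass spike misestimates its mass by order one; the
  mass form is what makes the point-mass regularization limit recover the
  standard filter).  Densities without a cdf always use plain Euler.
* Step endpoints snap onto support boundaries within $10^{-9}$ h — far above
  the floating-point error a grid accumulates over $10^4$ additions, far
  below any usable stepsize — so "support entered" bookkeeping can never
  disagree with the cdf by a step's worth of mass.
* Resampling: systematic by default (lowest variance), with stratified and
  multinomial available; selection weights are the current combined weights,
  so corrected weights are exactly 1 after each event.
* Complete weight collapse raises an error that carries the trace up to the
  failure rather than renormalizing silently.
* Measurement times (standard filter) and support boundaries (MTU filter)
  are always grid points; the reference measure for observation values is
  Lebesgue.
* Traces record ESS, cumulative log-likelihood and accepted stepsize at
  every step; weighted quantiles are thinned to ~200 record times (they are
  smooth and would otherwise dominate trace size).
* The ML baseline conditions on a sampled initial state (the linear example
  is exactly Gaussian given $q_0$ and $\theta$), uses closed-form moment
  propagation evaluated stably for small $\alpha$, and optimizes over
  $(\log\alpha, \log\beta)$ with BFGS at relative tolerance $10^{-8}$.

## Problem sizes used by the shipped tests

The test suite runs the one-state estimation study at $N = 10{,}000$ over ten
seeds, desk-scale leucine recovery at $N = 2{,}000$ over twenty filter seeds
on a fixed 4-patient population, and Monte Carlo property checks at
$10^3$–$10^4$ replicates; these sizes make every Monte Carlo tolerance a
3-standard-error bound of the quantity it checks.  The full 34-patient
leucine study (which needs the original clinical data file and runs for
hours) is out of desk scale; its configuration is reproduced by
`run_config(model = "leucine", ...)` given such a file in the documented
population format.

## Known limitations

* Only Euler–Maruyama propagation (no higher-order schemes) and only the
  prior proposal is exercised by the shipped applications; custom proposal
  kernels are supported by contract but the ESS prediction then requires
  re-sampling states, which the stepsize search does not do (it falls back
  to plain halving against the floor).
* Measurement times are assumed independent across observations; order
  constraints would need support restrictions.
* Online estimation with finite-support densities (delayed by the support
  diameter) is not implemented.
* Rao–Blackwellization of conditionally linear sub-models and PMCMC-style
  exact parameter inference are out of scope.
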