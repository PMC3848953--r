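# mtupf

Sequential Monte Carlo for continuous-time state-space models in which the
*times* of the measurements are random variables with known densities — the
situation of hand-drawn blood or tissue samples in PK/PD and metabolic
studies, where the intended sampling time is recorded but the actual draw
happens a little earlier or later and concentrations change fast.

For an Itô SDE state $dX_t = a(X_t,t)\,dt + B(X_t,t)\,dW_t$ with observation
densities $g_j(y_j \mid x_t, t)$ and measurement-time densities $\gamma_j$
(pdf, cdf, finite support), the measurement-time-uncertainty particle filter
(MTU-PF) replaces the standard point-in-time weight update by per-observation
weight *processes*

$$w_{j,t} = 1 - \bar\gamma_{j,t} + \int_{t_0}^t g_j(y_j\mid x_s,s)\,
\gamma_j(s)\,ds,$$

whose product (with resampling corrections) weights each particle, an
ESS-driven adaptive discretization stepsize, and a corrected marginal
data-likelihood estimator
$\hat Z_t = N^{-(\ell+1)}\prod_\lambda \left(\sum_i v^i_{s_\lambda}\right) \sum_i w^i_t$.
The package also provides the standard particle filter, a conditionally exact
continuous/discrete Kalman-filter ML baseline for the linear example,
Bayesian parameter estimation via state augmentation with decaying artificial
parameter dynamics, a four-compartment plasma-leucine tracer/tracee
mixed-effects model with two patient groups, and synthetic-data generators
for both applications.

## Worked example

Estimate the drift parameters of the one-state example
$dq = (-\alpha q + \beta)\,dt + 0.05\,dW$ (true values $\alpha=1$,
$\beta=3$) from four measurements taken at uncertain times around the
intended times $(0.5, 1, 2, 4)$ h:

```r
library(mtupf)
set.seed(1)

cfg   <- motivating_config()                  # the example's study conditions
dat   <- motivating_example_data()            # bundled reference measurements
model <- motivating_estimation_model(cfg)     # (q, alpha, beta) augmented state
obs   <- motivating_observations(dat$values, cfg)

trace <- mtu_pf(model, obs, n_particles = 10000, t_end = 10)
trace
#> <filter trace>  1010 steps on [0, 10], N = 10000
#>   final log-likelihood -4.9838 | min ESS 4544.6 | 12 resamplings

final_estimates(trace, coords = c("alpha", "beta"))
#>   coord    q0.025     q0.25     q0.5    q0.75    q0.975
#> 1 alpha 0.3842616 0.7274581 1.076144 1.753152  6.481207
#> 2  beta 1.1305604 2.1869426 3.218333 5.218348 19.602096
```

The weighted medians (the `q0.5` column — the point estimates) land near the
truth; the quantile boxes describe the terminal cloud of the
*diffusing-parameter* model, which is wider than a fixed-parameter posterior
because the artificial dynamics keep perturbing the parameters over the whole
horizon.  The ESS never collapses (its minimum stays near the resampling
threshold $N/2$) because the weights evolve continuously through each
measurement's time-density support instead of jumping at a single grid time.  Treating the intended times as exact and
lumping the timing error into the measurement noise, the standard filter is
markedly worse — with lumped sd 0.5 it gives $\alpha \approx 1.16$,
$\beta \approx 3.37$, and with the true value-noise sd 0.005 it degenerates
($\alpha \approx 7$, ESS dropping to a handful of particles).  The same
failure shows up in the Kalman-based ML baseline (`ml_estimate()`).

The two-group leucine study runs the same way through
`generate_leucine_population()` / `build_population_model()` (or
`run_config(model = "leucine", observations = "<population file>")` for data
in the documented plain-text dialect), estimating the seven shared kinetic
parameters and the per-patient random effects jointly.

A thin CLI wraps the same functions:

```sh
inst/cli/mtupf filter-mtu --n 10000 --seed 1 --out-dir run/
inst/cli/mtupf simulate-leucine --control 2 --diabetes 2 --out pop.txt
```

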