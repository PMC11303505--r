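---
title: "Models and methods for extracellular flux estimation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods for extracellular flux estimation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(exflux)
```

## The estimation problem

A batch culture is sampled over time and the concentrations of biomass
($X$, e.g. gDW/L) and of one or more extracellular metabolites ($M_j$,
e.g. mM) are measured. Given a growth model — a parameter vector $p$ and
rate equations

$$\frac{dX}{dt} = f(p, X, M), \qquad \frac{dM_j}{dt} = g_j(p, X, M_j),$$

exflux estimates $p$ (growth rate, lag time, initial concentrations,
exchange fluxes, degradation constants, ...) by weighted least squares.
With measured values $x_i$, per-variable measurement standard deviations
$\sigma_i$, and model predictions $y_i(p)$ at the same time points, the
objective is

$$c(p) \;=\; \sum_i \left( \frac{x_i - y_i(p)}{\sigma_i} \right)^2,$$

summed over every non-missing observation of biomass and of every
metabolite. Missing cells simply drop out of the sum. The exchange flux of
metabolite $j$ is a single signed per-biomass rate $q_j$
(mmol gDW$^{-1}$ h$^{-1}$): negative for uptake, positive for production.

## Built-in models

Four steady-state (balanced-growth) models assume constant $\mu$ and $q_j$,
which gives closed-form trajectories; the fifth is a dynamic Monod model
integrated numerically.

| model | biomass | metabolites |
|---|---|---|
| `exponential` | $X = X_0 e^{\mu t}$ | $M_j = M_{j0} + \frac{q_j}{\mu} X_0 (e^{\mu t} - 1)$ |
| `exponential_lag` | frozen at $X_0$ until $t_{lag}$, then exponential in $t - t_{lag}$ | same shift |
| `exponential_degradation` | $X = X_0 e^{\mu t}$ | $M_j = M_{j0} e^{-k_j t} + \frac{q_j X_0}{\mu + k_j}(e^{\mu t} - e^{-k_j t})$ |
| `exponential_lag_degradation` | as lag | decay-only during the lag, then the degradation form re-anchored at $t_{lag}$ (continuous there) |
| `monod` | $dX/dt = \mu_{max}\frac{S}{K_m + S}X$ | $dS/dt = -\frac{1}{yield}\,dX/dt$ |

These closed forms are the unique solutions of the rate laws
$f = \mu X$ and $g_j = q_j X$ (plus, where applicable, a first-order
abiotic degradation term $-k_j M_j$ and a lag phase). Design choices worth
stating explicitly:

* **Anchoring.** $X_0$ and $M_{j0}$ refer to $t = 0$ of the time axis in
  the data file, not to the first observed time. This keeps the closed
  forms unambiguous when the first sample is late.
* **Lag phase.** During the lag the cells are taken to be metabolically
  inactive: exchange is frozen and only abiotic degradation acts on the
  metabolites. Other conventions exist (e.g. reduced but nonzero uptake);
  with typical lag times of an hour or less the difference is usually
  below measurement noise, but it is a modelling assumption, not a fact.
* **Monod parameterization.** The Monod model is the conventional
  single-substrate form with parameters $\mu_{max}$ (1/h), $K_m$
  (concentration) and a biomass yield on substrate; it requires exactly
  one metabolite column. Multi-substrate or flux-parameterized variants
  are deliberately out of scope — they can be added through the user-model
  template (`system.file("extdata", "model_template.R", package = "exflux")`).
* **Removable singularities.** The metabolite closed forms divide by $\mu$
  (or $\mu + k_j$). Direct simulation at $\mu = 0$ uses the series limit
  ($M_j = M_{j0} + q_j X_0 t$), but fitting keeps the lower bound of $\mu$
  strictly positive (default $10^{-6}$) so the optimizer never sits on the
  singular manifold.

Analytical models still carry their rate equations: the package contract —
enforced by the test suite — is that every closed form agrees with
numerical integration of its own ODEs to $10^{-6}$ relative across random
parameter draws. Integration uses `deSolve::lsoda` at rtol $10^{-8}$ /
atol $10^{-10}$, one order tighter than the agreement it must support, with
the lag breakpoint inserted into the solver mesh so the rate discontinuity
at $t_{lag}$ is stepped through exactly.

## Optimization

`fit_growth()` minimizes $c(p)$ in two stages within user-editable bounds:

1. **Global stage: differential evolution** (best/1/bin), population
   $15 d$ for $d$ free parameters, mutation factor dithered in $(0.5, 1)$
   each generation, crossover 0.7, latin-hypercube initialization with the
   user's initial values injected as one member, convergence when the
   population energies collapse to 1% relative spread.
2. **Local stage: bounded quasi-Newton refinement** (L-BFGS-B). The local
   stage is restarted with the parameter scale re-estimated from the
   current point until the objective stops improving; this matters because
   the parameters span orders of magnitude (an inoculum of $10^{-2}$ gDW/L
   next to a 20 mM substrate pool) and finite-difference gradients on a
   fixed scale stall in the narrow curved valleys typical of exponential
   objectives. The refinement is seeded not only from the DE winner but
   also from up to two well-separated members of the final DE population
   and from the initial values — a guard against the occasional premature
   collapse of the population onto a plateau (for example a lag time
   beyond the observation window, where the objective is locally flat and
   gradients cannot escape). The best refined candidate is returned, and is
   never worse than the global stage's optimum.

Simulation failures during the search are treated as infinitely bad and
counted in the run log. A best fit sitting on a bound raises a warning,
not an error.

## Uncertainty: parametric bootstrap

`mc_uncertainty()` resamples the *fitted* model: each iteration adds
independent Gaussian noise (the configured $\sigma_i$) to the best-fit
trajectory at the observed times, respecting the missingness pattern, and
re-fits. Re-fits use the bounded quasi-Newton stage started from the point
estimate: by construction of the parametric bootstrap the perturbed
optimum lies in the fitted optimum's basin, and a fresh global search per
iteration would multiply the cost a hundredfold without changing the
resampling distribution. The 95% confidence intervals are the empirical
2.5%/97.5% percentiles over the default 100 iterations. Resampled
concentrations are deliberately **not** clipped at zero: clipping would
bias the noise distribution the intervals are built on. Iterations whose
re-fit fails are dropped and logged; more than 50% failures aborts.

An alternative would be residual resampling; the parametric form was
chosen because it matches the noise model the objective already assumes,
making the chi-squared calibration of the whole pipeline testable.

## Goodness of fit and model choice

With $\sigma_i$ treated as known, the optimal objective $c$ is
asymptotically $\chi^2$ with $n - k$ degrees of freedom ($n$ non-missing
observations, $k$ free parameters); `gof_test()` reports the upper-tail
p-value and an accept/reject verdict at $\alpha = 0.05$ by default.
`aic_scores()` uses the least-squares surrogate
$\mathrm{AIC} = n \ln(c/n) + 2k$ and
$\mathrm{AICc} = \mathrm{AIC} + 2k(k+1)/(n-k-1)$; the dropped likelihood
constant is shared by all models fitted to the same data, so rankings are
unaffected. `rank_models()` sorts by AICc (small-sample safe; AIC where
AICc is undefined), breaks ties by model name, and flags
$\Delta\mathrm{AIC} < 2$ rows as having similar support.

## Synthetic data: what it emulates and what it does not

`generate_dataset()` / `generate_batch()` simulate a chosen model at known
parameters and add independent, homoscedastic Gaussian noise per variable
— the same noise model the objective assumes. The reference conditions
(`builtin_truth()`) describe an *E. coli*-like batch culture on glucose:
inoculum 0.02 gDW/L, $\mu \approx 0.6$–0.8 1/h, 15–20 mM substrate,
uptake fluxes of 3–4 mmol gDW$^{-1}$ h$^{-1}$, a 1 h lag and a 0.05 1/h
degradation constant where applicable, sampled at 12 points over 8 h —
values picked once so every concentration stays non-negative across the
window and every parameter sits inside the default bounds. Where a noise
level is quoted as a percentage (e.g. "2% noise"), it means a per-variable
standard deviation of 2% of that variable's dynamic range
($\max_t |y(t)|$).

Passing the recovery, calibration and coverage tests on such data shows
the estimator, the statistics and the bootstrap are implemented correctly
and are self-consistent. It does **not** show that real instruments behave
this way: OD-derived biomass noise is typically multiplicative, LC-MS
drifts, sampling can be irregular, and $\sigma_i$ is rarely known exactly.
With misspecified $\sigma_i$ the parameter estimates are unchanged
(weights rescale the objective) but the $\chi^2$ verdict and the interval
widths inherit the misspecification.

## Problem sizes used in the validation suite

The test suite fixes its simulation sizes once: 12-point noiseless
time courses for the recovery checks (the five built-in models, plus a
50-experiment batch), 20 random parameter draws per analytical model for
the closed-form/ODE agreement, 200 replicates for the uniformity of
goodness-of-fit p-values (Kolmogorov–Smirnov at $\alpha = 0.01$), 100
replicate datasets with 100 bootstrap iterations each for interval
coverage (nominal 95%, accepted 88–100/100), and 50 replicates at 2%
noise for the model-recovery ranking check. These sizes give the
statistical checks enough resolution to fail loudly on real defects while
keeping the full suite comfortably runnable on a laptop.

## Known limitations

* All five built-in models assume a closed batch: no dilution, feeding,
  pH coupling or product inhibition. Such mechanisms belong in user models.
* One signed flux per metabolite; simultaneous uptake and production of
  the same compound are not separable from these data.
* The $\chi^2$ test requires trusted $\sigma_i$; it has no variance-scale
  estimation fallback.
* Differential evolution is stochastic: results are reproducible only
  under a seed (every fit, bootstrap and batch accepts one, and the run
  configuration records it).
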