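---
title: "Adaptation models for regimes painted on phylogenies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptation models for regimes painted on phylogenies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ouregime)
```

## The model

`ouregime` studies how a continuous species trait — canonically log
endocranial volume, in log cc — adapts to discrete selective regimes (diet,
mating system, activity period) and continuous predictors on an ultrametric
phylogeny. The trait `y` follows an Ornstein–Uhlenbeck (OU) process pulled
toward a primary optimum that depends on the regime history `z` painted on
the tree and on a Brownian predictor `g` (log group size), with an
immediate, *direct* effect of a covariate `x` (log body mass):

    dy = -alpha (y - theta(z, g)) dt + b dx + sigma_y dB_y
    dg = sigma_g dB_g
    dx = sigma_x dB_x

The adaptation rate `alpha` is reported as the **phylogenetic half-life**
`t_half = ln(2) / alpha`, the time for the expected trait to cover half the
distance from its ancestral state to the current optimum, in units of tree
height (trees are scaled to unit height; `original_height` converts back to
absolute time). The diffusion `sigma_y` is reported as the **stationary
variance** `Vy = sigma_y^2 / (2 alpha)`, the equilibrium residual variance
under a constant regime; in the Brownian limit below, `Vy` is instead the
diffusion variance per unit tree height.

Expected tip values are weighted sums over each lineage's regime history:
regime `r` receives weight `sum over epochs of exp(-alpha (T - t_end)) -
exp(-alpha (T - t_start))`, the ancestral state receives `exp(-alpha T)`,
and the weights sum to one (`regime_weights()`). A species that entered its
current regime recently is therefore still partly shaped by its past
regimes — the central difference from instant-adaptation (OLS-like) models.

**The trend limit.** When the half-life grows without bound while optima
diverge, the process converges on a Brownian motion with *niche-specific
deterministic trends* `tau_r` (trait change per tree height): the expected
tip value becomes a time-weighted sum of the trends experienced along the
lineage. Because all tips are at the same distance from the root, trends are
identified only up to an additive constant (they share the root state), so
they are reported relative to that confounded constant and only *contrasts*
between trends are meaningful (`regime_contrast()`).

## Design matrix and the ancestral state

On an ultrametric unit-height tree the ancestral-state weight
`exp(-alpha)` is the same for every species, and the regime weights sum to
the constant `1 - exp(-alpha)`; the ancestral column is therefore *always*
collinear with the regime columns, not only in the single-regime case. The
package resolves this by assuming the root sits at the optimum of the
root's regime: the ancestral weight is added to that regime's column. In
the trend limit the constant column is dropped outright, which is why trend
tables print no separate intercept. An allometric-only model (no regimes)
keeps a plain intercept.

## Predictors, measurement error, and the residual covariance

* **Direct effect.** `x` enters the design with its observed values; the
  estimated slope `b` is the unattenuated within-lineage response.
  Observation error in `x` (squared standard errors of species means) adds
  `b^2 * var_obs(x)` to the residual diagonal; because `b` itself is being
  estimated, the fit iterates the slope and the covariance to convergence
  (tolerance 1e-6, at most 50 rounds).
* **Brownian predictor in the optimum.** For `g` the estimated
  coefficient is the *evolutionary* slope `beta = k * rho(alpha, T)`, with
  `rho = 1 - (1 - exp(-alpha T)) / (alpha T)`; the slope of the optimum
  (`k = beta / rho`) is reported only for finite half-lives since `rho -> 0`
  in the trend limit. Because `y` tracks `g` with a lag, the residuals gain
  covariance beyond the OU kernel. Writing the weighted path integral
  `L_i = alpha * int (g(t) - g0) exp(-alpha (T_i - t)) dt` and using
  `min(t, t', s) = int_0^s 1[w<t] 1[w<t'] dw`, all required moments reduce
  to one-dimensional integrals with closed forms (`bm_lag_cov()`); the
  diagonal reduces, in the trend limit, to the classic Brownian-bridge
  integral variance `sigma_g^2 / 12`, a useful sanity anchor. The term is
  exactly quadratic in `beta`, so the fitting loop caches the unit-slope
  kernel per half-life. Since the SDE system itself does not hand us this
  covariance, it is *certified against the simulator*: the test suite
  compares the analytic matrix with the empirical tip covariance of 10,000
  simulated replicates, entrywise within three Monte-Carlo standard errors,
  for all four model variants.
* **OU kernel.** `Vy (1 - exp(-2 alpha s_ij)) exp(-alpha d_ij)` with `s`
  the shared time and `d` the patristic distance; `Vy * s_ij` in the trend
  limit. Response observation variances sit on the diagonal.

## Inference

Coefficients are profiled out by GLS (Cholesky whitening, never an explicit
inverse), and the remaining two parameters are maximized on a grid: by
default 50 log-spaced half-lives in [0.01, 100] tree heights plus the trend
boundary, and 50 log-spaced `Vy` values spanning 1e-4 to 10 times the
response variance, followed by bounded local refinement of both the best
finite-α point and the trend boundary. **Support sets** are the parameter
values whose profile log-likelihood lies within 2 units of the maximum,
reported as intervals (possibly reaching infinity). For the half-life the
profile is computed properly: `Vy` is re-optimized continuously at every
half-life value (the design matrix and covariance kernels are fixed within
a half-life, so this is cheap), and the interval endpoints are located by
root-finding on the profile rather than snapped to grid points — against
the refined maximum, grid-resolution profiles shrink support intervals
enough to break their nominal coverage. `Vy` support intervals remain
grid-resolution.

**Choosing between OU optima and the trend limit.** The trend model sits on
the boundary `alpha = 0` of the OU family, and under a true Brownian trend
the maximum-likelihood adaptation rate lands at an interior value in about
half of all replicates (the familiar upward bias of `alpha` under Brownian
truth). A raw likelihood comparison would therefore call an OU optimum on
trend data half the time. The package instead compares the two candidates by
AICc, counting one parameter fewer for the trend model (its half-life is not
estimated); this matches how candidate predictor sets are ranked and, in
simulation, calls the generating kind correctly in ~95% of trend replicates
without sacrificing detection of genuine finite half-lives. A consequence is
that the AICc parameter count is `#coefficients + 2` for OU fits and
`#coefficients + 1` for trend fits.

`R^2` is `1 - RSS/TSS` with both sums GLS-weighted by the model's own
covariance (TSS around the GLS grand mean). The **residual R²** of a model
is the share of the variance left by the allometric (body-mass-only)
baseline that its ecological/social predictors explain:
`(R2_full - R2_allom) / (1 - R2_allom)` — the relevant scale when body mass
alone explains ~80% of brain-size variance. Effect sizes on the natural-log
scale are translated with `effect_transform()` (fold changes, percent
shifts, percent change per doubling of a predictor via `ln 2`).

## Regime histories: Mk models and stochastic maps

Discrete predictors are mapped onto the tree with continuous-time Markov
models fitted by pruning (`fit_mk`), choosing among equal-rates, symmetric,
and all-rates-different matrices by AICc. Defaults and numerical choices:

* Root prior: the stationary distribution of the fitted matrix, with a flat
  option — the choice is declared, not derived.
* Rates are optimized on the log scale in [1e-8, 1e3] per unit tree height
  from three starting values, to dodge local optima.
* Marginal ancestral states come from an exact two-pass message schedule;
  MAP ties are broken lexicographically.
* `stochastic_maps()` samples joint node states backward from the pruning
  partials and fills in branch histories by *uniformization* (rejection
  sampling degenerates for low rates on long branches). Sampled histories
  are valid paintings whose endpoints match the node states by
  construction.
* A MAP painting places each edge in its child node's state, i.e. shifts at
  the rootward end of edges. This convention makes a node-state map fully
  determine a painting; the alternative (shift at the tipward end) would
  systematically shorten time spent in derived regimes.

## The synthetic world

`generate_study_like()` states one world and keeps it fixed: 128 species on
a unit-height pure-birth tree; a 2-level diet factor and a 5-level
mating-system factor evolving at 0.5 expected changes per tree height each
(a binary activity factor at 0.3); Brownian log body mass spanning roughly
two decades (diffusion variance 2.25, root log 5000 g) and Brownian log
group size (variance 1, root log 8); an OU response with half-life 2.63 tree
heights, stationary variance 0.18, direct slope 0.56, evolutionary
group-size slope -0.04, and crossed diet-by-mating optima of the magnitudes
reported in comparative primate brain-size tables; species means observed
with per-species sample sizes 1–30 and within-species SDs of 0.15 (log ECV)
and 0.2 (log body mass), reported as squared standard errors. These values
are the published magnitudes where such exist and field-plausible choices
where they do not; they were fixed once and are not tuned to test outcomes.

Two deliberate conventions in the simulator:

* The per-branch exact update adds the direct effect as
  `b (x_child - x_parent e^{-alpha l})`, i.e. `y = b x + u` with `u` an
  exact OU. Letting past direct effects decay (`+ b * delta x` alone) would
  contradict the estimator's semantics, under which the observed slope on
  `x` is the unattenuated `b`; the two coincide in the trend limit.
* When the optimum tracks `g`, no exact update exists, so `g` and the
  response are co-simulated by Euler–Maruyama at step 1e-3 tree heights —
  small enough that halving it moves 5-taxon tip moments by well under the
  Monte-Carlo noise at 10,000 replicates.

What a green test does **not** establish: the pure-birth topology is more
balanced than real primate phylogenies; regime factors evolve independently
(no diet–sociality correlation); observation error is Gaussian and
independent across species; and within-species sample sizes are uniform
rather than museum-skewed. Recovery results transfer to real data only to
the extent these simplifications are benign.

The parameter-recovery check (100 replicates at the world above) runs each
fit on a coarser grid (20 half-lives × 16 variances plus the trend boundary,
with local refinement) so the suite fits a single-CPU budget; the default
50×50 grid changes estimates only at the third decimal on these data.

## Degenerate inputs and numerical edges

* Trees must be ultrametric within a relative tolerance of 1e-6 (consensus
  trees carry rounding noise); after scaling, tip depths are snapped to 1
  within 1e-9. Non-ultrametric (fossil-tip) trees are out of scope.
* Regime levels with zero total weight across all species are dropped and
  flagged rather than allocated coefficients; diet ties are coded as
  neither frugivorous nor folivorous, with a warning; cathemeral activity
  is recoded diurnal; group-size bins round half-up since the category
  bounds are integers.
* A non-positive-definite assembled covariance aborts with a condition
  estimate rather than silently regularizing.
* Likelihood grid cells where the GLS step fails score `-Inf` and never
  become the optimum.

## Limitations

* No Bayesian shift search, no multivariate response, no within-species
  allometric-slope variation.
* Near the OU/trend boundary the half-life is weakly identified; support
  intervals routinely reach infinity and should be read as such, not as
  point estimates.
* Printed contrasts in comparative tables are sometimes computed on
  transformed scales that the plain coefficient-difference machinery of
  `regime_contrast()` does not reproduce; the function documents the
  standard linear-combination construction and nothing more.
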