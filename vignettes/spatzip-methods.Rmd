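---
title: "Methods: spatio-temporal ZIP disease mapping in spatzip"
author: "spatzip authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatio-temporal ZIP disease mapping in spatzip}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spatzip)
```

# The problem and the data model

Routine surveillance of a common respiratory infection produces monthly
case counts per small administrative area, stratified by age group
(under/over 15 years) and sex, alongside monthly climate covariates and
a static altitude per area. Three features dominate such data: a large
excess of zero reports relative to a Poisson model (months in which a
facility reported nothing, indistinguishable from true zeros), strong
12-month seasonality, and spatial correlation between neighbouring
areas. `spatzip` treats these with, respectively, zero-inflated Poisson
(ZIP) likelihoods, seasonal-trend decomposition by loess, and intrinsic
conditional autoregressive (ICAR) random effects over a queen-contiguity
graph.

A `surveillance_panel` is a complete grid: one row per (area, month,
age, sex) with a non-negative integer count and a positive population.
Completeness is enforced at read time with the missing cells named,
because every downstream operation (expected counts, model frames,
the zero audit) assumes the grid. Recorded zeros are taken at face
value — the data model cannot distinguish a non-reporting facility from
a month without cases, which is exactly why the ZIP mixture is used.

# Descriptive surface

Expected counts are built from the overall rate: the expected count of
a row is its stratum population times (total cases / total population)
divided by the number of months. This makes expected counts conserve
the observed total exactly, so the population-weighted mean SMR is 1 by
construction and per-area SMRs (`O_i / E_i`) read as relative risks
against the national average. "Average population" is the mean of the
stratum populations over the study period; annual incidence uses that
year's population. The SMR defaults to the total expectation over all
strata; a stratum-specific variant is exposed for externally supplied
rate tables.

# Seasonal decomposition

The monthly series is log-transformed and decomposed additively,
`Y_t = T_t + S_t + R_t`, in the periodic mode of STL: the seasonal
value of each calendar month is its cycle-subseries mean (centred so a
full cycle sums to zero), the trend is a degree-1 loess of the
deseasonalised series with the reference STL span
`nextodd(1.5 * period)`, and the two steps are iterated until the trend
changes by less than 1e-8 (at most 10 passes). The remainder is defined
by subtraction, so additivity is exact by construction, and both steps
are linear in the data, which gives exact location equivariance. The
inner loop is implemented in the package rather than delegated because
the periodic mode is well defined down to exactly two observed cycles,
the shortest series the contract accepts; the test suite cross-checks
the components against `stats::stl(s.window = "periodic")` on longer
series.

Zeros under a strict log are an error; an opt-in `log(x + 1)` offset is
available and recorded in the result, since no principled zero rule
exists for log-scale decomposition of counts. Seasonal peaks are the
local maxima of the 12-value cycle on a circular neighbourhood; a cycle
whose range is below 1e-8 is flagged degenerate rather than yielding
spurious peaks.

# Covariate screening

Each climate variable is screened univariately at lags 0-3 months with
Poisson regressions of the area-month totals offset by log expected
counts. All lags are fitted on the common months where every candidate
lag has an antecedent observation — AIC values are only comparable on
identical data, and fitting each lag on its own maximal subset makes
AIC fall mechanically with the lag. Months without an antecedent
observation are dropped, never zero-filled. The chosen lag minimises
AIC among lags with Wald p < 0.05; ties resolve to the smaller (most
proximal) lag. Wald rather than likelihood-ratio p-values are used for
the screen; the two agree to first order at these sample sizes and the
Wald form is what the per-lag coefficient table already carries.

Collinearity uses the classical variance inflation factor,
`1/(1 - R^2)` from OLS of each covariate on the rest, with covariates
above 4.0 flagged; exact collinearity is reported as infinite rather
than a large number. The ZIP-versus-Poisson comparison fits the ZIP
maximum likelihood with a single constant inflation probability by EM
(posterior structural-zero memberships, then weighted Poisson IRLS and
an `omega` update, to an absolute log-likelihood tolerance of 1e-8).
When the data carry no evidence of extra zeros the likelihood is flat
in `omega` near zero and EM creeps sublinearly, so `omega < 1e-6` is
collapsed to the boundary and the fit reduced exactly to the Poisson
MLE. The Vuong statistic is the uncorrected form,
`sqrt(n) mean(m) / sd(m)` on pointwise log-likelihood differences;
degenerate cases (one row, or identical likelihood vectors) are flagged
inconclusive instead of returning a number.

# The Bayesian spatial models

The four nested models share seven fixed effects — age, sex, a linear
trend, altitude per 100 m, maximum temperature per degree C, rainfall
per 10 mm lagged one month, relative humidity per percentage point
lagged three months — and differ only in their random effects: I has
iid area effects `u_i`, II has ICAR effects `v_i`, III is the BYM
convolution `u_i + v_i`, and IV adds a spatio-temporal term `w_ij`.

The internal structure of `w_ij` is a genuinely open design point: a
reported per-area *trend* derived from spatio-temporal random effects,
together with a separate "structured (trend)" variance component, is
produced naturally by the Bernardinelli-type linear interaction
`w_ij = delta_i * t_j` with an ICAR prior on the trend deviations
`delta_i`. That is the package's canonical interpretation, and the
posterior of `delta_i` is what the trend classification reads. The
trend covariate `t_j` is the month index centred at the series midpoint
and scaled by `1/T`: it spans roughly (-1/2, 1/2) for any study length,
keeping the linear predictor bounded and the trend coefficient
comparable across lengths; any rescaling of `t` is absorbed exactly by
a reparameterisation of `beta_trend` and `delta`.

Priors are: flat on the intercept, Normal(0, precision 1e-4) on
coefficients, Gamma(shape 0.001, rate 0.001) on the three random-effect
precisions, and Uniform(0, 1) on `omega` (no prior is dictated for the
inflation probability; the uniform makes its conjugate update a Beta).

## Sampler

The sampler is Metropolis-within-Gibbs, implemented in C++ with all
randomness drawn from R's RNG so a seed reproduces chains bitwise:

1. latent structural-zero indicators for observed zeros, by their exact
   Bernoulli conditional `omega / (omega + (1-omega) e^{-mu})`;
2. `omega` from its conjugate Beta posterior given the indicators;
3. each fixed effect by adaptive random-walk Metropolis (proposal
   scales tuned every 50 sweeps during burn-in toward an acceptance
   window of 0.20-0.45, frozen afterwards so the post-burn-in chain is
   a valid Markov chain);
4. each `u_i`, `v_i`, `delta_i` by single-site adaptive random-walk
   Metropolis against its full conditional — for ICAR effects the prior
   conditional mean is the neighbour average and the conditional
   precision is `tau` times the degree;
5. precisions by conjugate Gamma updates, with ICAR rank `n - c`
   (`c` = connected components) in the shape;
6. `v` and `delta` recentred to sum to zero each sweep, the shift
   absorbed exactly by the intercept and the trend coefficient
   respectively, leaving both likelihood and ICAR prior invariant.

Areas with no neighbours have their ICAR effects pinned at zero with a
warning; on such graphs the recentring shift cannot be absorbed by a
single coefficient, so the plain (approximate) recentring of the
non-island block is used instead. Any proposal that would push a linear
predictor above 50 is rejected outright, which bounds `exp(eta)` and
surfaces badly scaled inputs instead of overflowing. Convergence is
reported, not enforced: Geweke z-scores (first 10% versus last 50%,
batch-mean variances) and acceptance rates are returned with every fit,
replacing visual inspection of history plots.

Deviance is accumulated per retained draw on the marginal ZIP
likelihood (indicators integrated out), and
`DIC = Dbar + pD, pD = Dbar - D(posterior means of all parameters,
random effects included)`. A negative `pD` — possible in poorly
identified hierarchical fits — is flagged, not hidden. Relative risks
are posterior means and equal-tailed intervals of `exp(beta)` draws;
the intercept stays on the log scale as disease-mapping tables
conventionally report it.

## Defaults

Desk-scale chain defaults are burn-in 1,000, 11,000 total iterations,
thinning 5 (2,000 retained draws); full surveillance-scale settings
(burn-in 10,000, on the order of 100,000 iterations, convergence
re-checked in 20,000-iteration blocks) are selected through
`run_config(mcmc = ...)`. The credible level defaults to 95% and the
trend/exceedance probability threshold to 0.95.

# The synthetic-data generator

The generator exists so that every estimator can be exercised on data
whose answer is known; it *is* the model the sampler fits, plus a
climate process. A queen-contiguity lattice stands in for sub-district
polygons — contiguity, not geometry, is what every equation consumes.
Climate emulates a high-altitude monsoon regime: gamma-distributed
rainfall whose seasonal mean peaks mid-year (annual mean 5.2 mm at the
area-month scale, matching the magnitude of the real monthly means),
sinusoidal maximum temperature attenuated 3.5 degrees C per 1000 m of
altitude and clipped to 11-34, sinusoidal relative humidity clipped to
0-100, and altitude uniform on 300-4600 m. Climate is simulated with a
3-month warm-up so lagged covariates exist for every panel month; the
exposed panel starts at month 1, so fits drop the first three months
exactly as with real data.

Ground-truth defaults mirror the effect sizes typical of
respiratory-infection surveillance: children at 2.34-fold risk, males
at RR 0.876, trend RR 1.086 over the scaled trend, small positive
rainfall (1.051 per 10 mm) and temperature (1.026 per degree) effects,
weak negative altitude and humidity effects, `omega = 0.2` (about a
fifth of rows structurally zero), and precisions `tau_u = 10`,
`tau_v = 4`, `tau_delta = 1` giving moderate unstructured and spatial
heterogeneity and a pronounced area-specific trend. The baseline rate
(0.01 cases per person-month on stratum populations averaging 800)
puts typical expected counts near 8 per row — informative but firmly
in the small-count regime where zero inflation matters. ICAR effects
are drawn exactly on the sum-to-zero subspace by eigendecomposition of
the graph Laplacian, sampling only directions with positive eigenvalue.

What the generator does *not* emulate: reporting delays and
backfilling, population drift within the study period, facility-level
(as opposed to row-level) non-reporting, non-linear or interacting
climate effects, and real geography. Passing recovery tests therefore
demonstrates internal consistency of the estimators under the model's
own assumptions, not robustness to the ways real surveillance data
violate them.

# Verification strategy and problem sizes

Every closed-form quantity is tested against an independent oracle:
the Poisson GLM against direct BFGS maximisation of the likelihood,
VIF against `car::vif`, ICAR quadratic forms against hand enumeration
on 2-4 node graphs, the K2 ICAR draw against its closed form
(variance `1/(4 tau)` on the antisymmetric line), the ZIP pmf against
direct arithmetic, and the decomposition against `stats::stl`. The
sampler is validated by parameter recovery under the generator: 20
replicate worlds on a 6x6 lattice over 24 months (about 3,000 modelled
rows each) check that each generative coefficient falls in its 95%
credible interval at roughly the nominal rate, that the posterior mean
of `omega` lands within 0.03 of the truth, and that DIC ranks the
spatio-temporal model below the unstructured model when the data
contain genuine spatio-temporal structure. These sizes were chosen as
the smallest worlds in which all effects are identified and coverage
statements are meaningful at 20 replicates.

# Known limitations

* A single constant `omega`: no covariates in the zero component, and
  no spatially varying inflation.
* The ICAR prior is intrinsic; no proper-CAR spatial-dependence
  parameter is estimated.
* The trend interaction is linear in time; non-linear area-time
  surfaces are out of scope.
* Single-chain inference: diagnostics are within-chain (Geweke,
  acceptance rates); multi-chain R-hat would require running `mcmc_fit`
  at several seeds and comparing.
* The univariate lag screen is marginal and can be confounded by
  co-seasonal covariates; it reproduces a conventional screening
  pipeline rather than a joint distributed-lag model.
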