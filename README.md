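# spatzip

Bayesian spatio-temporal disease mapping for zero-inflated surveillance
counts.

`spatzip` is built for the common situation in infectious-disease
surveillance where monthly case counts are reported by small
administrative areas, stratified by age group and sex, and a substantial
share of the reports are zeros — some because nothing happened, some
because nothing was reported. It provides the full analysis chain for
such data: descriptive incidence and standardized morbidity ratios,
seasonal-trend decomposition, lagged climate covariate screening, and
four nested Bayesian zero-inflated Poisson (ZIP) spatial models fitted
by a purpose-built Metropolis-within-Gibbs sampler. A synthetic-data
generator with stored ground truth makes every estimator testable
against data whose answer is known.

## The model

Counts `Y_ij` in area `i` and month `j` (per age-sex stratum) follow a
zero-inflated Poisson mixture

    P(Y = 0) = omega + (1 - omega) exp(-mu)
    P(Y = y) = (1 - omega) exp(-mu) mu^y / y!,   y > 0

with log-linear mean anchored to the expected count `E` (population
times the overall rate, acting as an offset):

    log(mu_ij) = log(E_ij) + theta_ij
    theta_ij = alpha + beta' x_ij + u_i + v_i + delta_i t_j

where `x_ij` collects age, sex, a scaled month-index trend `t_j`,
altitude (per 100 m), maximum temperature (per degree C), rainfall
lagged one month (per 10 mm) and relative humidity lagged three months
(per percentage point). The four nested models are:

| Model | random effects |
|-------|----------------|
| I     | `u_i` unstructured (iid Normal) |
| II    | `v_i` spatially structured (intrinsic CAR over queen contiguity) |
| III   | `u_i + v_i` (BYM convolution) |
| IV    | convolution plus `delta_i t_j`, ICAR area-specific linear-trend deviations |

Priors: flat intercept, Normal(0, precision 1e-4) coefficients,
Gamma(0.001, 0.001) random-effect precisions, Uniform(0, 1) inflation
probability. Models are compared by DIC; posterior summaries include
relative risks with 95% credible intervals, per-area residual-risk
exceedance probabilities `P(u_i + v_i > 0 | data)`, and a trend
classification calling each area's trend above/below the overall
average when `P(delta_i <> 0)` exceeds a probability threshold.

## Worked example

Simulate a 6x6 queen-contiguity lattice (36 areas) for 24 months with
known truth, then fit the full spatio-temporal model:

```r
library(spatzip)

graph <- make_lattice_adjacency(6, 6)
truth <- ground_truth(graph, seed = 7, omega = 0.2)   # ~20% structural zeros
sim   <- simulate_dataset(graph, 24, truth, seed = 7)

zero_fraction(sim$panel)$percent
#> [1] 20.08102

fit <- mcmc_fit(model_spec("IV"), sim$panel, sim$climate, graph,
                run_config(mcmc = list(seed = 7)))
fit
#> <posterior_result> model IV, 2000 retained draws
#>        term estimate   lower  upper         scale pct_change
#> 1 intercept   0.1775 0.01547 0.3007   coefficient         NA
#> 2       age   2.3213 2.27661 2.3650 relative risk      132.1
#> 3       sex   0.8824 0.86722 0.8977 relative risk      -11.8
#> 4     trend   1.0756 1.03073 1.1228 relative risk        7.6
#> 5  altitude   0.9959 0.99118 1.0019 relative risk       -0.4
#> 6      tmax   1.0270 1.02347 1.0297 relative risk        2.7
#> 7  rainfall   1.0479 1.03885 1.0571 relative risk        4.8
#> 8        rh   0.9970 0.99633 0.9977 relative risk       -0.3
#> omega: 0.203 (0.188, 0.217)   DIC: 16809.9 (pD 74.5)
```

The generating values were age RR `exp(0.850) = 2.34`, sex RR
`exp(-0.132) = 0.876`, rainfall RR `exp(0.050) = 1.051` per 10 mm,
maximum temperature RR `exp(0.026) = 1.026` per degree, and
`omega = 0.2`: each is inside its credible interval. Children show a
132% higher risk than adults, males ~12% lower risk than females, and
each 10 mm of last month's rainfall raises risk by ~5%.

Per-area surprises and trends:

```r
cls <- exceedance_and_trend(fit, threshold = 0.95)
table(cls$trend_class)
#>     above     below uncertain
#>        14        12        10
```

`run_all()` chains every stage (describe, decompose, screen lags, fit,
summarize) over a data directory and writes the tables plus a
reproducibility manifest.

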