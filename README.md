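# ibdforecast

Projection of inflammatory bowel disease (IBD) prevalence for Asian regions
with a three-state illness-death model.

## The problem

IBD is a lifelong, largely nonfatal chronic disease whose incidence is rising
across Asia. Health systems planning diagnostic and treatment capacity need
forward projections of the number of prevalent cases, but most Asian regions
lack the multi-year registry series that time-series forecasting requires.
What *is* available is a single cross-section: an incidence rate, a
prevalence ratio and cause-specific death rates per region, plus the
prevalent-case count in a baseline year (2017).

`ibdforecast` turns that cross-section into a 2017–2035 projection with the
standard illness-death multistate model: three states (healthy → IBD → dead,
healthy → dead) with no recovery transition, constant rates, and a birth
inflow closing the demography. Two engines share the same parameters:

- **Deterministic:** the linear compartment ODE system

  $$\frac{dH}{dt} = -(d + \lambda)\,H + B, \qquad
    \frac{dI}{dt} = \lambda H - \mu I,$$

  with incidence hazard $\lambda$, background mortality $d$ (per healthy
  person-year), per-patient IBD mortality $\mu$ and birth inflow $B$.
  Under the default *stationary-healthy* closure ($B = (d+\lambda)H_0$) the
  model has the closed-form solution
  $I(t) = a/\mu + (I_0 - a/\mu)e^{-\mu t}$ with $a = \lambda H_0$, which the
  package uses as an independent oracle for the numerical integrator.

- **Stochastic:** a 3×3 one-step Markov transition matrix with absorbing
  death, built from the same hazards by competing-risks conversion
  ($p_{h\to ibd} = \tfrac{\lambda}{\lambda+d}(1-e^{-(\lambda+d)\Delta t})$,
  etc.), advanced by annual multinomial draws per compartment and solved by
  Monte-Carlo replication.

Published rates are per 100,000 per year; the per-patient IBD mortality
hazard is formed as `ibd_death / prevalence` (both share the per-100,000
denominator), and the baseline population is back-derived from the printed
prevalence ratio and case count. The six-region rate table driving the
published projections ships with the package
(`inst/extdata/asia_ibd_table1.csv`).

## Worked example

```r
library(ibdforecast)

iran <- asia_ibd_table()[["Iran"]]
m <- illness_death(iran)
m
#> Illness-death model: Iran (point rates, start 2017)
#>   population 88,192,593 | healthy 88,168,781 | prevalent IBD 23,812
#> Illness-death model hazards (per person-year):
#>   incidence (healthy -> IBD)     3.11e-05
#>   IBD mortality (per patient)    0.00592593
#>   background mortality (healthy) 0.0046397
#>   birth inflow: 411819 persons/year [stationary-healthy closure]

traj <- predict(m, horizon_years = 18)          # deterministic ODE
round(traj$ibd[traj$year %in% c(2020, 2025, 2030, 2035)] / 1e3, 3)
#> [1] 31.546 44.134 56.355 68.218   # thousand prevalent cases

doubling_time(traj, ref_year = 2020)
#> [1] 12.82157                      # years to double the 2020 count
fold_change(traj, 2020, 2035)
#> [1] 2.162517

ens <- simulate(m, nsim = 200, seed = 11)       # stochastic Markov ensemble
ens
#> Stochastic illness-death ensemble: 200 replicates, 2017-2035 (seed 11)
#>   mean prevalent IBD cases at 2035: 68,259
```

The deterministic 2035 figure (68.2 thousand) says Iran's prevalent IBD
caseload roughly triples from its 2017 baseline of 23.8 thousand; the
stochastic ensemble mean agrees to about a percent, and the 12.8-year
doubling time from 2020 quantifies the pace. `project_interval()` adds an
uncertainty envelope from the published 95% UI bounds, `rate_sensitivity()`
reports finite-difference elasticities of the projected count with respect
to each hazard, and `run_projection()` writes tidy CSV/JSON reports for all
regions at once. A thin command-line front end lives at
`inst/cli/ibdforecast.R` (subcommands `project`, `simulate`, `sensitivity`,
`synth`).

Synthetic-data tools (`generate_region_params()`,
`generate_observed_series()`, `fit_incidence()`) generate region tables and
noisy prevalence series with the model's own statistical structure, and
recover the incidence rate from an observed series by bounded least squares
— the package's parameter-recovery harness.

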