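# airadmit

Acute effects of ambient air pollution on daily elderly asthma hospital
admissions, estimated from a linked daily time series of admission counts,
pollutant concentrations (PM2.5, PM10, SO₂, NO₂; 24-h means, µg/m³) and
daily minimum temperature. The package is aimed at environmental
epidemiologists and healthcare-capacity analysts who need both the classical
short-term risk estimates and a day-to-day *dynamic* summary of admission
pressure usable for resource planning.

## What it computes

**1. Lagged relative risks.** For each pollutant and lag window
(lag0 = current day up to lag0–5 = six-day moving average), a
single-pollutant Poisson time-series GLM

```
Y_t ~ Poisson(μ_t),
log μ_t = α + β · x̄_t(w) + ns(tmin_t, df = 6) + DOW_t
```

where `x̄_t(w)` is the w-day trailing mean of the pollutant, `ns` a natural
cubic spline of minimum temperature and `DOW` day-of-week indicators.
Effects are reported as the percent increase in admissions per 10 µg/m³,
`(e^{10β} − 1)·100`, with Wald 95% CIs; the lag with the maximal point
estimate is flagged. Season (warm: Apr–Sep, cold: Oct–Mar) and sex subgroup
analyses reuse the same design.

**2. Admission states from the Lorenz curve.** Daily counts are sorted and
accumulated into a Lorenz curve; the smallest observed count `c` whose tail
share of days does not exceed a target (default top 30%) defines "high"
admission days (state 2, count ≥ c) versus "low" days (state 1).

**3. A binary pollution-severity index.** Every exceedance index — "the
pollutant exceeded a national concentration standard on ≥ k of the last w
days" — is scored by its 2×2 odds ratio against high-day status,
`OR = ad/bc`, and the candidate with the largest valid OR > 1 is selected
as the severity index.

**4. Severity-stratified Markov transitions.** With each day labelled
low/high and mild/severe, the one-day transition matrices
`P(i → j | severity)` are estimated by stratified maximum likelihood
(`n_ij / Σ_j n_ij`, time-homogeneous), with stationary block-bootstrap
percentile CIs and a severe-minus-mild contrast in percentage points.
Combined with a pollution forecast, the matrices give the next-day
admission-state distribution.

A synthetic-data module generates daily series (correlated lognormal
pollutants, sinusoidal temperature, Poisson admissions with known
coefficients) and severity-driven state chains with known transition
matrices, so every estimator is validated by parameter recovery.

## Worked example

```r
library(airadmit)

series <- simulate_daily_series(365, seed = 2014)  # one study-like year
lag_scan(series, "so2")
#>      lag percent_increase ci_low ci_high  p_value significant  best
#>   lag0               5.36  0.329    10.6 0.036460        TRUE FALSE
#>   lag0-1            12.72  5.312    20.6 0.000554        TRUE FALSE
#>   lag0-2            13.72  4.384    23.9 0.003263        TRUE  TRUE
#>   lag0-3             8.09 -2.561    19.9 0.141655       FALSE FALSE
#>   lag0-4             5.24 -6.761    18.8 0.408505       FALSE FALSE
#>   lag0-5             6.89 -6.640    22.4 0.334731       FALSE FALSE
```

SO₂ (the generator's true driver, acting through the two-day mean) shows
significant percent increases per 10 µg/m³ at the short lags; windows
longer than the true one dilute the association back toward noise.

```r
labelled <- add_states(series)              # Lorenz-curve high days
attr(labelled, "state_threshold")
#> [1] 6        # days with >= 6 admissions are "high" (86/365 days)

grid <- index_grid_search(series, labelled$state)
fit <- fit_markov(labelled$state,
                  severity_series(series, selected_index(grid)),
                  boot_B = 500, boot_seed = 1)
fit
#> Stratified two-state Markov transition estimate (360 day pairs, destination-day severity)
#>   stratum mild:          stratum severe:
#>        1      2               1      2
#>   1 0.7675 0.2325         1 0.6000 0.4000
#>   2 0.7901 0.2099         2 0.3333 0.6667
compare_conditions(fit)
#>   from to p_severe p_mild diff_pp
#>      1  2    0.400  0.232    16.8
#>      2  2    0.667  0.210    45.7   # (rows 1->1, 2->1 omitted)
```

On this one simulated year the low→high transition probability rises by
about 17 percentage points when pollution turns severe — at 365 days the
selected index and the stratified estimates are still noisy (note the wide
OR interval in the grid), which is exactly why the recovery tests run on
much longer chains.

`autoplot()` methods exist for `lag_scan`, `lorenz_curve` and `markov_fit`
objects; `run_pipeline(pipeline_config(...))` executes all stages and
writes CSV tables plus a JSON manifest, and `inst/cli/airadmit.R` exposes
the same stages as shell subcommands.

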