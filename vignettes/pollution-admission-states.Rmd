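---
title: "Methods: lagged Poisson risks and pollution-stratified admission-state dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lagged Poisson risks and pollution-stratified admission-state dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(airadmit)
```

This vignette is the package's own account of its statistical methods: the
models fitted, the conventions chosen where the methodology left choices
open, what the synthetic-data generator does and does not emulate, and the
known limitations.

## The setting

The data are one row per calendar day: elderly asthma admission counts
(optionally split by sex), four pollutant concentrations (PM2.5, PM10, SO₂,
NO₂; 24-hour means, µg/m³) and daily minimum temperature (°C). Analyses
treat the series as a time-series design: admissions and exposures are
linked by date, and short-term (days-scale) associations are the target.
Claim-level records are out of scope — the package consumes pre-aggregated
daily counts for the elderly subgroup.

## Stage 1: lagged Poisson regression

Daily admission counts are modelled as Poisson:

$$\log \mu_t = \alpha + \beta\,\bar{x}_t(w) + f(\mathrm{tmin}_t) + \mathrm{DOW}_t$$

* **Exposure** $\bar{x}_t(w)$ is the trailing $w$-day moving average of one
  pollutant, $w \in 1..6$ ("lag0" through "lag0–5"). Single-pollutant
  models are fitted one pollutant at a time; windows shorter than a day or
  longer than six are rejected because the scan is about *acute* effects.
* **Temperature** is adjusted by a natural cubic spline of daily minimum
  temperature, default 6 df, with interior knots at equally spaced
  quantiles of the observed values and natural boundary constraints
  (`splines::ns`). Six degrees of freedom over a year is the conventional
  smoothness for weather confounding in daily admission models: flexible
  enough for the seasonal U-shape, not so flexible that it absorbs
  short-term exposure variation.
* **Day-of-week** enters as six indicators with Monday as the reference;
  the choice of reference affects only the intercept.
* **Estimation** is maximum likelihood via IRLS (`stats::glm`, convergence
  tolerance $10^{-8}$). The default family is Poisson; a quasi-Poisson
  option rescales the covariance by the Pearson dispersion for series with
  extra-Poisson variation. Effects are reported as the percent increase per
  10 µg/m³, $(e^{10\beta}-1)\cdot 100$, with Wald 95% intervals
  ($\beta \pm 1.96\,\mathrm{SE}$); significance is the two-sided 5% Wald
  test, with no multiple-testing correction across the lag × pollutant ×
  subgroup grid (each cell is read as its own descriptive estimate).

**Missingness and subgroups.** Lag features are computed on the full series
*before* subgroup filtering, so a cold-season analysis keeps valid exposure
windows at the season boundaries; any row with a missing response, exposure
window or temperature is then dropped listwise. Calendar gaps are never
imputed — a gap poisons exactly the windows that touch it. Subgroups with
fewer than 30 usable days are refused. A constant temperature column makes
the spline basis rank-deficient; the design builder warns and omits it
rather than failing the fit.

**Best-lag identifiability.** The scan flags the window with the maximal
point estimate. This heuristic is weakly identified among nested windows:
if admissions truly respond to the $w$-day mean and exposure days are
serially independent, any window $W \ge w$ estimates the same coefficient
in expectation (the projection slope is exactly 1), while windows $W < w$
attenuate it by $W/w$. With positively autocorrelated exposure the maximum
even drifts slightly beyond the true window. The package therefore
documents the best-lag flag as "at or beyond the shortest fully-informative
window", and the recovery tests assert exactly that property rather than an
exact window match.

## Stage 2: admission states from the Lorenz curve

Days are sorted by admission count and the cumulative share of admissions
is accumulated against the cumulative share of days. The resulting Lorenz
curve starts at (0,0), ends at (1,1), and is nondecreasing, convex and
below the diagonal; the implied Gini coefficient (trapezoidal) equals the
classical mean-absolute-difference form exactly, which the tests exploit as
an independent oracle.

The "high day" threshold takes a target top share $q$ (default 0.30) and
returns the smallest *observed* count $c$ such that the fraction of days
with count $\ge c$ is at most $q$. Ties at $c$ are all high, so the
realised high-day share is the largest achievable share not exceeding $q$
at an observed count boundary. Restricting candidates to observed counts
(rather than all integers) makes the rule scale-free and reproduces the
intended behaviour on discrete count distributions: the next-lower count
class would always push the share above $q$. If no class satisfies the rule
(all counts equal), the maximum count is used with a warning. States are
then `2` (high) when the count is at least $c$, else `1`, and subgroup
analyses recompute the threshold from the subgroup's own Lorenz curve.

## Stage 3: severity-index selection by odds ratio

A candidate severity index is "pollutant $p$ exceeded standard $s$ on at
least $k$ of the last $w$ days". The registry of standards holds the
national daily-mean thresholds (primary/secondary: PM2.5 35/75, PM10
50/150, SO₂ 50/150, NO₂ 80/—; NO₂ has no secondary standard), and
"exceeded" means strictly greater by default (configurable to $\ge$).
The grid enumerates every $(p, s, w \in 1..6, k \le w)$ — 21 candidates per
pollutant-standard pair — cross-tabulates each against the high/low states
(undefined days dropped pairwise) and computes the cross-product odds ratio
with the Wald interval $\exp(\ln OR \pm 1.96\sqrt{1/a+1/b+1/c+1/d})$. A
zero cell makes a candidate incalculable (`NA`, no continuity correction).
The selected index maximises the valid OR; candidates with $OR \le 1$ are
protective or null and are never selected; ties break toward the smaller
window, then the smaller $k$ (the most parsimonious index). The tests
cross-check the OR against a saturated two-cell logistic regression.

## Stage 4: severity-stratified Markov transitions

Each consecutive-day pair $(t, t+1)$ contributes one transition,
attributed to the severity value of the **destination day** $t+1$: the
exceedance window ending on a day is what plausibly drives that day's
admissions. The origin-day convention is available as an option; on long
stationary chains the two differ negligibly, but the convention matters in
small samples and is therefore explicit. Within each stratum the
time-homogeneous MLE is the row-normalised count matrix. The off-diagonal
entry is computed as the count ratio and the diagonal as its exact
floating-point complement, so each row sums to 1 exactly and reported
complements are consistent to the last digit.

The model is discrete-time by design: observations are exactly daily, so
the one-day transition matrix is directly identified without passing
through a continuous-time intensity matrix. (The continuous-time
equivalent — the $2\times2$ intensity matrix whose one-day exponential
equals $\hat P$ — exists whenever $\hat P$ has positive eigenvalues and can
be used as a cross-check.) Rows with no outgoing pairs are `NA` and
flagged; a stratum with no pairs is omitted with a warning rather than
silently zero-filled.

**Uncertainty.** The bootstrap resamples *days* with the stationary block
bootstrap (geometric block lengths, mean $\lceil n^{1/3}\rceil$ by default,
circular wrap), then recounts transitions on the concatenated resample.
Block joins create a handful of artificial pairs, which is the standard
price of this scheme and is asymptotically negligible; replicates where a
stratum-row becomes empty are counted and reported as degenerate.
Percentile 2.5/97.5 intervals are returned per entry. The severe-minus-mild
contrast is reported in percentage points per transition entry.

## The synthetic-data generator

The generator exists so that every stage can be validated by parameter
recovery against known truth. Its defaults emulate the study setting: a
one-year series with mean 4.29 elderly admissions/day (female share 0.61),
pollutant means/SDs of 72/52 (PM2.5), 116/72 (PM10), 17/10 (SO₂), 52/16
(NO₂) µg/m³, inter-pollutant Pearson correlations of 0.86 (PM2.5–PM10)
down to 0.47 (SO₂–NO₂), and minimum temperature spanning roughly −2 to
24 °C over the year.

* **Pollutants** are lognormal, moment-matched to the target mean/SD —
  lognormality gives strict positivity and the right-skew typical of daily
  concentration data — and coupled by a Gaussian copula. The latent
  correlation is chosen by exact closed-form inversion so the *induced*
  data-scale Pearson correlation equals the target (plain latent-scale
  correlation would attenuate 0.86 to ≈0.84). Draws are iid across days.
* **Temperature** is a sinusoid (coldest mid-January, mean 13 °C, amplitude
  10 °C chosen so the annual SD is ≈7) plus Gaussian noise (SD 1.2 °C). A
  symmetric sinusoid cannot reproduce the asymmetric −2/24 range around a
  mean of 13 exactly; the defaults favour the winter tail and let the
  summer maximum run ≈1–3 °C warm.
* **Admissions** are Poisson with log-mean
  $\alpha + \beta \bar{x}_t(w) + f(\mathrm{tmin}) + \mathrm{DOW}$. The
  intercept is calibrated against the realised covariates so the marginal
  mean equals the target regardless of effect sizes. The default
  temperature effect is a mild convex function rising toward cold days and
  the day-of-week contrasts are small (|effect| ≤ 0.03 on the log scale) —
  enough to exercise the adjustment terms without dominating the exposure
  signal. The true coefficient, intercept and percent increase per
  10 µg/m³ travel with the output as a `truth` attribute.
* **State chains** draw day $t+1$'s state from the row of the severe or
  mild matrix selected by the severity of the governing day (destination
  convention, matching the estimator's default). Severity is iid
  Bernoulli(0.3) by default; real exceedance indices are autocorrelated,
  so explicit severity series can be supplied instead.

What the generator does **not** emulate: temporal autocorrelation of
pollutant and admission series, seasonality in pollution levels,
pollution–temperature dependence, overdispersion, and the feedback between
admissions and the states defined on them. Passing recovery tests
therefore demonstrate estimator correctness under the stated model, not
robustness to these real-data features.

## Problem sizes and tolerances in the tests

The recovery suite uses sizes at which Monte Carlo noise is comfortably
below the assertion tolerances: transition-matrix recovery on 200,000-day
chains (entries within ±0.5 pp; binomial SE ≈ 0.15 pp), the rare
low-to-high mild-regime rate (truth $10^{-4}$) on a 500,000-day chain
(within ±0.01 pp), odds-ratio recovery on 100,000 days (±0.15; SE ≈ 0.06),
and GLM interval coverage over 500 replicate 5,000-day series (accepted
band 92–98%). The percent-increase recovery check averages eight replicate
5,000-day series because a single series of that length carries ≈1 pp of
sampling noise at ~4.3 admissions/day — the average tests estimator bias at
the same ±1 pp tolerance instead of testing one draw's luck. Bootstrap
correctness is asserted on degenerate (zero-width) cases, seed
reproducibility and truth coverage rather than full coverage studies.

## Known limitations

* Ecological daily-counts design: the estimates are associations, not
  causal effects, and exposure is a regional average, not personal.
* The best-lag flag is a maximum over correlated estimates and inherits
  the weak identifiability discussed above.
* Wald intervals for the OR and transition entries are poor when cells are
  nearly empty; the package reports `NA` for zero cells rather than
  applying continuity corrections, so sparse grids contain many
  incalculable candidates.
* The two-state, two-stratum structure is fixed in the labelling and
  comparison stages; more states would require generalising the
  row-normalisation and comparison helpers (counting is already generic in
  the strata dimension).
* Transition estimates assume time-homogeneity within stratum; seasonal
  drift in the admission process shows up as severity-independent
  differences the model cannot express.
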