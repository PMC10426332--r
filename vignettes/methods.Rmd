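---
title: "Modelling temperature-attributable mortality with tempmort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling temperature-attributable mortality with tempmort}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tempmort)
```

## The model

`tempmort` estimates how daily mean temperature drives daily mortality in a
city, converts that association into annual heat- and cold-attributable excess
deaths, and projects those deaths under future climate, population and
adaptation assumptions.

The statistical core is a distributed-lag non-linear model (DLNM). Daily death
counts $Y_t$ for one city and age group (under 75 / 75 and over) follow a
quasi-Poisson model

$$\log E[Y_t] = \alpha + \sum_{l=0}^{21} f(T_{t-l}, l) + \text{DOW}_t +
\text{season}_t + \text{trend}_t,$$

where $f(\cdot,\cdot)$ is a bilinear tensor product of a natural cubic spline
in temperature and a natural cubic spline in lag. Temperature effects are
allowed to persist for up to 21 days because cold effects are known to act
over weeks while heat effects act over days. Confounders are six day-of-week
indicators (Sunday reference), two annual Fourier harmonic pairs with a
365.25-day period, and a linear long-term trend. Days without a full 21-day
exposure history (the first 21 days of the record) are excluded from the
likelihood rather than padded, which avoids biased early-lag exposure.

The fit is reduced to a *cumulative RR curve*: the lag-summed relative risk
at each temperature on a 0.1 °C grid spanning the observed range. The minimum
mortality temperature (MMT) is the argmin of the uncentered curve restricted
to the 1st–99th percentile of fitting-period temperatures (ties broken toward
the warmer temperature, flat curves flagged), and the curve is then centred
so RR(MMT) = 1 exactly. The search is done on the uncentered curve and the
centring applied afterwards; the two passes are mathematically redundant
(argmin is shift-invariant) but keep the procedure explicit.

Quasi-Poisson estimation is iteratively reweighted least squares
(`stats::glm.fit`) with the dispersion estimated as Pearson $\chi^2$ divided
by the residual degrees of freedom and the coefficient covariance
$\hat\phi\,(X^\top W X)^{-1}$. Rank-deficient designs are rejected with the
offending columns named rather than silently aliased.

## Attribution

Excess deaths convert risk to counts in two steps. The *baseline* is the mean
of observed daily deaths on days within ±0.5 °C of the MMT; if fewer than 30
days qualify, the window doubles (at most five times) before erroring. Daily
excess is then $B \cdot (\mathrm{RR}(T_t) - 1)$ with the curve interpolated
linearly between grid points; temperatures beyond the grid extrapolate the
log-RR linearly with a logged warning. Annual heat (cold) deaths sum the
excess over days warmer (colder) than the MMT; days exactly at the MMT
contribute zero to both, so heat + cold equals the total by construction.
Extreme heat/cold restrict the sums to days strictly beyond the 97.5th/2.5th
percentiles of the *historical reference* temperatures; the thresholds are
computed once from that reference and frozen, including for projections.
The forward form $B(\mathrm{RR}-1)$ is used rather than the
attributable-fraction form $N(1 - 1/\mathrm{RR})$, matching the two-step
baseline-then-curve procedure above. A fixed-population series
(excess / population × mean population) removes the population trend from
historical time series.

Throughout the package a single percentile convention is used (linear
interpolation between order statistics, the $(n-1)$-based rule, i.e.
`quantile(type = 7)`): spline knots, the MMT search window and the extreme
thresholds all share it.

## The analogue-city adaptation rule

Each curve is summarised by two scalars: the OLS slope of RR against
temperature over grid points above the MMT (hot slope) and below it (cold
slope, reported as a magnitude). Across cities these slopes correlate with
climate: cities with warmer summers have flatter hot sides, and cities with
colder winters have flatter cold sides — populations are adapted to their own
climate. `fit_slope_climate()` estimates these cross-city regressions of
slope on the 10-year JJA (June–August) or DJF (December–February) median
temperature, separately per age group. A DJF winter is labelled by its
January's year (December 2019 belongs to winter 2020); the first winter of a
record uses its available January/February days.

Under *strong adaptation* a city's hot slope evolves along the hot-side
regression line, evaluated at the city's trailing 10-year JJA median
(extrapolating beyond the fitted range as its climate leaves the observed
analogue pool) and clipped at zero. The curve's hot side is rescaled so the
excess risk $\mathrm{RR}-1$ is multiplied by
$r_\text{hot} = s_\text{new}/s_\text{base}$. Cold-side adaptation is coupled
to the hot side through $\rho$, the ratio of the magnitudes of the hot- and
cold-side fit slopes: the cold side's *fractional* risk change is $\rho$
times the hot side's, $r_\text{cold} = \max(0, 1 - \rho(1 - r_\text{hot}))$.
The alternative literal reading ($r_\text{cold} = \rho\, r_\text{hot}$) would
cut cold risk by $1-\rho$ even when the hot side is unchanged, violating the
no-adaptation fixed point, so the fractional form is the default and the
literal form is available via `cold_rule = "literal"`. Two further choices
the source framework leaves open: $r_\text{hot}$ is capped at 1 by default
(a cooling trailing window never *increases* vulnerability; configurable via
`cap_at_one`), and the MMT itself is never shifted. Slopes update annually
from year 11 of the record onward; before that the baseline curve is used,
so the baseline decade is identical across adaptation modes. A city whose
fitted hot side does not rise (base slope ≤ 0) is left unscaled.

## Projection and decomposition

`run_scenario()` applies one counterfactual fixing rule and re-runs the
attribution year by year with the projected baseline
$B(y) = \text{rate} \times \text{pop}(y)$, where the per-capita rate is the
historical baseline divided by the historical population of that age group:

* `all_factor` — nothing fixed;
* `fixed_climate` — the reference decade's (default 2011–2020) daily
  temperatures tiled over the whole horizon (a target 29 February without a
  source counterpart reuses 28 February);
* `fixed_demographics` — the over-75 population share frozen at its
  reference-decade mean (totals still evolve);
* `fixed_population` — the total population frozen at its reference-decade
  mean (the age ratio still evolves).

A factor's contribution is the all-factor result minus the fixed result, per
category and year. The contributions need not sum to the total change; the
interaction residual (total change minus the three contributions) is always
computed and reported, never dropped. Under strong adaptation the trailing
seasonal medians come from the scenario's own temperature stream, so a
fixed-climate world adapts to the fixed climate.

Global warming levels are two-stage ensemble means — members averaged within
each climate model, model means averaged across models, so heavily-ensembled
models do not dominate — expressed as anomalies against a preindustrial
(1850–1859) reference decade. Mortality at a warming level averages annual
deaths over years whose 10-year centred rolling-mean warming lies within
±0.05 °C of the level; the rolling mean suppresses interannual weather noise
in the association. Latitudinal aggregation uses half-open 5° bins
([30, 35), [35, 40), …) with per-capita rates as bin deaths over bin
population.

## The synthetic-data generator

Because the real inputs (city mortality registries, reanalysis temperatures,
climate-model ensembles) are restricted or bulky, every stage is exercised on
synthetic data with known ground truth.

* **Temperature** — an annual sinusoid (`mean + amplitude ·
  cos(2π(doy − peak)/365.25)`) on real Gregorian dates, a linear warming
  trend, and AR(1) residuals. Defaults for the reference city: mean 14 °C,
  amplitude 10 °C, AR(1) coefficient 0.7, innovation sd 3 °C — a
  mid-latitude, mid-continental profile.
* **Deaths** — the generator inverts the DLNM: the expected count is
  `baseline · dow · exp(Σ_l w_l log RR(T_{d−l}))` with RR a piecewise-linear
  V around the true MMT, and counts are negative binomial with variance
  `dispersion × mean` (dispersion 1.3 by default — the registry data's
  overdispersion is not published, so this is a free parameter — matching the
  quasi-Poisson variance assumption; dispersion 1 gives Poisson). The lag
  weights are one nonnegative vector summing to 1 (default a fast plus a slow
  exponential decay, `0.7·e^{−l/1.5} + 0.3·e^{−l/10}` normalised, mixing the
  short memory of heat with the long memory of cold). Lags reaching before
  the series start reuse the earliest observations; the fitter, not the
  generator, decides what to discard.
* **True MMT placement** — `mean + 0.9 × amplitude`, about the 85th
  percentile of the city's daily temperatures, where MMTs are empirically
  found in US cities. This placement matters: smoothing a kinked V with a
  natural cubic spline shifts the argmin toward the flatter (cold) side, and
  the shift grows as the kink moves into the sparse upper tail — a property
  of spline MMT estimation worth knowing when interpreting fitted MMTs, not
  an artefact of this package.
* **Multi-city ensembles** — city mean temperatures drawn uniformly over a
  climate range; true hot slopes follow `a_hot + b_hot · JJA median + noise`
  (clipped at 0) with `b_hot = −0.002` RR/°C per °C by default, and cold
  slopes follow `a_cold + b_cold · DJF median + noise` with `b_cold = +0.0015`
  — positive, because cities with colder winters are *less* vulnerable to
  cold. With these signs the projection stage reproduces, by construction,
  the poleward-shift pattern: warming removes deaths in hot-summer cities
  (flat hot side, steep cold side) and adds them in cool-summer cities.
* **Population** — totals compound at a growth rate while the over-75 share
  rises linearly.

What the generator does **not** emulate: independent seasonality of mortality
(influenza), demographic structure beyond two age groups, spatial correlation
between cities, humidity or pollution covariates, urban-heat-island
gradients, and any non-stationarity of vulnerability other than the
adaptation rule itself. Passing recovery tests therefore demonstrate that the
estimation machinery inverts the stated generative model — not that the model
captures everything in real registry data.

## Numerical choices

* Exposure spline: internal knots at the 10th/75th/90th percentiles of
  fitting temperatures, boundary knots at the observed min/max (standard
  DLNM practice for temperature); lag spline: intercept plus two internal
  knots equally spaced on the log(lag+1) scale over lags 0–21. Both
  configurable.
* Annual cycle: two Fourier pairs rather than a day-of-year spline; the
  trend is linear. Configurable via `n_harmonics`.
* RR grid step 0.1 °C, snapped outward so every observed temperature lies on
  the grid; all consumers interpolate linearly between grid points.
* IRLS convergence `epsilon = 1e-12`, at most 100 iterations;
  non-convergence and rank deficiency are hard errors.
* MMT window 1st–99th percentile, ties toward warmth, flat curves return the
  window midpoint with a warning.
* All randomness flows through one explicit integer seed per generator call;
  the previous RNG state is restored afterwards, so generators have no
  global side effects and identical calls are bit-identical.

## Problem sizes in the test-suite experiments

The packaged experiments are sized to be informative while remaining quick:
parameter recovery uses one city × 14 years × 10 replicate seeds (baseline 30
deaths/day, hot slope 0.03, cold slope 0.008 RR/°C, dispersion 1.3); the
null-effect flatness check uses a 200 deaths/day city over 10 years, judged
over the P1–P99 window on which the curve is used; the multi-city study uses
12 cities × 10 years × 2 age groups; the slope-law recovery uses 100-city
ensembles with CI coverage checked across 40 replicates; scenario and
decomposition checks use 2–3 cities over 20–40-year horizons.

## Limitations

* The MMT estimate inherits the spline argmin bias described above when the
  true risk minimum sits in a sparse tail of the exposure distribution.
* The adaptation engine extrapolates the cross-city regression beyond the
  observed analogue pool; the zero-clip is the only guardrail there.
* Fitted hot/cold RR slopes are grid-range dependent (they summarise the
  curve over the observed temperature span), so they are comparable across
  cities with similar records but not across very different ones.
* Scenario arithmetic treats cities independently; no shared weather or
  shared adaptation budget across cities.
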