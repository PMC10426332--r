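# tempmort

Temperature-attributable mortality modelling for city-level daily time
series: distributed-lag non-linear models (DLNM) of the temperature–mortality
association, attribution of heat-, cold- and extreme-temperature excess
deaths, an analogue-city adaptation engine, and projection of future
mortality decomposed into climate, demographic and population contributions.

The package is aimed at environmental epidemiologists and climate-impact
researchers who work with daily death counts, daily mean temperatures and
annual population by age group, and who want a tested, reproducible pipeline
from raw series to projected attributable deaths. Because the canonical data
sources for this kind of study (mortality registries, reanalysis
temperatures, regional climate ensembles) are restricted or bulky, the
package ships a first-class synthetic-data generator with known ground-truth
risk surfaces, so every stage can be validated by parameter recovery.

## The model

For one city and age group, daily deaths follow a quasi-Poisson regression

log E[Y_t] = α + Σ_{l=0..21} f(T_{t−l}, l) + DOW_t + season_t + trend_t

with f a tensor product of natural cubic splines in temperature and in lag
(heat acts over days, cold over weeks, hence lags to 21 days). The fit is
reduced to a cumulative relative-risk curve RR(T) on a 0.1 °C grid, centred
at the minimum mortality temperature (MMT) so RR(MMT) = 1. Annual excess
deaths are B·(RR(T_t) − 1) summed over days above (heat) or below (cold) the
MMT, with B the mean observed deaths within ±0.5 °C of the MMT; extreme
variants restrict to days beyond the frozen 97.5th/2.5th percentiles of the
historical reference temperatures.

Adaptation follows the analogue-city idea: across cities, the slope of RR
versus temperature above the MMT falls with the local summer (JJA) median
temperature — hot cities are already adapted. Under strong adaptation each
city's hot slope evolves along that cross-city regression as its own
trailing 10-year climate warms, the curve's hot side is rescaled by
r_hot = s_new/s_base, and the cold side's fractional risk change is coupled
to the hot side's through the ratio ρ of the two regression slopes:
r_cold = max(0, 1 − ρ(1 − r_hot)). Projections re-run the attribution with
future temperatures and populations; factor contributions are differences
against runs with climate, demographics or population frozen at a reference
decade, with the interaction residual reported explicitly.

See `vignettes/methods.Rmd` for the full account of the model, the
generator, and every numerical choice.

## Worked example

Simulate ten years of a mid-latitude city whose true risk surface is a V
with MMT 23 °C, hot slope 0.03 and cold slope 0.008 RR/°C and overdispersed
counts (dispersion 1.3), then fit and attribute:

```r
library(tempmort)
city <- city_climate_spec("springfield", latitude = 41, mean_temp = 14,
                          seasonal_amplitude = 10)
temps  <- sim_temperature(city, 1991, 2000, seed = 1)
truth  <- rr_surface(mmt = 23, hot_slope = 0.03, cold_slope = 0.008)
deaths <- sim_deaths(temps, truth, baseline_rate = 30, dispersion = 1.3, seed = 2)

fit <- tm_fit(deaths, temps, city_id = "springfield", age_group = "over75")
fit
#> Temperature-mortality DLNM (quasi-Poisson)
#>   city: springfield (over75)
#>   3632 days fitted (lags 0..21 excluded at start), 28 coefficients
#>   dispersion 1.298, residual deviance 4708.7 on 3604 df

curve <- cumulative_rr(fit)
curve
#> Cumulative RR curve [springfield/over75]: 477 grid points over [-7.4, 40.2] C, MMT 22.7 C
#>   RR range 1.000 .. 2.407

b   <- baseline_deaths(deaths, temps, curve$mmt)
thr <- extreme_thresholds(temps)
att <- attribute_years(temps, curve, b, thr)
round(colMeans(att[c("heat", "cold", "extreme_heat", "extreme_cold")]), 1)
#>         heat         cold extreme_heat extreme_cold
#>        143.6        851.2         84.1         58.7
```

The fitted dispersion (1.298) recovers the generating 1.3; the MMT estimate
(22.7 °C) sits 0.3 °C from the true 23 °C; and the attribution shows the
field's characteristic pattern — most attributable deaths are cold-side,
because the MMT sits high in the temperature distribution, while heat deaths
concentrate in the extreme tail (84 of 144 heat deaths/yr beyond the 97.5th
percentile versus 59 of 851 cold deaths/yr beyond the 2.5th).

Multi-city studies run through the CSV pipeline: `sim_city_ensemble()` +
`write_synthetic_inputs()` create the four canonical inputs
(`temperatures.csv`, `deaths.csv`, `population.csv`, `cities.csv`),
`run_pipeline(run_config(...))` fits every city × age group and writes
`rr_curves.csv`, `slopes.csv`, `slope_fits.csv`, `attribution.csv` and a
manifest; `run_scenario()`, `decomposition_table()`, `mortality_at_warming()`
and `latitude_profile()` handle projection and reporting.

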