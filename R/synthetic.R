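#' City climate specification for the synthetic generator
#'
#' Describes the deterministic and stochastic parts of a city's daily mean
#' temperature process: an annual sinusoid around a long-term mean, a linear
#' warming trend, and AR(1) day-to-day weather noise.
#'
#' @param city_id character identifier.
#' @param latitude degrees north (used only for spatial aggregation).
#' @param mean_temp long-term mean temperature, degrees C.
#' @param seasonal_amplitude half the peak-to-trough seasonal swing, degrees C
#'   (must be >= 0).
#' @param peak_doy day-of-year of the warmest day (1-366).
#' @param ar1_coef AR(1) coefficient of the daily weather residual, |ar1| < 1.
#' @param noise_sd innovation standard deviation of the AR(1) residual,
#'   degrees C (>= 0; 0 gives the exact deterministic sinusoid).
#' @param warming_per_year linear warming trend, degrees C per year, applied
#'   from the start of the generated series.
#' @return An object of class `city_climate_spec`.
#' @examples
#' spec <- city_climate_spec("c01", 41, mean_temp = 12, seasonal_amplitude = 11)
#' temps <- sim_temperature(spec, 1990, 1992, seed = 1)
#' head(temps)
#' @export
city_climate_spec <- function(city_id, latitude, mean_temp, seasonal_amplitude,
                              peak_doy = 200, ar1_coef = 0.7, noise_sd = 3,
                              warming_per_year = 0) {
  for (nm in c("latitude", "mean_temp", "seasonal_amplitude", "peak_doy",
               "ar1_coef", "noise_sd", "warming_per_year")) {
    stop_if_not_finite(get(nm), nm)
  }
  if (seasonal_amplitude < 0) stop("'seasonal_amplitude' must be >= 0", call. = FALSE)
  if (abs(ar1_coef) >= 1) stop("'ar1_coef' must satisfy |ar1_coef| < 1", call. = FALSE)
  if (noise_sd < 0) stop("'noise_sd' must be >= 0", call. = FALSE)
  structure(list(city_id = as.character(city_id), latitude = latitude,
                 mean_temp = mean_temp, seasonal_amplitude = seasonal_amplitude,
                 peak_doy = peak_doy, ar1_coef = ar1_coef, noise_sd = noise_sd,
                 warming_per_year = warming_per_year),
            class = "city_climate_spec")
}

#' Ground-truth piecewise-linear risk surface
#'
#' The generating exposure-response is a V in relative risk: RR(T) = 1 +
#' hot_slope * (T - mmt) above the minimum mortality temperature (MMT) and
#' 1 + cold_slope * (mmt - T) below it. The lagged effect distributes
#' log RR(T) over lags 0..21 with nonnegative weights summing to one, so the
#' cumulative (lag-summed) RR at a sustained temperature T equals RR(T).
#'
#' @param mmt minimum mortality temperature, degrees C.
#' @param hot_slope RR increase per degree C above the MMT (>= 0).
#' @param cold_slope RR increase per degree C below the MMT (>= 0, magnitude).
#' @param lag_weights nonnegative vector over lags 0..21 summing to 1; the
#'   default mixes a fast and a slow exponential decay so that part of the
#'   effect is immediate and part persists for weeks.
#' @return An object of class `rr_surface`.
#' @export
rr_surface <- function(mmt, hot_slope, cold_slope, lag_weights = NULL) {
  stop_if_not_finite(mmt, "mmt")
  stop_if_not_finite(hot_slope, "hot_slope")
  stop_if_not_finite(cold_slope, "cold_slope")
  if (hot_slope < 0 || cold_slope < 0) stop("slopes must be >= 0", call. = FALSE)
  if (is.null(lag_weights)) {
    l <- 0:21
    lag_weights <- 0.7 * exp(-l / 1.5) + 0.3 * exp(-l / 10)
    lag_weights <- lag_weights / sum(lag_weights)
  }
  stop_if_not_finite(lag_weights, "lag_weights")
  if (length(lag_weights) != 22L || any(lag_weights < 0)) {
    stop("'lag_weights' must be a nonnegative vector over lags 0..21", call. = FALSE)
  }
  if (abs(sum(lag_weights) - 1) > 1e-12) {
    stop("'lag_weights' must sum to 1", call. = FALSE)
  }
  structure(list(mmt = mmt, hot_slope = hot_slope, cold_slope = cold_slope,
                 lag_weights = lag_weights),
            class = "rr_surface")
}

#' Point relative risk of a ground-truth surface
#' @param surface an [rr_surface()].
#' @param temp temperatures, degrees C.
#' @return RR values (>= 1).
#' @export
surface_rr <- function(surface, temp) {
  d <- temp - surface$mmt
  ifelse(d > 0, 1 + surface$hot_slope * d, 1 + surface$cold_slope * (-d))
}

#' Population growth/aging specification
#'
#' @param base_pop named vector `c(under75 = , over75 = )` of persons in the
#'   first year.
#' @param growth_per_year total population growth rate, fraction per year.
#' @param aging_shift_per_year absolute increase of the over-75 population
#'   share per year.
#' @return An object of class `population_spec`.
#' @export
population_spec <- function(base_pop, growth_per_year = 0, aging_shift_per_year = 0) {
  if (!all(c("under75", "over75") %in% names(base_pop))) {
    stop("'base_pop' must be named with 'under75' and 'over75'", call. = FALSE)
  }
  stop_if_not_finite(unname(base_pop), "base_pop")
  if (any(base_pop <= 0)) stop("populations must be > 0", call. = FALSE)
  stop_if_not_finite(growth_per_year, "growth_per_year")
  stop_if_not_finite(aging_shift_per_year, "aging_shift_per_year")
  structure(list(base_pop = base_pop[c("under75", "over75")],
                 growth_per_year = growth_per_year,
                 aging_shift_per_year = aging_shift_per_year),
            class = "population_spec")
}

#' Simulate a daily mean temperature series
#'
#' Expected value at day d is `mean_temp + seasonal_amplitude *
#' cos(2*pi*(doy - peak_doy)/365.25) + warming_per_year * years_elapsed`;
#' residuals follow an AR(1) process with innovation sd `noise_sd`. Real
#' Gregorian dates (with leap days) are used; the sinusoid runs on a 365.25-day
#' cycle so it has no leap discontinuity.
#'
#' @param spec a [city_climate_spec()].
#' @param start_year,end_year first and last calendar years (inclusive).
#' @param seed integer seed; the same spec and seed give an identical series.
#' @return `data.frame(date, temp)`, one row per calendar day.
#' @export
sim_temperature <- function(spec, start_year, end_year, seed) {
  stopifnot(inherits(spec, "city_climate_spec"))
  if (start_year > end_year) stop("'start_year' must be <= 'end_year'", call. = FALSE)
  dates <- seq(as.Date(sprintf("%d-01-01", start_year)),
               as.Date(sprintf("%d-12-31", end_year)), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  elapsed <- as.numeric(dates - dates[1L]) / 365.25
  mu <- spec$mean_temp +
    spec$seasonal_amplitude * cos(2 * pi * (doy - spec$peak_doy) / 365.25) +
    spec$warming_per_year * elapsed
  n <- length(dates)
  eps <- if (spec$noise_sd > 0) {
    with_seed(seed, {
      innov <- stats::rnorm(n, 0, spec$noise_sd)
      as.numeric(stats::filter(innov, spec$ar1_coef, method = "recursive"))
    })
  } else rep(0, n)
  data.frame(date = dates, temp = mu + eps)
}

#' Simulate daily death counts from a ground-truth risk surface
#'
#' The expected count on day d is `baseline_rate * dow_effect[d] *
#' exp(sum_l lag_weights[l] * log RR(T[d-l]))` with RR the piecewise-linear V
#' of the surface. Lags reaching before the series start reuse the series'
#' earliest observations (no burn-in is discarded; the fitter decides what to
#' exclude). Counts are negative binomial with variance `dispersion * mean`
#' (`dispersion = 1` gives Poisson), matching the quasi-Poisson variance
#' assumption of the fitting stage.
#'
#' @param temps `data.frame(date, temp)` from [sim_temperature()].
#' @param surface an [rr_surface()].
#' @param baseline_rate expected deaths/day at the MMT (> 0).
#' @param dispersion variance-to-mean ratio, >= 1.
#' @param dow_effects 7 multiplicative day-of-week effects (Sunday first).
#' @param seed integer seed.
#' @return `data.frame(date, deaths)`.
#' @export
sim_deaths <- function(temps, surface, baseline_rate, dispersion = 1.3,
                       dow_effects = rep(1, 7), seed = 1) {
  stopifnot(inherits(surface, "rr_surface"))
  if (!is.numeric(baseline_rate) || baseline_rate <= 0) {
    stop("'baseline_rate' must be > 0", call. = FALSE)
  }
  if (dispersion < 1) stop("'dispersion' must be >= 1", call. = FALSE)
  if (length(dow_effects) != 7L || any(dow_effects <= 0)) {
    stop("'dow_effects' must be 7 positive multipliers", call. = FALSE)
  }
  n <- nrow(temps)
  log_rr <- log(surface_rr(surface, temps$temp))
  w <- surface$lag_weights
  lag_sum <- numeric(n)
  for (l in 0:21) {                      # lagged index clamped at series start
    idx <- pmax(seq_len(n) - l, 1L)
    lag_sum <- lag_sum + w[l + 1L] * log_rr[idx]
  }
  dow <- as.POSIXlt(temps$date)$wday + 1 # 1 = Sunday
  mu <- baseline_rate * dow_effects[dow] * exp(lag_sum)
  counts <- with_seed(seed, {
    if (dispersion == 1) {
      stats::rpois(n, mu)
    } else {
      # NB2 with size = mu/(phi-1) has variance mu + mu^2/size = phi * mu
      stats::rnbinom(n, size = mu / (dispersion - 1), mu = mu)
    }
  })
  data.frame(date = temps$date, deaths = counts)
}

#' Simulate annual population by age group
#'
#' Total population compounds at `growth_per_year`; the over-75 share rises
#' linearly by `aging_shift_per_year` per year from its base value.
#'
#' @param spec a [population_spec()].
#' @param years integer vector of calendar years (first year = base year).
#' @param city_id optional identifier column value.
#' @return `data.frame(city_id, year, age_group, population)` in long form.
#' @export
sim_population <- function(spec, years, city_id = "city") {
  stopifnot(inherits(spec, "population_spec"))
  base_total <- sum(spec$base_pop)
  share0 <- spec$base_pop[["over75"]] / base_total
  k <- years - years[1L]
  total <- base_total * (1 + spec$growth_per_year)^k
  share <- share0 + spec$aging_shift_per_year * k
  if (any(share <= 0 | share >= 1)) {
    stop("over-75 share leaves (0, 1) within the requested years", call. = FALSE)
  }
  data.frame(city_id = city_id,
             year = rep(years, 2L),
             age_group = rep(c("under75", "over75"), each = length(years)),
             population = c(total * (1 - share), total * share),
             row.names = NULL)
}

#' Deterministic seasonal medians implied by a climate spec
#'
#' Median of the noise-free sinusoid over the days of June-August (JJA) or
#' December-February (DJF) of one non-leap year; used as the generating
#' climate covariate in [sim_city_ensemble()].
#' @param spec a [city_climate_spec()].
#' @param season "JJA" or "DJF".
#' @return degrees C.
#' @export
spec_seasonal_median <- function(spec, season = c("JJA", "DJF")) {
  season <- match.arg(season)
  dates <- seq(as.Date("2001-01-01"), as.Date("2001-12-31"), by = "day")
  doy <- as.POSIXlt(dates)$yday + 1
  months <- month_of(dates)
  sel <- if (season == "JJA") months %in% 6:8 else months %in% c(12, 1, 2)
  mu <- spec$mean_temp +
    spec$seasonal_amplitude * cos(2 * pi * (doy[sel] - spec$peak_doy) / 365.25)
  stats::median(mu)
}

#' Simulate an ensemble of cities obeying a slope-vs-climate law
#'
#' Generates `n_cities` climate specs spanning `climate_range` and ground-truth
#' risk surfaces whose hot slope follows `a_hot + b_hot * JJA_median +
#' N(0, scatter_sd)` (clipped at 0) and analogously cold slope vs the DJF
#' median, emulating the cross-city anti-correlation between vulnerability and
#' seasonal climate that the adaptation stage estimates.
#'
#' @param n_cities number of cities (>= 3).
#' @param a_hot,b_hot intercept and slope of the hot-side generating law
#'   (RR per degree C, per degree C of JJA median); warmer summers give
#'   flatter hot sides, so `b_hot < 0`.
#' @param a_cold,b_cold the cold-side law vs DJF median; cities with colder
#'   winters are better adapted to cold (flatter cold sides), so the cold
#'   slope rises with the DJF median and `b_cold > 0`.
#' @param scatter_sd residual sd of city slopes about the law.
#' @param climate_range range of city mean temperatures, degrees C.
#' @param seed integer seed.
#' @param mmt_offset degrees C the true MMT sits above the city mean
#'   temperature; the default `0.9 * seasonal_amplitude` places it near the
#'   85th percentile of the city's daily temperatures, where MMTs are
#'   empirically found.
#' @return list with `specs` (list of [city_climate_spec()]), `surfaces`
#'   (list of [rr_surface()]), and `truth` — a data.frame of city ids,
#'   latitudes, generating seasonal medians and true slopes/MMTs.
#' @export
sim_city_ensemble <- function(n_cities, a_hot = 0.08, b_hot = -0.002,
                              a_cold = 0.02, b_cold = 0.0015,
                              scatter_sd = 0.002, climate_range = c(5, 25),
                              seed = 1, mmt_offset = NULL) {
  if (n_cities < 3) stop("'n_cities' must be >= 3", call. = FALSE)
  with_seed(seed, {
    mean_temp <- stats::runif(n_cities, climate_range[1L], climate_range[2L])
    amp <- stats::runif(n_cities, 8, 14)
    lat <- pmin(50, pmax(25, 48 - 1.1 * (mean_temp - climate_range[1L]) +
                           stats::rnorm(n_cities, 0, 1.5)))
    specs <- surfaces <- vector("list", n_cities)
    jja <- djf <- hot <- cold <- mmt <- numeric(n_cities)
    for (i in seq_len(n_cities)) {
      sp <- city_climate_spec(sprintf("c%03d", i), latitude = lat[i],
                              mean_temp = mean_temp[i], seasonal_amplitude = amp[i])
      jja[i] <- spec_seasonal_median(sp, "JJA")
      djf[i] <- spec_seasonal_median(sp, "DJF")
      hot[i] <- max(0, a_hot + b_hot * jja[i] + stats::rnorm(1, 0, scatter_sd))
      cold[i] <- max(0, a_cold + b_cold * djf[i] + stats::rnorm(1, 0, scatter_sd))
      mmt[i] <- mean_temp[i] + (mmt_offset %||% (0.9 * amp[i]))
      specs[[i]] <- sp
      surfaces[[i]] <- rr_surface(mmt[i], hot[i], cold[i])
    }
    truth <- data.frame(city_id = vapply(specs, `[[`, "", "city_id"),
                        latitude = lat, jja_median = jja, djf_median = djf,
                        hot_slope = hot, cold_slope = cold, mmt = mmt)
    list(specs = specs, surfaces = surfaces, truth = truth,
         law = list(a_hot = a_hot, b_hot = b_hot, a_cold = a_cold,
                    b_cold = b_cold, scatter_sd = scatter_sd))
  })
}
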