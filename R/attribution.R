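#' Baseline deaths at the minimum mortality temperature
#'
#' Mean daily deaths over days whose temperature lies within `half_width`
#' degrees C of the MMT. If fewer than `min_days` days qualify the window is
#' doubled (once per retry, at most 5 times) before erroring.
#'
#' @param deaths `data.frame(date, deaths)`.
#' @param temps `data.frame(date, temp)` on the same dates.
#' @param mmt minimum mortality temperature, degrees C.
#' @param half_width half window width, degrees C.
#' @param min_days minimum qualifying days before the window widens.
#' @return baseline deaths/day (scalar).
#' @export
baseline_deaths <- function(deaths, temps, mmt, half_width = 0.5, min_days = 30) {
  if (!identical(as.Date(deaths$date), as.Date(temps$date))) {
    stop("'deaths' and 'temps' must cover identical dates", call. = FALSE)
  }
  h <- half_width
  for (i in 0:5) {
    sel <- abs(temps$temp - mmt) <= h
    if (sum(sel) >= min(min_days, nrow(temps))) {
      return(mean(deaths$deaths[sel]))
    }
    h <- 2 * h
  }
  stop(sprintf("no window around MMT %.1f C with >= %d days after 5 doublings",
               mmt, min_days), call. = FALSE)
}

#' Daily temperature-attributable excess deaths
#'
#' Excess on day d is `baseline * (rr(T_d) - 1)` with the curve interpolated
#' linearly between grid points. Days warmer than the MMT contribute to heat,
#' days colder to cold; days exactly at the MMT contribute zero to both.
#'
#' @param temps `data.frame(date, temp)`.
#' @param curve an `rr_curve` (see [cumulative_rr()]).
#' @param baseline baseline deaths/day (> 0).
#' @return `data.frame(date, temp, excess, side)` with side in
#'   {"heat", "cold", "none"}.
#' @export
daily_excess <- function(temps, curve, baseline) {
  if (baseline <= 0) stop("'baseline' must be > 0", call. = FALSE)
  rr <- rr_at(curve, temps$temp)
  side <- ifelse(temps$temp > curve$mmt, "heat",
                 ifelse(temps$temp < curve$mmt, "cold", "none"))
  data.frame(date = temps$date, temp = temps$temp,
             excess = baseline * (rr - 1), side = side)
}

#' Extreme-temperature thresholds from a reference period
#'
#' The 2.5th and 97.5th percentiles of the daily temperatures of a historical
#' reference period; once computed they are frozen and reused unchanged for
#' any later (e.g. projected) series.
#'
#' @param ref_temps `data.frame(date, temp)` of at least one year.
#' @param probs lower/upper percentile positions.
#' @return object of class `extreme_thresholds`: list(p_low, p_high, probs,
#'   reference = range of reference dates).
#' @export
extreme_thresholds <- function(ref_temps, probs = c(0.025, 0.975)) {
  if (nrow(ref_temps) < 365) stop("reference series must cover >= 1 year", call. = FALSE)
  q <- pctl(ref_temps$temp, probs)
  structure(list(p_low = q[1L], p_high = q[2L], probs = probs,
                 reference = range(as.Date(ref_temps$date))),
            class = "extreme_thresholds")
}

#' Annual attribution of heat, cold and extreme excess deaths
#'
#' Sums [daily_excess()] by calendar year: heat over days with T > MMT, cold
#' over days with T < MMT, and extreme variants restricted to days strictly
#' beyond the frozen reference thresholds.
#'
#' @param temps `data.frame(date, temp)`.
#' @param curve an `rr_curve`.
#' @param baseline baseline deaths/day.
#' @param thresholds an [extreme_thresholds()] object.
#' @param city_id,age_group optional label columns.
#' @return `data.frame(city_id, age_group, year, heat, cold, extreme_heat,
#'   extreme_cold, baseline)`.
#' @export
attribute_years <- function(temps, curve, baseline, thresholds,
                            city_id = curve$city_id %||% NA_character_,
                            age_group = curve$age_group %||% NA_character_) {
  ex <- daily_excess(temps, curve, baseline)
  yr <- year_of(as.Date(ex$date))
  hot <- ex$side == "heat"; cold <- ex$side == "cold"
  xhot <- hot & ex$temp > thresholds$p_high
  xcold <- cold & ex$temp < thresholds$p_low
  sum_by <- function(sel) {
    s <- tapply(ex$excess[sel], factor(yr[sel], levels = sort(unique(yr))), sum)
    ifelse(is.na(s), 0, s)
  }
  years <- sort(unique(yr))
  data.frame(city_id = city_id, age_group = age_group, year = years,
             heat = as.numeric(sum_by(hot)), cold = as.numeric(sum_by(cold)),
             extreme_heat = as.numeric(sum_by(xhot)),
             extreme_cold = as.numeric(sum_by(xcold)),
             baseline = baseline, row.names = NULL)
}

#' Fixed-population rescaling of an annual series
#'
#' Removes the effect of population change: divides each year's excess deaths
#' by that year's population and multiplies by the average population over
#' the period.
#'
#' @param excess numeric annual excess deaths.
#' @param population numeric annual population, same length.
#' @return rescaled annual series.
#' @export
fixed_population_series <- function(excess, population) {
  if (length(excess) != length(population)) {
    stop("'excess' and 'population' must have matching years", call. = FALSE)
  }
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  excess / population * mean(population)
}
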