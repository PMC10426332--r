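#' Per-capita baseline death rate and its projection
#'
#' Converts a historical baseline (deaths/day at the MMT) into a per-person
#' rate using the historical population, so future baselines scale with the
#' projected population of each age group.
#'
#' @param baseline historical baseline deaths/day.
#' @param population historical population (persons).
#' @return deaths/day/person.
#' @export
death_rate <- function(baseline, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  baseline / population
}

#' @rdname death_rate
#' @param rate deaths/day/person from [death_rate()].
#' @export
project_baseline <- function(rate, population) {
  if (any(population <= 0)) stop("population must be > 0", call. = FALSE)
  rate * population
}

#' Tile a reference decade of daily temperatures over a target horizon
#'
#' Builds the fixed-climate counterfactual: each target date takes the
#' temperature of the same month/day in the reference block, with reference
#' years cycled in order; a February 29 without a counterpart in its source
#' year reuses February 28. The block is tiled forward and backward.
#'
#' @param temps `data.frame(date, temp)` covering the reference decade.
#' @param ref_years length-2 first/last year of the reference block.
#' @param target_dates `Date` vector to fill.
#' @return `data.frame(date, temp)` over `target_dates`.
#' @export
tile_reference_climate <- function(temps, ref_years = c(2011, 2020), target_dates) {
  dates <- as.Date(temps$date)
  span <- ref_years[2L] - ref_years[1L] + 1L
  ty <- year_of(target_dates)
  src_year <- ref_years[1L] + ((ty - ref_years[1L]) %% span + span) %% span
  md <- format(target_dates, "%m-%d")
  md[md == "02-29"] <- "02-29"           # tried first, then falls back to 02-28
  key <- paste0(src_year, "-", md)
  lookup <- stats::setNames(temps$temp, format(dates))
  temp <- unname(lookup[key])
  feb29 <- is.na(temp) & md == "02-29"
  if (any(feb29)) {
    temp[feb29] <- unname(lookup[paste0(src_year[feb29], "-02-28")])
  }
  if (anyNA(temp)) {
    stop("reference block does not cover: ",
         paste(utils::head(key[is.na(temp)], 5L), collapse = ", "), call. = FALSE)
  }
  data.frame(date = target_dates, temp = temp)
}

# population in wide per-year form for one city, with scenario fixing applied
fix_population <- function(pop_city, scenario, ref_years) {
  wide <- stats::reshape(pop_city[, c("year", "age_group", "population")],
                         idvar = "year", timevar = "age_group", direction = "wide")
  names(wide) <- sub("^population\\.", "", names(wide))
  wide <- wide[order(wide$year), ]
  total <- wide$under75 + wide$over75
  share <- wide$over75 / total
  ref <- wide$year >= ref_years[1L] & wide$year <= ref_years[2L]
  if (!any(ref)) stop("population does not cover the reference decade", call. = FALSE)
  if (scenario == "fixed_demographics") {
    share <- rep(mean(share[ref]), length(share))
  } else if (scenario == "fixed_population") {
    total <- rep(mean(total[ref]), length(total))
  }
  data.frame(year = wide$year, under75 = total * (1 - share), over75 = total * share)
}

#' Run a mortality projection scenario
#'
#' Applies a counterfactual fixing rule, then computes annual attributable
#' deaths city by city, age group by age group, optionally evolving each
#' city's RR curve under the strong-adaptation analogue-city rule. Scenarios:
#' `all_factor` (nothing fixed), `fixed_climate` (daily temperatures of the
#' reference decade tiled over the whole horizon), `fixed_demographics`
#' (over-75 share frozen at its reference-decade mean), `fixed_population`
#' (total population frozen at its reference-decade mean).
#'
#' Under strong adaptation each city's hot-side slope is re-estimated every
#' year from year 11 of the record onward, by evaluating the cross-city
#' slope-vs-climate regression at the city's trailing 10-year seasonal median
#' (computed from the scenario's own temperature stream); the cold side is
#' coupled through `rho`. Before year 11 the baseline curve is used.
#'
#' @param scenario one of "all_factor", "fixed_climate", "fixed_demographics",
#'   "fixed_population".
#' @param temps `data.frame(city_id, date, temp)` over the full horizon.
#' @param population `data.frame(city_id, year, age_group, population)`.
#' @param curves list of baseline `rr_curve` objects (city_id and age_group
#'   set) — the fitted historical exposure-response.
#' @param rates `data.frame(city_id, age_group, rate)` of per-capita baseline
#'   rates (see [death_rate()]).
#' @param thresholds named list of [extreme_thresholds()] keyed by city_id
#'   (frozen historical reference).
#' @param adaptation "none" or "strong".
#' @param slope_fits for strong adaptation, a list with elements `hot` and
#'   `cold`, each a named list of [fit_slope_climate()] objects keyed by age
#'   group.
#' @param rho cold-coupling ratio; default [slope_ratio()] of the supplied
#'   fits, per age group.
#' @param ref_years reference decade, first/last year.
#' @param cap_at_one,cold_rule passed to [scale_rr_curve()].
#' @return `data.frame` of class `scenario_result`: scenario, adaptation,
#'   city_id, age_group, year, heat, cold, extreme_heat, extreme_cold,
#'   baseline.
#' @export
run_scenario <- function(scenario = c("all_factor", "fixed_climate",
                                      "fixed_demographics", "fixed_population"),
                         temps, population, curves, rates, thresholds,
                         adaptation = c("none", "strong"), slope_fits = NULL,
                         rho = NULL, ref_years = c(2011, 2020),
                         cap_at_one = TRUE, cold_rule = "fractional") {
  scenario <- match.arg(scenario)
  adaptation <- match.arg(adaptation)
  if (adaptation == "strong" && is.null(slope_fits)) {
    stop("strong adaptation requires 'slope_fits'", call. = FALSE)
  }
  temps$date <- as.Date(temps$date)
  out <- list()
  for (cid in unique(vapply(curves, `[[`, "", "city_id"))) {
    ct <- temps[temps$city_id == cid, c("date", "temp")]
    ct <- ct[order(ct$date), ]
    if (!nrow(ct)) stop("no temperatures for city ", cid, call. = FALSE)
    if (scenario == "fixed_climate") {
      ref <- ct[year_of(ct$date) >= ref_years[1L] & year_of(ct$date) <= ref_years[2L], ]
      if (!nrow(ref)) stop("temperatures do not cover the reference decade", call. = FALSE)
      ct <- tile_reference_climate(ref, ref_years, ct$date)
    }
    pop <- fix_population(population[population$city_id == cid, ], scenario, ref_years)
    years <- sort(unique(year_of(ct$date)))
    if (!all(years %in% pop$year)) {
      stop("population does not cover the projection horizon for city ", cid, call. = FALSE)
    }
    thr <- thresholds[[cid]]
    if (is.null(thr)) stop("no extreme thresholds for city ", cid, call. = FALSE)
    start_year <- years[1L]
    city_curves <- Filter(function(cv) cv$city_id == cid, curves)
    for (cv in city_curves) {
      ag <- cv$age_group
      rate <- rates$rate[rates$city_id == cid & rates$age_group == ag]
      if (length(rate) != 1L) stop("missing rate for ", cid, "/", ag, call. = FALSE)
      s_hot_base <- if (adaptation == "strong") rr_slope(cv, "hot") else NA_real_
      rho_ag <- if (adaptation == "strong") {
        rho %||% slope_ratio(slope_fits$hot[[ag]], slope_fits$cold[[ag]])
      } else NA_real_
      rows <- lapply(years, function(y) {
        curve_y <- cv
        # a non-rising fitted hot side leaves nothing to rescale
        if (adaptation == "strong" && y >= start_year + 10 && s_hot_base > 0) {
          jja <- seasonal_median(ct, "JJA", end_year = y - 1, window = 10)
          s_new <- adapted_slope(slope_fits$hot[[ag]], jja)
          curve_y <- scale_rr_curve(cv, s_new, s_hot_base, rho_ag,
                                    cap_at_one = cap_at_one, cold_rule = cold_rule)
        }
        b <- project_baseline(rate, pop[[ag]][pop$year == y])
        ty <- ct[year_of(ct$date) == y, ]
        attribute_years(ty, curve_y, b, thr, city_id = cid, age_group = ag)
      })
      out[[length(out) + 1L]] <- do.call(rbind, rows)
    }
  }
  res <- do.call(rbind, out)
  res <- cbind(scenario = scenario, adaptation = adaptation, res)
  class(res) <- c("scenario_result", "data.frame")
  res
}

#' Difference between the all-factor run and a fixed-factor run
#'
#' The contribution of a factor is the all-factor mortality minus the
#' mortality with that factor frozen, per city, age group, year and category.
#'
#' @param all_factor,fixed `scenario_result` objects on the same horizon.
#' @return `data.frame(city_id, age_group, year, heat, cold, extreme_heat,
#'   extreme_cold)` of differences, with attribute `fixed_scenario`.
#' @export
decompose_scenarios <- function(all_factor, fixed) {
  key <- c("city_id", "age_group", "year")
  a <- as.data.frame(all_factor)[order(all_factor$city_id, all_factor$age_group, all_factor$year), ]
  f <- as.data.frame(fixed)[order(fixed$city_id, fixed$age_group, fixed$year), ]
  if (!identical(a[key], f[key])) {
    stop("scenario results cover different cities, ages or years", call. = FALSE)
  }
  cats <- c("heat", "cold", "extreme_heat", "extreme_cold")
  out <- a[key]
  out[cats] <- a[cats] - f[cats]
  attr(out, "fixed_scenario") <- unique(as.character(f$scenario))
  out
}

#' Annual totals of a scenario result or contribution table
#' @param result a `scenario_result` or a [decompose_scenarios()] table.
#' @return `data.frame(year, heat, cold, extreme_heat, extreme_cold, total)`
#'   summed over cities and age groups; total = heat + cold.
#' @export
annual_totals <- function(result) {
  cats <- c("heat", "cold", "extreme_heat", "extreme_cold")
  agg <- stats::aggregate(result[cats], by = list(year = result$year), FUN = sum)
  agg$total <- agg$heat + agg$cold
  agg
}

#' Full three-factor decomposition with interaction residual
#'
#' For each year, the change in total attributable deaths relative to the
#' reference-decade mean of the all-factor run is split into climate,
#' demographic and population contributions (all-factor minus the respective
#' fixed run); the interaction residual — the part of the change the three
#' contributions do not account for — is reported explicitly, never dropped.
#'
#' @param all_factor,fixed_climate,fixed_demographics,fixed_population
#'   `scenario_result` objects on one horizon.
#' @param ref_years reference decade.
#' @return `data.frame(year, total, change, climate, demographics, population,
#'   interaction)`.
#' @export
decomposition_table <- function(all_factor, fixed_climate, fixed_demographics,
                                fixed_population, ref_years = c(2011, 2020)) {
  tot <- annual_totals(all_factor)
  ref <- tot$year >= ref_years[1L] & tot$year <= ref_years[2L]
  if (!any(ref)) stop("horizon does not cover the reference decade", call. = FALSE)
  base <- mean(tot$total[ref])
  contrib <- function(fx) annual_totals(decompose_scenarios(all_factor, fx))$total
  cl <- contrib(fixed_climate); de <- contrib(fixed_demographics); po <- contrib(fixed_population)
  change <- tot$total - base
  data.frame(year = tot$year, total = tot$total, change = change,
             climate = cl, demographics = de, population = po,
             interaction = change - (cl + de + po))
}

#' Global-mean warming series from a model ensemble
#'
#' Two-stage averaging: ensemble members are averaged within each climate
#' model first, then the model means are averaged, so models with many
#' members do not dominate. The result is expressed as an anomaly relative to
#' the mean over a preindustrial reference period.
#'
#' @param models named list; each element is a list of member
#'   `data.frame(year, temp)` (a bare data.frame counts as one member).
#' @param ref_years length-2 first/last year of the preindustrial reference.
#' @return `data.frame(year, warming)` of class `warming_series`.
#' @export
warming_series <- function(models, ref_years = c(1850, 1859)) {
  if (!length(models)) stop("no climate models supplied", call. = FALSE)
  model_means <- lapply(models, function(members) {
    if (is.data.frame(members)) members <- list(members)
    if (!length(members)) stop("empty model group", call. = FALSE)
    years <- members[[1L]]$year
    vals <- sapply(members, function(m) {
      if (!identical(m$year, years)) stop("members cover different years", call. = FALSE)
      m$temp
    })
    data.frame(year = years, temp = rowMeans(as.matrix(vals)))
  })
  years <- model_means[[1L]]$year
  temp <- rowMeans(sapply(model_means, function(m) {
    if (!identical(m$year, years)) stop("models cover different years", call. = FALSE)
    m$temp
  }))
  ref <- years >= ref_years[1L] & years <= ref_years[2L]
  if (!any(ref)) stop("series does not cover the reference period", call. = FALSE)
  structure(data.frame(year = years, warming = temp - mean(temp[ref])),
            class = c("warming_series", "data.frame"))
}

#' Mortality as a function of global warming level
#'
#' Associates each year with its 10-year centered rolling-mean warming and,
#' for each requested level, averages annual deaths over the years whose
#' smoothed warming falls within `half_width` of the level. Levels with no
#' qualifying years are reported as absent (dropped).
#'
#' @param deaths `data.frame(year, deaths)` of annual totals.
#' @param warming a [warming_series()].
#' @param levels warming levels, degrees C.
#' @param half_width bin half-width, degrees C.
#' @param smooth_years rolling-mean window, years.
#' @return `data.frame(level, deaths, n_years)`.
#' @export
mortality_at_warming <- function(deaths, warming, levels = seq(1, 4, by = 0.1),
                                 half_width = 0.05, smooth_years = 10) {
  w <- warming[match(deaths$year, warming$year), "warming"]
  if (anyNA(w)) stop("warming series does not cover all death years", call. = FALSE)
  roll <- as.numeric(stats::filter(w, rep(1 / smooth_years, smooth_years), sides = 2))
  rows <- lapply(levels, function(lv) {
    sel <- !is.na(roll) & abs(roll - lv) <= half_width
    if (!any(sel)) return(NULL)
    data.frame(level = lv, deaths = mean(deaths$deaths[sel]), n_years = sum(sel))
  })
  do.call(rbind, rows)
}

#' Aggregate mortality by latitude band
#'
#' Sums deaths into half-open latitude bins ([30, 35), [35, 40), ...) and
#' divides by the bin population for per-capita rates.
#'
#' @param deaths_by_city `data.frame(city_id, deaths)`.
#' @param cities `data.frame(city_id, lat)`.
#' @param population_by_city `data.frame(city_id, population)`.
#' @param bin_width bin width, degrees.
#' @return `data.frame(lat_lo, lat_hi, deaths, population, per_capita)`.
#' @export
latitude_profile <- function(deaths_by_city, cities, population_by_city, bin_width = 5) {
  lat <- cities$lat[match(deaths_by_city$city_id, cities$city_id)]
  if (anyNA(lat)) {
    stop("cities without latitude: ",
         paste(deaths_by_city$city_id[is.na(lat)], collapse = ", "), call. = FALSE)
  }
  pop <- population_by_city$population[match(deaths_by_city$city_id,
                                             population_by_city$city_id)]
  lo <- floor(lat / bin_width) * bin_width
  agg <- stats::aggregate(cbind(deaths = deaths_by_city$deaths, population = pop),
                          by = list(lat_lo = lo), FUN = sum)
  agg$lat_hi <- agg$lat_lo + bin_width
  agg$per_capita <- agg$deaths / agg$population
  agg[, c("lat_lo", "lat_hi", "deaths", "population", "per_capita")]
}
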