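#' Hot- or cold-side slope of a relative-risk curve
#'
#' Ordinary least-squares slope of RR versus temperature over the curve's
#' grid points strictly above (hot) or below (cold) the MMT. Although RR
#' curves are not linear, the slope is a scalar metric of how steeply risk
#' rises away from the MMT; the cold side is reported as a magnitude.
#'
#' @param curve an `rr_curve`.
#' @param side "hot" or "cold".
#' @return RR per degree C (>= 0 for a rising curve).
#' @export
rr_slope <- function(curve, side = c("hot", "cold")) {
  side <- match.arg(side)
  sel <- if (side == "hot") curve$temp > curve$mmt else curve$temp < curve$mmt
  if (sum(sel) < 3) stop(sprintf("fewer than 3 grid points on the %s side", side),
                         call. = FALSE)
  x <- curve$temp[sel]; y <- curve$rr[sel]
  s <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  if (side == "cold") -s else s
}

#' Trailing seasonal median temperature
#'
#' Median daily mean temperature of the hot season (JJA: June-August) or cold
#' season (DJF: December-February) over a trailing window of years. A DJF
#' winter is labelled by its January's year (December 2019 belongs to DJF
#' 2020); the first winter of a record uses its available January/February
#' days when the preceding December predates the data.
#'
#' @param temps `data.frame(date, temp)`.
#' @param season "JJA" or "DJF".
#' @param end_year last (inclusive) year of the window.
#' @param window window length in years.
#' @return degrees C.
#' @export
seasonal_median <- function(temps, season = c("JJA", "DJF"), end_year, window = 10) {
  season <- match.arg(season)
  dates <- as.Date(temps$date)
  yr <- year_of(dates); mo <- month_of(dates)
  years <- (end_year - window + 1):end_year
  if (season == "JJA") {
    sel <- mo %in% 6:8 & yr %in% years
    covered <- unique(yr[mo %in% 6:8])
  } else {
    season_yr <- ifelse(mo == 12L, yr + 1L, yr)   # Dec joins the next winter
    sel <- mo %in% c(12L, 1L, 2L) & season_yr %in% years
    covered <- unique(season_yr[mo %in% c(1L, 2L)])
  }
  missing <- setdiff(years, covered)
  if (length(missing)) {
    stop("seasonal window not covered for year(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  stats::median(temps$temp[sel])
}

#' Cross-city regression of RR slope on seasonal climate
#'
#' Fits the linear relationship between city vulnerability (hot or cold RR
#' slope) and city climate (JJA or DJF median temperature) across cities —
#' the analogue-city law: cities with warmer summers have flatter hot sides,
#' cities with colder winters flatter cold sides.
#'
#' @param pairs `data.frame` with columns `city_id`, `age_group`, `hot_slope`,
#'   `cold_slope`, `jja_median`, `djf_median` (see [slope_table()]).
#' @param side "hot" (slope vs JJA median) or "cold" (slope vs DJF median).
#' @param age_group optional filter on the `age_group` column.
#' @return object of class `slope_climate_fit`: list(side, age_group,
#'   intercept, slope, residual_sd, n_cities, se_slope, median_range).
#' @export
fit_slope_climate <- function(pairs, side = c("hot", "cold"), age_group = NULL) {
  side <- match.arg(side)
  if (!is.null(age_group)) pairs <- pairs[pairs$age_group == age_group, , drop = FALSE]
  if (nrow(pairs) < 3) stop("at least 3 cities required", call. = FALSE)
  x <- if (side == "hot") pairs$jja_median else pairs$djf_median
  y <- if (side == "hot") pairs$hot_slope else pairs$cold_slope
  if (stats::sd(x) == 0) stop("degenerate variance in seasonal medians", call. = FALSE)
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(side = side, age_group = age_group,
                 intercept = unname(stats::coef(fit)[1L]),
                 slope = unname(stats::coef(fit)[2L]),
                 se_slope = sm$coefficients[2L, 2L],
                 residual_sd = sm$sigma, n_cities = nrow(pairs),
                 median_range = range(x)),
            class = "slope_climate_fit")
}

#' @export
print.slope_climate_fit <- function(x, ...) {
  cat(sprintf("%s-side slope-vs-climate fit%s: slope %.5f (se %.5f) RR/°C per °C, intercept %.4f, %d cities\n",
              x$side, if (!is.null(x$age_group)) paste0(" [", x$age_group, "]") else "",
              x$slope, x$se_slope, x$intercept, x$n_cities))
  invisible(x)
}

#' Ratio of the hot-side to cold-side slope-climate fits
#'
#' The scalar that couples cold-side adaptation to hot-side adaptation:
#' the magnitude of the hot-side fit slope divided by the magnitude of the
#' cold-side fit slope.
#' @param fit_hot,fit_cold [fit_slope_climate()] objects.
#' @return rho (unitless, >= 0).
#' @export
slope_ratio <- function(fit_hot, fit_cold) {
  if (fit_cold$slope == 0) stop("cold-side fit slope is zero", call. = FALSE)
  abs(fit_hot$slope) / abs(fit_cold$slope)
}

#' Slope predicted by the analogue-city law at a given climate
#'
#' Evaluates the cross-city regression at a (possibly future, extrapolated)
#' trailing seasonal median; slopes are clipped at zero — vulnerability never
#' becomes protective.
#' @param fit a [fit_slope_climate()] object.
#' @param trailing_median trailing 10-year seasonal median, degrees C.
#' @return RR per degree C (>= 0).
#' @export
adapted_slope <- function(fit, trailing_median) {
  pmax(0, fit$intercept + fit$slope * trailing_median)
}

#' Rescale a relative-risk curve for adaptation
#'
#' The hot side is scaled so its excess risk (RR - 1) is multiplied by
#' `r_hot = s_hot_new / s_hot_base`; the cold side's fractional risk change is
#' `rho` times the hot side's: `r_cold = max(0, 1 - rho * (1 - r_hot))`. The
#' MMT is left unchanged. With `cold_rule = "literal"` the cold factor is
#' instead `rho * r_hot`.
#'
#' @param curve an `rr_curve`.
#' @param s_hot_new,s_hot_base new and baseline hot-side RR slopes; if the
#'   base slope is 0 the hot factor is 1.
#' @param rho hot-to-cold coupling ratio (see [slope_ratio()]).
#' @param cap_at_one cap the hot factor at 1 so adaptation never increases
#'   vulnerability (default TRUE).
#' @param cold_rule "fractional" (default) or "literal".
#' @return a rescaled `rr_curve`.
#' @export
scale_rr_curve <- function(curve, s_hot_new, s_hot_base, rho,
                           cap_at_one = TRUE, cold_rule = c("fractional", "literal")) {
  cold_rule <- match.arg(cold_rule)
  if (s_hot_base < 0) stop("'s_hot_base' must be >= 0", call. = FALSE)
  r_hot <- if (s_hot_base > 0) s_hot_new / s_hot_base else 1
  if (r_hot < 0) stop("negative hot-side scaling factor", call. = FALSE)
  if (cap_at_one) r_hot <- min(1, r_hot)
  r_cold <- switch(cold_rule,
                   fractional = max(0, 1 - rho * (1 - r_hot)),
                   literal = rho * r_hot)
  hot <- curve$temp > curve$mmt
  cold <- curve$temp < curve$mmt
  rr <- curve$rr
  rr[hot] <- 1 + (rr[hot] - 1) * r_hot
  rr[cold] <- 1 + (rr[cold] - 1) * r_cold
  out <- curve
  out$rr <- rr
  out
}

#' Slope/climate table for a set of fitted curves
#'
#' Convenience assembly of the per-city inputs of [fit_slope_climate()]:
#' hot and cold RR slopes of each curve plus trailing seasonal medians of the
#' fitting-period climate.
#'
#' @param curves list of `rr_curve` objects (with `city_id`/`age_group` set).
#' @param temps_by_city named list of `data.frame(date, temp)` keyed by city.
#' @param end_year last year of the seasonal-median window.
#' @param window window length, years.
#' @return `data.frame` of SlopePair rows.
#' @export
slope_table <- function(curves, temps_by_city, end_year, window = 10) {
  rows <- lapply(curves, function(cv) {
    tm <- temps_by_city[[cv$city_id]]
    if (is.null(tm)) stop("no temperatures for city ", cv$city_id, call. = FALSE)
    data.frame(city_id = cv$city_id, age_group = cv$age_group %||% NA_character_,
               hot_slope = rr_slope(cv, "hot"), cold_slope = rr_slope(cv, "cold"),
               jja_median = seasonal_median(tm, "JJA", end_year, window),
               djf_median = seasonal_median(tm, "DJF", end_year, window))
  })
  do.call(rbind, rows)
}
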