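# CSV schemas, validation, run configuration and the pipeline driver.

iso_date <- function(x, what) {
  if (!all(grepl("^\\d{4}-\\d{2}-\\d{2}$", x))) {
    bad <- x[!grepl("^\\d{4}-\\d{2}-\\d{2}$", x)]
    stop(sprintf("non ISO-8601 date(s) in %s: %s", what,
                 paste(utils::head(bad, 3L), collapse = ", ")), call. = FALSE)
  }
  as.Date(x)
}

check_schema <- function(df, cols, what) {
  if (!identical(names(df), cols)) {
    stop(sprintf("%s must have columns exactly: %s (got: %s)", what,
                 paste(cols, collapse = ","), paste(names(df), collapse = ",")),
         call. = FALSE)
  }
  invisible(df)
}

read_csv_commented <- function(path) {
  if (!file.exists(path)) stop("required file not found: ", path, call. = FALSE)
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Read the canonical input tables
#'
#' Schema-validated readers for the four inputs. Dates must be ISO-8601;
#' each city's daily series must be contiguous (gaps are an error listing the
#' first missing dates); duplicated (city, date) rows are rejected.
#'
#' @param path file path.
#' @return validated `data.frame`s: temperatures `(city_id, date, temp)`,
#'   deaths `(city_id, date, age_group, deaths)`, population
#'   `(city_id, year, age_group, population)`, cities
#'   `(city_id, name, lat, lon)`.
#' @export
read_temperatures <- function(path) {
  df <- check_schema(read_csv_commented(path), c("city_id", "date", "tmean_c"),
                     "temperatures.csv")
  df$date <- iso_date(df$date, "temperatures.csv")
  if (anyDuplicated(df[c("city_id", "date")])) {
    stop("duplicated (city_id, date) rows in temperatures.csv", call. = FALSE)
  }
  for (cid in unique(df$city_id)) {
    check_daily_dates(sort(df$date[df$city_id == cid]),
                      sprintf("temperature dates for city %s", cid))
  }
  stop_if_not_finite(df$tmean_c, "tmean_c")
  data.frame(city_id = df$city_id, date = df$date, temp = df$tmean_c)
}

#' @rdname read_temperatures
#' @export
read_deaths <- function(path) {
  df <- check_schema(read_csv_commented(path),
                     c("city_id", "date", "age_group", "deaths"), "deaths.csv")
  df$date <- iso_date(df$date, "deaths.csv")
  if (!all(df$age_group %in% c("under75", "over75"))) {
    stop("age_group must be 'under75' or 'over75'", call. = FALSE)
  }
  if (anyDuplicated(df[c("city_id", "date", "age_group")])) {
    stop("duplicated (city_id, date, age_group) rows in deaths.csv", call. = FALSE)
  }
  if (any(df$deaths < 0) || any(df$deaths != round(df$deaths))) {
    stop("deaths must be nonnegative integers", call. = FALSE)
  }
  df
}

#' @rdname read_temperatures
#' @export
read_population <- function(path) {
  df <- check_schema(read_csv_commented(path),
                     c("city_id", "year", "age_group", "population"), "population.csv")
  if (any(df$population <= 0)) stop("population must be > 0", call. = FALSE)
  df
}

#' @rdname read_temperatures
#' @export
read_cities <- function(path) {
  df <- check_schema(read_csv_commented(path),
                     c("city_id", "name", "lat", "lon"), "cities.csv")
  stop_if_not_finite(df$lat, "lat")
  df
}

#' Run configuration
#'
#' Collects every tunable of the pipeline with defaults matching the design
#' defaults of the individual stages.
#'
#' @param input_dir directory holding temperatures.csv, deaths.csv,
#'   population.csv, cities.csv.
#' @param out_dir output directory.
#' @param seed integer seed for every stochastic stage.
#' @param exposure_probs exposure-knot percentiles.
#' @param max_lag maximum lag, days.
#' @param n_harmonics annual Fourier pairs.
#' @param mmt_window MMT search percentiles.
#' @param extreme_probs extreme-threshold percentiles.
#' @param adaptation "none" or "strong".
#' @param rho optional override of the hot/cold coupling ratio.
#' @param ref_years reference decade for scenarios.
#' @param scenarios scenario names to run in the projection stage.
#' @return a `run_config` list with a `hash` field (md5 of the settings).
#' @export
run_config <- function(input_dir, out_dir, seed = 1,
                       exposure_probs = c(0.10, 0.75, 0.90), max_lag = 21,
                       n_harmonics = 2, mmt_window = c(0.01, 0.99),
                       extreme_probs = c(0.025, 0.975),
                       adaptation = "none", rho = NULL,
                       ref_years = c(2011, 2020),
                       scenarios = "all_factor") {
  cfg <- list(input_dir = input_dir, out_dir = out_dir, seed = seed,
              exposure_probs = exposure_probs, max_lag = max_lag,
              n_harmonics = n_harmonics, mmt_window = mmt_window,
              extreme_probs = extreme_probs, adaptation = adaptation,
              rho = rho, ref_years = ref_years, scenarios = scenarios)
  cfg$hash <- config_hash(cfg)
  class(cfg) <- "run_config"
  cfg
}

#' @rdname run_config
#' @param cfg a configuration list.
#' @export
config_hash <- function(cfg) {
  cfg$hash <- NULL
  cfg$input_dir <- cfg$out_dir <- NULL      # hash settings, not paths
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(cfg[order(names(cfg))]), f)
  unname(tools::md5sum(f))
}

# all floats at 6 significant digits, first line carries the config hash
write_output_csv <- function(df, path, hash) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write synthetic study inputs to the canonical CSVs
#'
#' Generates daily temperatures and age-stratified deaths for every city of a
#' [sim_city_ensemble()], annual populations, and the city table, and writes
#' them (plus a ground-truth sidecar with the generating law and true slopes)
#' to `dir`. Deterministic given `seed`.
#'
#' @param ensemble a [sim_city_ensemble()] result.
#' @param dir output directory (created if needed).
#' @param start_year,end_year span of the daily series.
#' @param baseline_rate named `c(under75 = , over75 = )` expected deaths/day
#'   at the MMT.
#' @param dispersion count variance-to-mean ratio.
#' @param pop_spec a [population_spec()] applied to every city.
#' @param warming_per_year warming trend applied to every city, degrees C/yr.
#' @param seed integer seed.
#' @return invisibly, the list of written paths.
#' @export
write_synthetic_inputs <- function(ensemble, dir, start_year, end_year,
                                   baseline_rate = c(under75 = 12, over75 = 14),
                                   dispersion = 1.3,
                                   pop_spec = population_spec(
                                     c(under75 = 95e4, over75 = 5e4),
                                     growth_per_year = 0.005,
                                     aging_shift_per_year = 0.001),
                                   warming_per_year = 0, seed = 1) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  temps <- deaths <- pops <- list()
  years <- start_year:end_year
  for (i in seq_along(ensemble$specs)) {
    sp <- ensemble$specs[[i]]
    sp$warming_per_year <- warming_per_year
    tm <- sim_temperature(sp, start_year, end_year, seed = seed + 13L * i)
    temps[[i]] <- data.frame(city_id = sp$city_id, date = format(tm$date),
                             tmean_c = tm$temp)
    for (j in 1:2) {
      ag <- c("under75", "over75")[j]
      dd <- sim_deaths(tm, ensemble$surfaces[[i]], baseline_rate[[ag]],
                       dispersion = dispersion, seed = seed + 13L * i + j)
      deaths[[length(deaths) + 1L]] <-
        data.frame(city_id = sp$city_id, date = format(dd$date),
                   age_group = ag, deaths = dd$deaths)
    }
    pops[[i]] <- sim_population(pop_spec, years, city_id = sp$city_id)
  }
  cities <- data.frame(city_id = ensemble$truth$city_id,
                       name = ensemble$truth$city_id,
                       lat = ensemble$truth$latitude, lon = -95)
  paths <- c(temperatures = file.path(dir, "temperatures.csv"),
             deaths = file.path(dir, "deaths.csv"),
             population = file.path(dir, "population.csv"),
             cities = file.path(dir, "cities.csv"),
             truth = file.path(dir, "ground_truth.csv"))
  utils::write.csv(do.call(rbind, temps), paths["temperatures"], row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, deaths), paths["deaths"], row.names = FALSE, quote = FALSE)
  utils::write.csv(do.call(rbind, pops), paths["population"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cities, paths["cities"], row.names = FALSE, quote = FALSE)
  utils::write.csv(cbind(ensemble$truth,
                         as.data.frame(ensemble$law[c("a_hot", "b_hot", "a_cold", "b_cold")])),
                   paths["truth"], row.names = FALSE, quote = FALSE)
  invisible(paths)
}

#' Run the fitting/attribution pipeline on the canonical inputs
#'
#' Reads the four input CSVs, fits the DLNM per city and age group, reduces
#' each fit to its RR curve, computes baseline deaths, extreme thresholds and
#' annual attribution, fits the cross-city slope-vs-climate regressions, and
#' writes `rr_curves.csv`, `slopes.csv`, `slope_fits.csv`, `attribution.csv`
#' and `manifest.json` to the output directory. Re-running with the same
#' configuration and inputs produces byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the fitted curves, slope table, slope fits,
#'   rho per age group, attribution table, thresholds, rates and output paths.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  temps <- read_temperatures(file.path(config$input_dir, "temperatures.csv"))
  deaths <- read_deaths(file.path(config$input_dir, "deaths.csv"))
  pop <- read_population(file.path(config$input_dir, "population.csv"))
  cities <- read_cities(file.path(config$input_dir, "cities.csv"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  curves <- list(); attrib <- list(); rates <- list(); thresholds <- list()
  temps_by_city <- split(temps[c("date", "temp")], temps$city_id)
  fit_years <- range(year_of(temps$date))
  for (cid in unique(temps$city_id)) {
    ct <- temps_by_city[[cid]]
    ct <- ct[order(ct$date), ]
    thresholds[[cid]] <- extreme_thresholds(ct, config$extreme_probs)
    for (ag in c("under75", "over75")) {
      dd <- deaths[deaths$city_id == cid & deaths$age_group == ag,
                   c("date", "deaths")]
      dd <- dd[order(dd$date), ]
      fit <- tm_fit(dd, ct, city_id = cid, age_group = ag,
                    exposure = exposure_knots(ct$temp, config$exposure_probs),
                    max_lag = config$max_lag, n_harmonics = config$n_harmonics,
                    mmt_window = config$mmt_window)
      cv <- cumulative_rr(fit)
      b <- baseline_deaths(dd, ct, cv$mmt)
      pop_hist <- mean(pop$population[pop$city_id == cid & pop$age_group == ag &
                                        pop$year >= fit_years[1L] &
                                        pop$year <= fit_years[2L]])
      curves[[paste(cid, ag, sep = ".")]] <- cv
      attrib[[paste(cid, ag, sep = ".")]] <-
        attribute_years(ct, cv, b, thresholds[[cid]])
      rates[[paste(cid, ag, sep = ".")]] <-
        data.frame(city_id = cid, age_group = ag, baseline = b,
                   rate = death_rate(b, pop_hist))
    }
  }
  slopes <- slope_table(curves, temps_by_city, end_year = fit_years[2L],
                        window = min(10, fit_years[2L] - fit_years[1L] + 1L))
  fits <- list(hot = list(), cold = list())
  rho <- list()
  for (ag in c("under75", "over75")) {
    fits$hot[[ag]] <- fit_slope_climate(slopes, "hot", ag)
    fits$cold[[ag]] <- fit_slope_climate(slopes, "cold", ag)
    rho[[ag]] <- config$rho %||% slope_ratio(fits$hot[[ag]], fits$cold[[ag]])
  }

  h <- config$hash
  curve_df <- do.call(rbind, lapply(curves, function(cv) {
    data.frame(city = cv$city_id, age = cv$age_group, temp = cv$temp,
               rr = cv$rr, mmt = cv$mmt)
  }))
  fit_df <- do.call(rbind, lapply(c("hot", "cold"), function(sd) {
    do.call(rbind, lapply(c("under75", "over75"), function(ag) {
      f <- fits[[sd]][[ag]]
      data.frame(side = sd, age_group = ag, intercept = f$intercept,
                 slope = f$slope, se_slope = f$se_slope,
                 residual_sd = f$residual_sd, n_cities = f$n_cities,
                 rho = rho[[ag]])
    }))
  }))
  attrib_df <- do.call(rbind, c(attrib, list(make.row.names = FALSE)))
  paths <- c(rr_curves = file.path(config$out_dir, "rr_curves.csv"),
             slopes = file.path(config$out_dir, "slopes.csv"),
             slope_fits = file.path(config$out_dir, "slope_fits.csv"),
             attribution = file.path(config$out_dir, "attribution.csv"),
             manifest = file.path(config$out_dir, "manifest.json"))
  write_output_csv(curve_df, paths["rr_curves"], h)
  write_output_csv(slopes, paths["slopes"], h)
  write_output_csv(fit_df, paths["slope_fits"], h)
  write_output_csv(attrib_df, paths["attribution"], h)
  manifest <- list(config_hash = h, seed = config$seed,
                   package = "tempmort",
                   version = as.character(utils::packageVersion("tempmort")),
                   r_version = R.version.string)
  jsonlite::write_json(manifest, paths["manifest"], auto_unbox = TRUE, pretty = TRUE)
  invisible(list(curves = curves, slopes = slopes, slope_fits = fits, rho = rho,
                 attribution = attrib_df, thresholds = thresholds,
                 rates = do.call(rbind, c(rates, list(make.row.names = FALSE))),
                 paths = paths, config = config))
}
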