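# small scenario fixture built from ground-truth curves (no fitting needed)
scenario_fixture <- function(seed = 1, n_cities = 2, start = 2006, end = 2025,
                             warming = 0, growth = 0.01, aging = 0.002) {
  ens <- sim_city_ensemble(max(n_cities, 3), seed = seed)
  cities <- seq_len(n_cities)
  temps <- list(); curves <- list(); pop <- list(); thr <- list(); rates <- list()
  for (i in cities) {
    sp <- ens$specs[[i]]
    sp$warming_per_year <- warming
    tm <- sim_temperature(sp, start, end, seed = seed + i)
    temps[[i]] <- cbind(city_id = sp$city_id, tm)
    thr[[sp$city_id]] <- extreme_thresholds(tm[1:3653, ])
    for (ag in c("under75", "over75")) {
      cv <- true_curve(ens$surfaces[[i]], lo = min(tm$temp) - 3,
                       hi = max(tm$temp) + 3, city_id = sp$city_id, age_group = ag)
      curves[[paste(sp$city_id, ag)]] <- cv
      rates[[paste(sp$city_id, ag)]] <-
        data.frame(city_id = sp$city_id, age_group = ag,
                   rate = ifelse(ag == "over75", 10, 8) / 1e5)
    }
    pop[[i]] <- sim_population(population_spec(c(under75 = 95e4, over75 = 5e4),
                                               growth, aging),
                               start:end, city_id = sp$city_id)
  }
  list(temps = do.call(rbind, temps), population = do.call(rbind, pop),
       curves = curves, rates = do.call(rbind, rates), thresholds = thr,
       truth = ens$truth[cities, ], ens = ens)
}

test_that("baseline rates scale with population and aging shifts them", {
  expect_equal(project_baseline(death_rate(10, 1e5), 1e5), 10)
  expect_equal(project_baseline(death_rate(10, 1e5), 2e5), 20)
  # aging with fixed total: over-75 baseline rises by the share ratio
  r_u <- death_rate(8, 9e5); r_o <- death_rate(12, 1e5)
  tot <- 1e6
  b_o <- project_baseline(r_o, tot * 0.2); b_u <- project_baseline(r_u, tot * 0.8)
  expect_equal(b_o, 12 * 2)
  expect_equal(b_u, 8 * 0.8 / 0.9)
  expect_error(death_rate(10, 0), "population")
})

test_that("reference-climate tiling repeats the decade and handles leap days", {
  spec <- city_climate_spec("c", 40, 12, 9, ar1_coef = 0, noise_sd = 0)
  ref <- sim_temperature(spec, 2011, 2020, seed = 1)
  target <- seq(as.Date("2021-01-01"), as.Date("2040-12-31"), by = "day")
  tiled <- tile_reference_climate(ref, c(2011, 2020), target)
  expect_equal(nrow(tiled), length(target))
  # 2031 maps back onto 2011
  t1 <- tiled$temp[format(tiled$date, "%Y-%m-%d") >= "2031-03-01" &
                     format(tiled$date, "%Y-%m-%d") <= "2031-03-10"]
  s1 <- ref$temp[format(ref$date, "%Y-%m-%d") >= "2011-03-01" &
                   format(ref$date, "%Y-%m-%d") <= "2011-03-10"]
  expect_equal(t1, s1)
  # Feb 29 2024 sources 2014 (no leap day there): falls back to Feb 28 2014
  v <- tiled$temp[tiled$date == as.Date("2024-02-29")]
  expect_equal(v, ref$temp[ref$date == as.Date("2014-02-28")])
  # tiling its own reference period is the identity
  self <- tile_reference_climate(ref, c(2011, 2020), ref$date)
  expect_equal(self$temp, ref$temp)
})

test_that("fixing rules are idempotent against already-fixed inputs", {
  fx <- scenario_fixture(seed = 3, start = 2006, end = 2025)
  # constant population: fixed_population and fixed_demographics equal all_factor
  pop_const <- fx$population
  pop_const$population <- ifelse(pop_const$age_group == "over75", 5e4, 95e4)
  base <- run_scenario("all_factor", fx$temps, pop_const, fx$curves, fx$rates,
                       fx$thresholds, ref_years = c(2011, 2020))
  fp <- run_scenario("fixed_population", fx$temps, pop_const, fx$curves, fx$rates,
                     fx$thresholds, ref_years = c(2011, 2020))
  fd <- run_scenario("fixed_demographics", fx$temps, pop_const, fx$curves, fx$rates,
                     fx$thresholds, ref_years = c(2011, 2020))
  cats <- c("heat", "cold", "extreme_heat", "extreme_cold")
  expect_equal(fp[cats], base[cats], tolerance = 1e-12)
  expect_equal(fd[cats], base[cats], tolerance = 1e-12)

  # input that already repeats the reference decade: fixed_climate = all_factor
  ref_block <- fx$temps[fx$temps$city_id == fx$truth$city_id[1], ]
  ref_block <- ref_block[format(ref_block$date, "%Y") %in% as.character(2011:2020), ]
  tiled <- tile_reference_climate(ref_block[, c("date", "temp")], c(2011, 2020),
                                  sort(unique(fx$temps$date[fx$temps$city_id ==
                                                              fx$truth$city_id[1]])))
  temps2 <- cbind(city_id = fx$truth$city_id[1], tiled)
  curves1 <- fx$curves[grep(fx$truth$city_id[1], names(fx$curves))]
  a2 <- run_scenario("all_factor", temps2, fx$population, curves1, fx$rates,
                     fx$thresholds, ref_years = c(2011, 2020))
  f2 <- run_scenario("fixed_climate", temps2, fx$population, curves1, fx$rates,
                     fx$thresholds, ref_years = c(2011, 2020))
  expect_equal(f2[cats], a2[cats], tolerance = 1e-12)
})

test_that("decomposition identities hold and interaction is reported", {
  fx <- scenario_fixture(seed = 5, n_cities = 2)
  args <- list(temps = fx$temps, population = fx$population, curves = fx$curves,
               rates = fx$rates, thresholds = fx$thresholds,
               ref_years = c(2011, 2020))
  a <- do.call(run_scenario, c(list("all_factor"), args))
  d0 <- decompose_scenarios(a, a)
  expect_true(all(d0[c("heat", "cold")] == 0))

  fc <- do.call(run_scenario, c(list("fixed_climate"), args))
  fd <- do.call(run_scenario, c(list("fixed_demographics"), args))
  fp <- do.call(run_scenario, c(list("fixed_population"), args))
  tab <- decomposition_table(a, fc, fd, fp, ref_years = c(2011, 2020))
  expect_true(all(c("climate", "demographics", "population", "interaction") %in%
                    names(tab)))
  # the interaction residual completes the stated identity by construction
  expect_equal(tab$interaction,
               tab$change - (tab$climate + tab$demographics + tab$population),
               tolerance = 1e-9)
  # population growth only: population contribution = D_all - D_fixedpop exactly
  contrib <- decompose_scenarios(a, fp)
  by_year <- annual_totals(contrib)
  manual <- annual_totals(a)$total - annual_totals(fp)$total
  expect_equal(by_year$total, manual, tolerance = 1e-9)
})

test_that("two-stage warming mean differs from the pooled member mean", {
  models <- list(m1 = list(data.frame(year = 2000, temp = 0),
                           data.frame(year = 2000, temp = 4)),
                 m2 = data.frame(year = 2000, temp = 1))
  # need a reference period: extend with identical pre-industrial years
  mk <- function(v) data.frame(year = c(1850:1859, 2000), temp = c(rep(0, 10), v))
  models <- list(m1 = list(mk(0), mk(4)), m2 = mk(1))
  ws <- warming_series(models, ref_years = c(1850, 1859))
  expect_equal(ws$warming[ws$year == 2000], 1.5)          # (2 + 1) / 2
  expect_false(isTRUE(all.equal(ws$warming[ws$year == 2000], 5 / 3)))
  # reference decade anomaly averages zero
  expect_equal(mean(ws$warming[ws$year <= 1859]), 0)
  expect_error(warming_series(list()), "models")
  expect_error(warming_series(list(m = list())), "empty")
})

test_that("warming-level binning matches a brute-force year selection", {
  yrs <- 1950:2100
  w <- data.frame(year = yrs, warming = 0.02 * (yrs - 1950) +
                    sin(yrs / 7) * 0.01)
  class(w) <- c("warming_series", "data.frame")
  dth <- data.frame(year = yrs, deaths = 1000 + 2 * (yrs - 1950))
  mv <- mortality_at_warming(dth, w, levels = seq(0.5, 2.5, 0.5))
  roll <- as.numeric(stats::filter(w$warming, rep(0.1, 10), sides = 2))
  for (i in seq_len(nrow(mv))) {
    sel <- !is.na(roll) & abs(roll - mv$level[i]) <= 0.05
    expect_equal(mv$deaths[i], mean(dth$deaths[sel]))
    expect_equal(mv$n_years[i], sum(sel))
  }
  # constant deaths map every populated level to that constant
  dth2 <- data.frame(year = yrs, deaths = 123)
  mv2 <- mortality_at_warming(dth2, w, levels = seq(0.5, 2.5, 0.5))
  expect_true(all(mv2$deaths == 123))
})

test_that("latitude bins are half-open and aggregate population-weighted", {
  deaths <- data.frame(city_id = c("a", "b", "c"), deaths = c(100, 200, 50))
  cities <- data.frame(city_id = c("a", "b", "c"), lat = c(32.1, 35.0, 43.9))
  pop <- data.frame(city_id = c("a", "b", "c"), population = c(1e5, 2e5, 5e4))
  lp <- latitude_profile(deaths, cities, pop)
  expect_equal(lp$lat_lo, c(30, 35, 40))
  expect_equal(lp$deaths, c(100, 200, 50))       # one city per bin
  expect_equal(lp$per_capita, c(100 / 1e5, 200 / 2e5, 50 / 5e4))
  # city at exactly 35.0 fell in [35, 40)
  expect_equal(lp$lat_lo[lp$deaths == 200], 35)
  # merging bins: per-capita of the merged bin is the pop-weighted mean
  lp10 <- latitude_profile(deaths, cities, pop, bin_width = 10)
  merged <- lp10[lp10$lat_lo == 30, ]
  expect_equal(merged$per_capita,
               sum(lp$deaths[1:2]) / sum(lp$population[1:2]))
  expect_error(latitude_profile(deaths, cities[1:2, ], pop), "latitude")
})

test_that("strong adaptation never exceeds no-adaptation heat burden", {
  # warming cities with slope-climate fits from the generating law
  fx <- scenario_fixture(seed = 7, n_cities = 2, start = 2006, end = 2030,
                         warming = 0.06)
  pairs <- do.call(rbind, lapply(c("under75", "over75"), function(ag) {
    data.frame(city_id = fx$ens$truth$city_id, age_group = ag,
               hot_slope = fx$ens$truth$hot_slope,
               cold_slope = fx$ens$truth$cold_slope,
               jja_median = fx$ens$truth$jja_median,
               djf_median = fx$ens$truth$djf_median)
  }))
  fits <- list(hot = list(), cold = list())
  for (ag in c("under75", "over75")) {
    fits$hot[[ag]] <- fit_slope_climate(pairs, "hot", ag)
    fits$cold[[ag]] <- fit_slope_climate(pairs, "cold", ag)
  }
  args <- list(temps = fx$temps, population = fx$population, curves = fx$curves,
               rates = fx$rates, thresholds = fx$thresholds,
               ref_years = c(2011, 2020))
  none <- do.call(run_scenario, c(list("all_factor"), args))
  strong <- do.call(run_scenario, c(list("all_factor"), args,
                                    list(adaptation = "strong", slope_fits = fits)))
  key <- paste(none$city_id, none$age_group, none$year)
  expect_identical(key, paste(strong$city_id, strong$age_group, strong$year))
  expect_true(all(strong$heat <= none$heat + 1e-9))
  # equality over the first decade of the record (no adaptation before year 11)
  first <- none$year < 2006 + 10
  expect_equal(strong$heat[first], none$heat[first], tolerance = 1e-12)
  expect_gt(sum(none$heat) - sum(strong$heat), 0)  # adaptation bites under warming
})

test_that("climate contribution is negative in hot-summer cities and positive in cool ones", {
  # no adaptation; slopes follow the generating law, so hot cities have flat
  # hot sides and steep cold sides (cold benefit dominates) while cool cities
  # have the reverse -- a sign test on the poleward-shift pattern
  ens <- sim_city_ensemble(12, seed = 61)
  ord <- order(ens$truth$jja_median)
  pick <- c(ord[1], ord[12])                    # coolest and hottest summers
  ids <- ens$truth$city_id[pick]
  temps <- list(); curves <- list(); thr <- list()
  for (k in seq_along(pick)) {
    i <- pick[k]
    sp <- ens$specs[[i]]; sp$warming_per_year <- 0.06
    tm <- sim_temperature(sp, 2006, 2035, seed = 62 + i)
    temps[[k]] <- cbind(city_id = sp$city_id, tm)
    thr[[sp$city_id]] <- extreme_thresholds(tm[1:3653, ])
    curves[[k]] <- true_curve(ens$surfaces[[i]], lo = min(tm$temp) - 3,
                              hi = max(tm$temp) + 3, city_id = sp$city_id,
                              age_group = "under75")
  }
  pop <- do.call(rbind, lapply(ids, function(cid) {
    sim_population(population_spec(c(under75 = 95e4, over75 = 5e4)),
                   2006:2035, city_id = cid)
  }))
  args <- list(temps = do.call(rbind, temps), population = pop, curves = curves,
               rates = data.frame(city_id = ids, age_group = "under75", rate = 1e-4),
               thresholds = thr, ref_years = c(2011, 2020))
  a <- suppressWarnings(do.call(run_scenario, c(list("all_factor"), args)))
  fc <- suppressWarnings(do.call(run_scenario, c(list("fixed_climate"), args)))
  d <- decompose_scenarios(a, fc)
  contrib <- function(cid) {
    sel <- d$city_id == cid & d$year >= 2026
    mean(d$heat[sel] + d$cold[sel])
  }
  expect_gt(contrib(ids[1]), 0)   # cool-summer city: warming adds deaths
  expect_lt(contrib(ids[2]), 0)   # hot-summer city: warming removes deaths
})
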