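test_that("quasi-Poisson fitter reproduces closed-form and saturated fits", {
  # intercept-only: MLE is the log of the mean
  f <- fit_qpois(c(1, 2, 3), matrix(1, 3, 1, dimnames = list(NULL, "i")))
  expect_equal(unname(f$coefficients), log(2), tolerance = 1e-10)

  # saturated design reproduces the observations exactly
  y <- c(4, 7, 2, 9)
  X <- diag(4); colnames(X) <- paste0("d", 1:4)
  fs <- fit_qpois(y, X)
  expect_equal(unname(fs$fitted), y, tolerance = 1e-8)
})

test_that("IRLS agrees with an independent Newton-Raphson solver", {
  set.seed(21)
  n <- 200
  X <- cbind(1, rnorm(n), runif(n))
  colnames(X) <- c("i", "x1", "x2")
  beta_true <- c(1.2, 0.4, -0.8)
  y <- rpois(n, exp(X %*% beta_true))
  f <- fit_qpois(y, X)
  oracle <- newton_poisson(y, X)
  expect_lt(max(abs(unname(f$coefficients) - oracle)), 1e-6)
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  X <- cbind(a = rep(1, 10), b = 1:10, c = 2 * (1:10))
  expect_error(fit_qpois(rpois(10, 5), X), "collinear.*c")
})

test_that("confounder matrix has weekly and annual periodicity", {
  dates <- seq(as.Date("1995-01-01"), by = "day", length.out = 1200)
  M <- confounder_matrix(dates, n_harmonics = 2)
  expect_equal(ncol(M), 6 + 2 * 2 + 1)
  # day-of-week columns repeat with period 7
  dow <- grep("^dow", colnames(M))
  expect_equal(M[8, dow], M[1, dow])
  expect_equal(M[100, dow], M[107, dow])
  # annual harmonics at lag 365.25 days: compare the continuous-time harmonic
  h <- function(t) c(sin(2 * pi * t / 365.25), cos(2 * pi * t / 365.25))
  t0 <- as.numeric(dates[1])
  expect_equal(h(t0), h(t0 + 365.25), tolerance = 1e-6)
  # and the matrix columns at integer dates one period apart (365 d + 0.25 d)
  harm <- M[, c("sin1", "cos1")]
  drift <- harm[366, ] - h(t0 + 365)[1:2]
  expect_lt(max(abs(drift)), 1e-12)
  expect_error(confounder_matrix(rep(dates[1], 2)), "duplicated")
})

test_that("zero temperature effect yields a flat cumulative RR curve", {
  # very large city (200 deaths/day), 10 years; flatness is judged over the
  # MMT search window (P1-P99 of fitting temperatures), the range on which
  # the curve is used downstream — beyond it the spline tails are
  # extrapolation with little data
  spec <- ref_city_spec()
  tm <- sim_temperature(spec, 1991, 2000, seed = 31)
  dd <- sim_deaths(tm, rr_surface(23, 0, 0), baseline_rate = 200,
                   dispersion = 1.3, seed = 32)
  fit <- tm_fit(dd, tm)
  cv <- cumulative_rr(fit)
  w <- fit$mmt_window
  sel <- cv$temp >= w[1] & cv$temp <= w[2]
  expect_lt(max(abs(log(cv$rr[sel]))), 0.05)
})

test_that("RR curves are invariant to rescaling the death counts", {
  spec <- ref_city_spec()
  tm <- sim_temperature(spec, 1994, 1999, seed = 41)
  dd <- sim_deaths(tm, ref_surface(), baseline_rate = 15, seed = 42)
  f1 <- tm_fit(dd, tm)
  dd2 <- dd; dd2$deaths <- 2L * dd$deaths
  f2 <- tm_fit(dd2, tm)
  c1 <- cumulative_rr(f1); c2 <- cumulative_rr(f2)
  expect_equal(c1$rr, c2$rr, tolerance = 1e-6)
  expect_equal(c1$mmt, c2$mmt)
  # and refitting identical inputs is bit-identical
  f3 <- tm_fit(dd, tm)
  expect_identical(f1$coefficients, f3$coefficients)
  expect_identical(cumulative_rr(f3)$rr, c1$rr)
})

test_that("MMT search respects window, ties and shift invariance", {
  grid <- seq(0, 40, by = 0.1)
  win <- c(5, 35)
  parab <- (grid - 22)^2 / 100
  expect_equal(as.numeric(find_mmt(parab, grid, win)), 22.0)
  # monotone decreasing curve ends at the window's upper bound
  expect_equal(as.numeric(find_mmt(-grid, grid, win)), 35.0)
  # adding a constant does not move the argmin
  expect_equal(as.numeric(find_mmt(parab + 5, grid, win)),
               as.numeric(find_mmt(parab, grid, win)))
  # ties break toward the warmer temperature
  flat_mid <- pmax(abs(grid - 20), 2)
  expect_equal(as.numeric(find_mmt(flat_mid, grid, win)), 22.0)
  expect_warning(m <- find_mmt(rep(1, length(grid)), grid, win), "flat")
  expect_true(attr(m, "flat"))
})

test_that("cumulative RR equals a brute-force double sum and is 1 at the MMT", {
  # hand-set model with a small 2x2 cross-basis
  expo <- list(knots = 10, boundary = c(0, 20))      # 2 columns
  lg <- list(knots = numeric(0), boundary = c(0, 21)) # 2 columns (intercept)
  beta <- c(0.02, -0.01, 0.015, 0.005)
  model <- structure(list(
    coefficients = stats::setNames(c(0.5, beta), c("(Intercept)",
      paste0("cb_", rep(1:2, each = 2), "_", rep(1:2, 2)))),
    cb_cols = 2:5, exposure = expo, lag = lg, max_lag = 21,
    temp_range = c(0, 20), mmt_window = c(1, 19)), class = "tm_model")
  cv <- cumulative_rr(model)
  expect_equal(cv$rr[which.min(abs(cv$temp - cv$mmt))], 1.0)

  be_f <- function(t) ns_basis(t, expo$knots, expo$boundary)
  bl <- ns_basis(0:21, lg$knots, lg$boundary, intercept = TRUE)
  brute <- function(t) {
    s <- 0
    for (l in 0:21) for (j in 1:2) for (k in 1:2) {
      s <- s + be_f(t)[1, j] * bl[l + 1, k] * beta[(j - 1) * 2 + k]
    }
    s
  }
  for (t in c(3.0, 11.5, 19.0)) {
    lr_pkg <- log(rr_at(cv, t)) + (brute(cv$mmt))
    expect_equal(lr_pkg, brute(t), tolerance = 1e-6)
  }

  # all-zero coefficients give the unit curve
  m0 <- model
  m0$coefficients[2:5] <- 0
  expect_warning(c0 <- cumulative_rr(m0), "flat")
  expect_true(all(c0$rr == 1))
})

test_that("model methods expose coefficients, residuals and predictions", {
  spec <- ref_city_spec()
  tm <- sim_temperature(spec, 1995, 1999, seed = 51)
  dd <- sim_deaths(tm, ref_surface(), baseline_rate = 20, seed = 52)
  fit <- tm_fit(dd, tm, city_id = "ref", age_group = "over75")
  expect_s3_class(fit, "tm_model")
  expect_equal(length(coef(fit)), nrow(vcov(fit)))
  expect_true(all(eigen(vcov(fit), symmetric = TRUE, only.values = TRUE)$values > -1e-8))
  expect_output(print(fit), "dispersion")
  expect_output(print(summary(fit)), "MMT")
  r <- residuals(fit)
  expect_equal(length(r), length(fit$valid))
  expect_lt(abs(mean(r)), 0.1)
  # predict on the training data reproduces the stored fitted values
  mu <- predict(fit, data.frame(date = tm$date, temp = tm$temp), type = "response")
  expect_equal(mu[fit$valid], fit$fitted[fit$valid], tolerance = 1e-8)
  p_rr <- predict(fit, c(23, 33), type = "rr")
  expect_equal(length(p_rr), 2L)
  sim <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(sim, simulate(fit, nsim = 2, seed = 5))
  expect_equal(length(sim[[1]]), length(fit$valid))
})

test_that("dispersion estimate recovers the generating dispersion", {
  spec <- ref_city_spec()
  tm <- sim_temperature(spec, 1987, 2000, seed = 61)[1:5000, ]
  dd <- sim_deaths(tm, ref_surface(), baseline_rate = 30, dispersion = 1.3, seed = 62)
  fit <- tm_fit(dd[1:5000, ], tm)
  expect_lt(abs(fit$dispersion - 1.3), 0.2)
})
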