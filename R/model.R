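#' Quasi-Poisson regression by iteratively reweighted least squares
#'
#' Fits a log-link Poisson-mean model and estimates the dispersion as the
#' Pearson chi-square divided by the residual degrees of freedom; the
#' coefficient covariance is `dispersion * (X' W X)^-1`.
#'
#' @param y nonnegative integer counts.
#' @param X design matrix, full column rank.
#' @param weights optional prior weights.
#' @return list with `coefficients`, `vcov`, `dispersion`, `fitted`,
#'   `deviance`, `df_residual`.
#' @export
fit_qpois <- function(y, X, weights = NULL) {
  X <- as.matrix(X)
  if (any(y < 0) || any(y != round(y))) {
    stop("'y' must be nonnegative integer counts", call. = FALSE)
  }
  qrx <- qr(X)
  if (qrx$rank < ncol(X)) {
    bad <- colnames(X)[qrx$pivot[(qrx$rank + 1L):ncol(X)]] %||% ""
    stop("design matrix is rank deficient; collinear columns: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  w <- weights %||% rep(1, length(y))
  fit <- stats::glm.fit(x = X, y = y, weights = w, family = stats::quasipoisson(),
                        control = stats::glm.control(epsilon = 1e-12, maxit = 100))
  if (!fit$converged) {
    stop(sprintf("IRLS did not converge in 100 iterations (last deviance %.6g)",
                 fit$deviance), call. = FALSE)
  }
  mu <- fit$fitted.values
  df <- length(y) - ncol(X)
  pearson <- sum(w * (y - mu)^2 / mu)
  dispersion <- pearson / df
  xw <- X * sqrt(w * mu)                      # IRLS weights at the solution
  vcov <- dispersion * chol2inv(chol(crossprod(xw)))
  dimnames(vcov) <- list(colnames(X), colnames(X))
  list(coefficients = stats::setNames(fit$coefficients, colnames(X)),
       vcov = vcov, dispersion = dispersion, fitted = mu,
       deviance = fit$deviance, df_residual = df)
}

#' Confounder design matrix for the daily mortality regression
#'
#' Columns: 6 day-of-week indicators (Sunday is the reference), `n_harmonics`
#' sine/cosine pairs with a 365.25-day period for the annual cycle, and a
#' linear year term for the long-term trend.
#'
#' @param dates contiguous daily `Date` vector.
#' @param n_harmonics number of annual Fourier harmonic pairs.
#' @return matrix with `6 + 2 * n_harmonics + 1` columns.
#' @export
confounder_matrix <- function(dates, n_harmonics = 2) {
  check_daily_dates(dates)
  wday <- as.POSIXlt(dates)$wday               # 0 = Sunday (reference)
  dow <- sapply(1:6, function(d) as.numeric(wday == d))
  colnames(dow) <- paste0("dow", 1:6)
  t <- as.numeric(dates)                       # days; 365.25-day periodicity exact
  harm <- do.call(cbind, lapply(seq_len(n_harmonics), function(k) {
    m <- cbind(sin(2 * pi * k * t / 365.25), cos(2 * pi * k * t / 365.25))
    colnames(m) <- paste0(c("sin", "cos"), k)
    m
  }))
  trend <- (t - mean(t)) / 365.25
  cbind(dow, harm, trend = trend)
}

#' Fit a city temperature-mortality model
#'
#' Fits the distributed-lag non-linear model (DLNM) for one city and age
#' group: a quasi-Poisson regression of daily deaths on the temperature
#' cross-basis (lags 0..21 by default) plus day-of-week, annual-cycle and
#' long-term-trend confounders. Days without a full lag history are excluded
#' from the likelihood.
#'
#' @param deaths `data.frame(date, deaths)` of daily counts.
#' @param temps `data.frame(date, temp)` of daily mean temperatures, degrees C,
#'   covering the same dates.
#' @param city_id,age_group optional labels stored on the fit.
#' @param exposure,lag knot specifications (see [exposure_knots()],
#'   [lag_knots()]); defaults follow standard DLNM practice.
#' @param max_lag maximum lag, days.
#' @param n_harmonics annual Fourier pairs in the confounder set.
#' @param mmt_window percentile window of fitting-period temperatures within
#'   which the minimum mortality temperature is searched.
#' @return An object of class `tm_model`.
#' @seealso [cumulative_rr()], [predict.tm_model()], [plot.tm_model()]
#' @examples
#' spec <- city_climate_spec("c01", 41, mean_temp = 14, seasonal_amplitude = 10)
#' tm <- sim_temperature(spec, 1991, 1996, seed = 8)
#' dth <- sim_deaths(tm, rr_surface(21, 0.03, 0.008), baseline_rate = 25, seed = 9)
#' fit <- tm_fit(dth, tm)
#' fit
#' @export
tm_fit <- function(deaths, temps, city_id = NULL, age_group = NULL,
                   exposure = NULL, lag = NULL, max_lag = 21, n_harmonics = 2,
                   mmt_window = c(0.01, 0.99)) {
  if (!identical(as.Date(deaths$date), as.Date(temps$date))) {
    stop("'deaths' and 'temps' must cover identical daily dates", call. = FALSE)
  }
  dates <- as.Date(deaths$date)
  check_daily_dates(dates)
  if (length(dates) < 2 * 365) stop("at least 2 years of daily data required", call. = FALSE)
  exposure <- exposure %||% exposure_knots(temps$temp)
  lag <- lag %||% lag_knots(max_lag)
  cb <- cross_basis(temps$temp, exposure, lag, max_lag)
  conf <- confounder_matrix(dates, n_harmonics)
  X <- cbind(`(Intercept)` = 1, cb, conf)
  valid <- attr(cb, "valid_from"):nrow(X)
  fit <- fit_qpois(deaths$deaths[valid], X[valid, , drop = FALSE])
  cb_cols <- grep("^cb_", colnames(X))
  structure(list(
    city_id = city_id, age_group = age_group,
    coefficients = fit$coefficients, vcov = fit$vcov,
    dispersion = fit$dispersion, deviance = fit$deviance,
    df_residual = fit$df_residual,
    cb_cols = cb_cols, exposure = exposure, lag = lag, max_lag = max_lag,
    n_harmonics = n_harmonics,
    temp_range = range(temps$temp),
    temp_percentiles = pctl(temps$temp, c(0.01, 0.025, 0.975, 0.99)),
    mmt_window = pctl(temps$temp, mmt_window),
    dates = dates, y = deaths$deaths, fitted = {
      f <- rep(NA_real_, length(dates)); f[valid] <- fit$fitted; f
    },
    valid = valid, call = match.call()
  ), class = "tm_model")
}

#' Locate the minimum mortality temperature on a grid
#'
#' Argmin of the (uncentered) cumulative log relative risk restricted to a
#' search window of the fitting-period temperature distribution; ties are
#' broken toward the warmer temperature. A flat curve returns the window
#' midpoint with a warning.
#'
#' @param log_rr uncentered log RR evaluated on `grid`.
#' @param grid increasing temperature grid, degrees C.
#' @param window length-2 temperature bounds of the search window.
#' @return the MMT (a value of `grid`), with attribute `flat` if degenerate.
#' @export
find_mmt <- function(log_rr, grid, window) {
  sel <- which(grid >= window[1L] & grid <= window[2L])
  if (!length(sel)) stop("grid does not cover the MMT search window", call. = FALSE)
  v <- log_rr[sel]
  if (diff(range(v)) == 0) {
    warning("flat risk curve: MMT set to the window midpoint")
    mid <- sel[ceiling(length(sel) / 2)]
    return(structure(grid[mid], flat = TRUE))
  }
  ties <- sel[v == min(v)]
  grid[max(ties)]                # warmest among ties
}

#' Cumulative relative-risk curve of a fitted model
#'
#' Sums the fitted lag-response over lags 0..max_lag at each grid temperature,
#' locates the minimum mortality temperature (MMT) on the uncentered curve,
#' and centers so that RR at the MMT is exactly 1.
#'
#' @param model a [tm_fit()] object.
#' @param step grid step, degrees C.
#' @param grid optional explicit grid (must lie within 2 degrees C of the
#'   observed range); defaults to the observed range at `step` resolution.
#' @return object of class `rr_curve`: list(temp, rr, mmt, city_id, age_group).
#' @export
cumulative_rr <- function(model, step = 0.1, grid = NULL) {
  stopifnot(inherits(model, "tm_model"))
  rng <- model$temp_range
  if (is.null(grid)) {
    # snap outward to the step so every observed temperature is inside the grid
    grid <- seq(floor(rng[1L] / step) * step, ceiling(rng[2L] / step) * step,
                by = step)
  } else if (min(grid) < rng[1L] - 2 || max(grid) > rng[2L] + 2) {
    stop("grid must stay within 2 degrees C of the observed range", call. = FALSE)
  }
  log_rr <- crossbasis_logrr(model, grid)
  mmt <- find_mmt(log_rr, grid, model$mmt_window)
  centered <- log_rr - log_rr[which.min(abs(grid - mmt))]
  structure(list(temp = grid, rr = exp(centered), mmt = as.numeric(mmt),
                 flat = isTRUE(attr(mmt, "flat")),
                 city_id = model$city_id, age_group = model$age_group),
            class = "rr_curve")
}

# uncentered cumulative log RR at temperatures t: sum over lags of the
# cross-basis contribution, which reduces to B_exp(t) %*% (rowsum over lag
# basis of the coefficient matrix).
crossbasis_logrr <- function(model, t) {
  be <- ns_basis(t, model$exposure$knots, model$exposure$boundary, intercept = FALSE)
  bl <- ns_basis(0:model$max_lag, model$lag$knots, model$lag$boundary, intercept = TRUE)
  beta <- model$coefficients[model$cb_cols]
  J <- ncol(be); K <- ncol(bl)
  bmat <- matrix(beta, nrow = J, ncol = K, byrow = TRUE)  # (j, k) with k fastest
  as.numeric(be %*% (bmat %*% colSums(bl)))
}

#' Interpolate a relative-risk curve at arbitrary temperatures
#'
#' Linear interpolation of RR between grid points; beyond the grid the log RR
#' is extrapolated linearly from the end slope, with a warning.
#' @param curve an `rr_curve`.
#' @param temp temperatures, degrees C.
#' @return RR values.
#' @export
rr_at <- function(curve, temp) {
  g <- curve$temp; r <- curve$rr
  out <- stats::approx(g, r, xout = temp, rule = 1)$y
  lo <- temp < g[1L]; hi <- temp > g[length(g)]
  if (any(lo) || any(hi)) {
    warning(sprintf("%d temperature(s) beyond the RR grid: extrapolating log RR linearly",
                    sum(lo) + sum(hi)))
    lr <- log(r)
    n <- length(g)
    if (any(lo)) {
      s <- (lr[2L] - lr[1L]) / (g[2L] - g[1L])
      out[lo] <- exp(lr[1L] + s * (temp[lo] - g[1L]))
    }
    if (any(hi)) {
      s <- (lr[n] - lr[n - 1L]) / (g[n] - g[n - 1L])
      out[hi] <- exp(lr[n] + s * (temp[hi] - g[n]))
    }
  }
  out
}

# ---- S3 methods -------------------------------------------------------------

#' @export
print.tm_model <- function(x, ...) {
  cat("Temperature-mortality DLNM (quasi-Poisson)\n")
  if (!is.null(x$city_id)) cat("  city:", x$city_id,
                               if (!is.null(x$age_group)) paste0("(", x$age_group, ")"), "\n")
  cat(sprintf("  %d days fitted (lags 0..%d excluded at start), %d coefficients\n",
              length(x$valid), x$max_lag, length(x$coefficients)))
  cat(sprintf("  dispersion %.3f, residual deviance %.1f on %d df\n",
              x$dispersion, x$deviance, x$df_residual))
  invisible(x)
}

#' @export
coef.tm_model <- function(object, ...) object$coefficients

#' @export
vcov.tm_model <- function(object, ...) object$vcov

#' @export
summary.tm_model <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  tab <- cbind(Estimate = object$coefficients, `Std. Error` = se,
               `t value` = object$coefficients / se)
  curve <- cumulative_rr(object)
  out <- list(coefficients = tab, dispersion = object$dispersion,
              mmt = curve$mmt,
              rr_p975 = rr_at(curve, object$temp_percentiles[3L]),
              rr_p025 = rr_at(curve, object$temp_percentiles[2L]),
              city_id = object$city_id, age_group = object$age_group)
  class(out) <- "summary.tm_model"
  out
}

#' @export
print.summary.tm_model <- function(x, ...) {
  cat("Temperature-mortality DLNM (quasi-Poisson)\n")
  if (!is.null(x$city_id)) cat("  city:", x$city_id,
                               if (!is.null(x$age_group)) paste0("(", x$age_group, ")"), "\n")
  cat(sprintf("  dispersion %.3f | MMT %.1f C | RR at 97.5th pct %.3f | RR at 2.5th pct %.3f\n",
              x$dispersion, x$mmt, x$rr_p975, x$rr_p025))
  cat("\nCross-basis coefficients:\n")
  stats::printCoefmat(x$coefficients[grep("^cb_", rownames(x$coefficients)), , drop = FALSE])
  invisible(x)
}

#' Predict from a fitted temperature-mortality model
#'
#' `type = "rr"` returns the cumulative relative risk at the supplied
#' temperatures (curve interpolation); `type = "response"` returns expected
#' daily deaths for a `data.frame(date, temp)` of new data, using the model's
#' confounder structure.
#' @param object a `tm_model`.
#' @param newdata temperatures (numeric) for `type = "rr"`; `data.frame(date,
#'   temp)` for `type = "response"`.
#' @param type "rr" or "response".
#' @param ... unused.
#' @export
predict.tm_model <- function(object, newdata, type = c("rr", "response"), ...) {
  type <- match.arg(type)
  if (type == "rr") {
    temp <- if (is.data.frame(newdata)) newdata$temp else newdata
    return(rr_at(cumulative_rr(object), temp))
  }
  cb <- cross_basis(newdata$temp, object$exposure, object$lag, object$max_lag)
  conf <- confounder_matrix(as.Date(newdata$date), object$n_harmonics)
  X <- cbind(`(Intercept)` = 1, cb, conf)
  eta <- as.numeric(X %*% object$coefficients)
  out <- exp(eta)
  out[seq_len(attr(cb, "valid_from") - 1L)] <- NA_real_
  out
}

#' @export
residuals.tm_model <- function(object, type = c("pearson", "deviance", "response"), ...) {
  type <- match.arg(type)
  y <- object$y[object$valid]
  mu <- object$fitted[object$valid]
  switch(type,
         pearson = (y - mu) / sqrt(mu),
         response = y - mu,
         deviance = {
           d <- 2 * (ifelse(y > 0, y * log(y / mu), 0) - (y - mu))
           sign(y - mu) * sqrt(pmax(d, 0))
         })
}

#' Simulate daily death counts from a fitted model
#'
#' Draws counts at the fitted means with variance `dispersion * mean`
#' (negative binomial; Poisson when the estimated dispersion is <= 1).
#' @param object a `tm_model`.
#' @param nsim number of replicate series.
#' @param seed integer seed.
#' @param ... unused.
#' @export
simulate.tm_model <- function(object, nsim = 1, seed = 1, ...) {
  mu <- object$fitted[object$valid]
  phi <- object$dispersion
  with_seed(seed, {
    replicate(nsim, if (phi <= 1) stats::rpois(length(mu), mu)
              else stats::rnbinom(length(mu), size = mu / (phi - 1), mu = mu),
              simplify = FALSE)
  })
}

#' Plot the cumulative relative-risk curve of a fit
#' @param x a `tm_model`.
#' @param ... passed to `plot.rr_curve`.
#' @export
plot.tm_model <- function(x, ...) plot(cumulative_rr(x), ...)

#' @export
print.rr_curve <- function(x, ...) {
  cat(sprintf("Cumulative RR curve%s: %d grid points over [%.1f, %.1f] C, MMT %.1f C\n",
              if (!is.null(x$city_id)) paste0(" [", x$city_id,
                if (!is.null(x$age_group)) paste0("/", x$age_group), "]") else "",
              length(x$temp), min(x$temp), max(x$temp), x$mmt))
  cat(sprintf("  RR range %.3f .. %.3f\n", min(x$rr), max(x$rr)))
  invisible(x)
}

#' @export
plot.rr_curve <- function(x, ...) {
  graphics::plot(x$temp, x$rr, type = "l", xlab = "temperature (°C)",
                 ylab = "cumulative RR", ...)
  graphics::abline(h = 1, lty = 3)
  graphics::abline(v = x$mmt, col = "grey50", lty = 2)
  invisible(x)
}
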