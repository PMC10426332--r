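# Shared fixtures, built in code.

# mid-latitude reference city used across recovery tests
ref_city_spec <- function(warming_per_year = 0) {
  city_climate_spec("ref", latitude = 41, mean_temp = 14, seasonal_amplitude = 10,
                    ar1_coef = 0.7, noise_sd = 3, warming_per_year = warming_per_year)
}

ref_surface <- function(hot = 0.03, cold = 0.008) rr_surface(23, hot, cold)

# an rr_curve built directly from a ground-truth surface (no fitting)
true_curve <- function(surface, lo = surface$mmt - 30, hi = surface$mmt + 15,
                       city_id = "ref", age_group = "under75") {
  grid <- seq(lo, hi, by = 0.1)
  structure(list(temp = grid, rr = surface_rr(surface, grid), mmt = surface$mmt,
                 flat = FALSE, city_id = city_id, age_group = age_group),
            class = "rr_curve")
}

# tiny multi-city CSV study on disk; returns the input directory
write_small_study <- function(dir = tempfile("study"), n_cities = 3,
                              start_year = 1997, end_year = 2000, seed = 42) {
  ens <- sim_city_ensemble(n_cities, seed = seed)
  write_synthetic_inputs(ens, dir, start_year, end_year, seed = seed)
  list(dir = dir, ensemble = ens)
}

# independent Newton-Raphson Poisson ML solver (oracle for the IRLS fitter)
newton_poisson <- function(y, X, tol = 1e-12, maxit = 200) {
  beta <- rep(0, ncol(X))
  beta[1] <- log(mean(y) + 0.1)
  for (i in seq_len(maxit)) {
    mu <- as.numeric(exp(X %*% beta))
    grad <- crossprod(X, y - mu)
    hess <- crossprod(X, X * mu)
    step <- solve(hess, grad)
    beta <- beta + step
    if (max(abs(step)) < tol) break
  }
  as.numeric(beta)
}
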