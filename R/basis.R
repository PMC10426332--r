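#' Natural cubic spline basis
#'
#' Evaluates a natural cubic spline basis (C2 inside the boundary knots,
#' linear beyond them) at arbitrary points. A fixed knot specification makes
#' the basis a pointwise function of x, so the same value always maps to the
#' same row regardless of the other entries.
#'
#' @param x numeric vector of evaluation points (finite).
#' @param knots internal knots, strictly increasing and strictly inside the
#'   boundary knots.
#' @param boundary length-2 boundary knots.
#' @param intercept logical; include the constant column (used for the lag
#'   basis so that lag 0 carries risk).
#' @return matrix with `length(knots) + 1 + intercept` columns.
#' @export
ns_basis <- function(x, knots, boundary, intercept = FALSE) {
  stop_if_not_finite(x, "x")
  stop_if_not_finite(boundary, "boundary")
  if (length(boundary) != 2L || boundary[1L] >= boundary[2L]) {
    stop("'boundary' must be two increasing values", call. = FALSE)
  }
  if (length(knots)) {
    stop_if_not_finite(knots, "knots")
    if (is.unsorted(knots, strictly = TRUE)) {
      stop("internal knots must be strictly increasing", call. = FALSE)
    }
    if (min(knots) <= boundary[1L] || max(knots) >= boundary[2L]) {
      stop("internal knots must lie strictly inside the boundary knots", call. = FALSE)
    }
  }
  m <- splines::ns(x, knots = if (length(knots)) knots else NULL,
                   Boundary.knots = boundary, intercept = intercept)
  m <- unclass(m)
  attributes(m)[c("knots", "Boundary.knots", "intercept", "degree")] <- NULL
  dimnames(m) <- list(NULL, paste0("b", seq_len(ncol(m))))
  m
}

#' Default knot placement for the exposure and lag dimensions
#'
#' Exposure: internal knots at the 10th/75th/90th percentiles of the fitting
#' temperatures, boundary at the observed min/max (standard DLNM practice for
#' temperature). Lag: 2 internal knots equally spaced on the log(lag+1) scale
#' over lags 0..max_lag, with an intercept.
#' @param temp fitting-period temperatures.
#' @param probs percentile positions of the exposure knots.
#' @return list(knots, boundary).
#' @export
exposure_knots <- function(temp, probs = c(0.10, 0.75, 0.90)) {
  list(knots = pctl(temp, probs), boundary = range(temp))
}

#' @rdname exposure_knots
#' @param max_lag maximum lag in days.
#' @param n_knots number of internal lag knots.
#' @export
lag_knots <- function(max_lag = 21, n_knots = 2) {
  lk <- exp(seq(0, log(max_lag + 1), length.out = n_knots + 2)) - 1
  list(knots = lk[-c(1L, n_knots + 2L)], boundary = c(0, max_lag))
}

#' Build the DLNM cross-basis of a temperature series
#'
#' The cross-basis is the day-by-(exposure basis x lag basis) design matrix of
#' a distributed-lag non-linear model: entry for day d and column (j, k) is
#' `sum_{l=0}^{max_lag} B_exp_j(T[d-l]) * B_lag_k(l)`. Rows with incomplete
#' lag history (the first `max_lag` days) are computed with the available
#' leading values but flagged unusable via the `valid_from` attribute; the
#' fitter excludes them from the likelihood.
#'
#' @param temp numeric daily temperature vector (no missing values) or a
#'   `data.frame(date, temp)`.
#' @param exposure list(knots, boundary) for the exposure dimension, e.g.
#'   [exposure_knots()].
#' @param lag list(knots, boundary) for the lag dimension, e.g. [lag_knots()].
#' @param max_lag maximum lag in days.
#' @return matrix of class `cross_basis` with attributes `exposure`, `lag`,
#'   `max_lag`, `valid_from` (first 1-based row with full history).
#' @export
cross_basis <- function(temp, exposure, lag = lag_knots(max_lag), max_lag = 21) {
  if (is.data.frame(temp)) {
    if (anyNA(temp$temp)) {
      bad <- temp$date[is.na(temp$temp)]
      stop("missing temperatures on: ", paste(utils::head(format(bad), 5L), collapse = ", "),
           call. = FALSE)
    }
    temp <- temp$temp
  }
  stop_if_not_finite(temp, "temp")
  n <- length(temp)
  if (n <= max_lag) stop("series length must exceed 'max_lag'", call. = FALSE)
  be <- ns_basis(temp, exposure$knots, exposure$boundary, intercept = FALSE)
  bl <- ns_basis(0:max_lag, lag$knots, lag$boundary, intercept = TRUE)
  J <- ncol(be); K <- ncol(bl)
  out <- matrix(0, n, J * K)
  for (l in 0:max_lag) {
    rows <- (l + 1L):n
    contrib <- be[rows - l, , drop = FALSE]        # B_exp(T[d-l])
    for (k in seq_len(K)) {
      cols <- (seq_len(J) - 1L) * K + k            # column (j, k)
      out[rows, cols] <- out[rows, cols] + contrib * bl[l + 1L, k]
    }
  }
  colnames(out) <- paste0("cb_", rep(seq_len(J), each = K), "_", rep(seq_len(K), J))
  structure(out, exposure = exposure, lag = lag, max_lag = as.integer(max_lag),
            valid_from = as.integer(max_lag) + 1L,
            class = c("cross_basis", "matrix", "array"))
}
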