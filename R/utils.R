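# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves any existing `.Random.seed`, seeds the generator, evaluates `expr`,
#' and restores the previous state, so generators take an explicit seed and
#' leave no global RNG footprint.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("'seed' must be a single finite integer", call. = FALSE)
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# quantile with the (n-1)-based linear-interpolation convention used for all
# knots, MMT windows and extreme thresholds in this package (= type 7).
pctl <- function(x, probs) {
  unname(stats::quantile(x, probs = probs, type = 7, names = FALSE))
}

stop_if_not_finite <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop(sprintf("'%s' must be finite and numeric", name), call. = FALSE)
  }
  invisible(x)
}

# daily date sequence checks
check_daily_dates <- function(dates, what = "dates") {
  if (!inherits(dates, "Date")) stop(sprintf("'%s' must be of class Date", what), call. = FALSE)
  if (anyDuplicated(dates)) stop(sprintf("duplicated %s are not allowed", what), call. = FALSE)
  d <- diff(as.integer(dates))
  if (length(d) && any(d != 1L)) {
    gaps <- dates[which(d != 1L)]
    stop(sprintf("%s must be contiguous daily values; gaps after: %s",
                 what, paste(utils::head(format(gaps), 5L), collapse = ", ")), call. = FALSE)
  }
  invisible(dates)
}

year_of <- function(dates) as.integer(format(dates, "%Y"))
month_of <- function(dates) as.integer(format(dates, "%m"))
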