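#' Normalize consultation counts by enrollment
#'
#' Converts monthly visit counts into the percentage of enrolled students who
#' sought a consultation that month: `100 * visits / enrollment`.
#'
#' @param visits Nonnegative monthly visit counts.
#' @param enrollment Positive monthly enrollment (recycled if scalar).
#' @param months `"YYYY-MM"` labels for the series.
#' @return A `monthly_series` of kind `rate_percent`.
#' @export
normalize_consultations <- function(visits, enrollment, months) {
  enrollment <- rep_len(enrollment, length(visits))
  if (any(enrollment <= 0)) stop("enrollment must be positive")
  if (any(visits < 0)) stop("visits must be nonnegative")
  monthly_series(months, 100 * visits / enrollment, "rate_percent")
}

# Dickey-Fuller distribution (trend case), interpolated over sample size and
# statistic; classical tabulated quantiles for T = 25,50,100,250,500,Inf at
# the probabilities in adf_tablep.
adf_table <- -matrix(c(
  4.38, 4.15, 4.04, 3.99, 3.98, 3.96,
  3.95, 3.80, 3.73, 3.69, 3.68, 3.66,
  3.60, 3.50, 3.45, 3.43, 3.42, 3.41,
  3.24, 3.18, 3.15, 3.13, 3.13, 3.12,
  1.14, 1.19, 1.22, 1.23, 1.24, 1.25,
  0.80, 0.87, 0.90, 0.92, 0.93, 0.94,
  0.50, 0.58, 0.62, 0.64, 0.65, 0.66,
  0.15, 0.24, 0.28, 0.31, 0.32, 0.33), nrow = 6L)
adf_tablen <- c(25, 50, 100, 250, 500, 1e9)
adf_tablep <- c(0.01, 0.025, 0.05, 0.10, 0.90, 0.95, 0.975, 0.99)

#' Augmented Dickey-Fuller stationarity test
#'
#' Unit-root test with constant and linear trend. The number of lagged
#' differences is selected by AIC up to `floor((n - 1)^(1/3))`, all candidate
#' regressions being fit on the common largest-lag sample. The p-value is
#' interpolated from the tabulated Dickey-Fuller distribution and clamped to
#' `[0.01, 0.99]`. A constant series is reported as non-stationary with a
#' `degenerate` flag rather than an error.
#'
#' @param x A `monthly_series` or numeric vector (no missing values).
#' @param alpha Significance level for the `stationary` verdict.
#' @return An `adf_report`: `statistic`, `p_value`, `stationary`,
#'   `lag_order`, `degenerate`.
#' @export
adf_test <- function(x, alpha = 0.05) {
  if (inherits(x, "monthly_series")) x <- x$value
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains missing values")
  n <- length(x)
  if (n < 24L) stop("series too short for the stationarity test (need >= 24)")
  if (stats::sd(x) == 0) {
    return(structure(list(statistic = NA_real_, p_value = 1,
                          stationary = FALSE, lag_order = 0L,
                          degenerate = TRUE), class = "adf_report"))
  }
  kmax <- max(0L, floor((n - 1)^(1 / 3)))
  dx <- diff(x)
  # common sample across lag orders so AIC values are comparable
  start <- kmax + 1L
  tt <- seq.int(start, n - 1L)
  y <- dx[tt]
  fits <- lapply(0:kmax, function(k) {
    X <- cbind(ylag = x[tt], trend = tt)
    if (k > 0L)
      X <- cbind(X, vapply(seq_len(k), function(j) dx[tt - j],
                           numeric(length(tt))))
    stats::lm(y ~ X)
  })
  k <- which.min(vapply(fits, stats::AIC, 0)) - 1L
  fit <- fits[[k + 1L]]
  stat <- summary(fit)$coefficients["Xylag", "t value"]
  row <- vapply(seq_along(adf_tablep), function(j)
    stats::approx(adf_tablen, adf_table[, j], n, rule = 2)$y, 0)
  p <- stats::approx(row, adf_tablep, stat, rule = 2)$y
  structure(list(statistic = unname(stat), p_value = p,
                 stationary = p < alpha, lag_order = k, degenerate = FALSE),
            class = "adf_report")
}

#' @exportS3Method base::print
print.adf_report <- function(x, ...) {
  cat(sprintf("ADF test: statistic %.3f, lag order %d, p %s %.3f -> %s\n",
              x$statistic, x$lag_order,
              if (x$p_value %in% c(0.01, 0.99)) "~" else "=", x$p_value,
              if (x$stationary) "stationary" else "non-stationary"))
  invisible(x)
}

#' Moving-window trend and seasonality decomposition
#'
#' Classical additive decomposition: trend is a centered moving average of
#' width `window` (the conventional 2 x m average when `window` is even);
#' the seasonal component is the per-month-of-year mean of detrended values
#' on the interior (where the moving average is defined), re-centered to sum
#' to zero over the 12 months; the residual is the remainder, so
#' trend + seasonal + residual reconstructs the input exactly. Edge trend
#' values are filled with the nearest interior estimate rather than
#' discarded, keeping short series usable.
#'
#' @param series A `monthly_series` (gap-free, no missing values).
#' @param window Moving-average width in months (>= 2; default 12, one
#'   academic year).
#' @return A `series_decomposition`: `trend`, `seasonal`, `residual`
#'   (numeric), `residual_series` (a `monthly_series`), `interior` (logical
#'   mask of months with a genuine trend estimate), `window`.
#' @export
decompose_series <- function(series, window = 12L) {
  stopifnot(inherits(series, "monthly_series"))
  if (window < 2L) stop("window must be >= 2")
  x <- series$value
  n <- length(x)
  if (anyNA(x)) stop("decompose requires a complete series; see fill_month_gaps()")
  if (n < 2L * window) stop("series must be at least twice the window")
  if (window %% 2L == 0L) {
    w <- c(0.5, rep(1, window - 1L), 0.5) / window
  } else {
    w <- rep(1 / window, window)
  }
  trend <- as.numeric(stats::filter(x, w, sides = 2))
  interior <- !is.na(trend)
  first <- which(interior)[1L]
  last <- rev(which(interior))[1L]
  trend[seq_len(first - 1L)] <- trend[first]
  if (last < n) trend[(last + 1L):n] <- trend[last]
  detr <- x - trend
  moy <- month_of_year(series$month)
  seas12 <- rep(0, 12L)
  means <- tapply(detr[interior], moy[interior], mean)
  seas12[as.integer(names(means))] <- means
  seas12 <- seas12 - mean(seas12)
  seasonal <- seas12[moy]
  residual <- x - trend - seasonal
  structure(list(trend = trend, seasonal = seasonal, residual = residual,
                 residual_series = monthly_series(series$month, residual,
                                                  "residual"),
                 interior = interior, window = as.integer(window),
                 months = series$month),
            class = "series_decomposition")
}

#' Residualize a monthly series
#'
#' Removes moving-window trend and period-12 seasonality
#' ([decompose_series()]) and verifies stationarity of the remainder with
#' [adf_test()]; a warning (not an error) is raised when the residual still
#' fails the test at `alpha`. The ADF report is attached as attribute
#' `"adf"`.
#'
#' @inheritParams decompose_series
#' @param alpha Stationarity significance level.
#' @return A `monthly_series` of kind `residual`.
#' @export
residualize <- function(series, window = 12L, alpha = 0.05) {
  dec <- decompose_series(series, window)
  res <- dec$residual_series
  rpt <- adf_test(res, alpha)
  if (!rpt$stationary)
    warning(sprintf(
      "residual series still fails the stationarity test (ADF p = %.3f)",
      rpt$p_value))
  attr(res, "adf") <- rpt
  res
}

#' Lagged, controlled association between two residual series
#'
#' Ordinary least squares of the consultation residual at month `t` on the
#' expression residual at `t - lag`, controlling for the previous month's
#' consultation residual and expression residual. All variables are
#' standardized on the aligned sample, so the reported `e` is a standardized
#' coefficient comparable across outcomes. A lag of `n` months means the
#' social-media series is shifted `n` months behind the ground truth. At
#' `lag = 1` the expression control duplicates the predictor and is dropped.
#'
#' @param visits_resid,expr_resid Residual `monthly_series` sharing months.
#' @param lag Nonnegative lag in months.
#' @param controls Include the previous-month controls (default TRUE).
#' @return A `lag_association`: `lag`, `e` (standardized coefficient of the
#'   lagged expression residual), `p_value`, `n` (months used).
#' @export
lagged_association <- function(visits_resid, expr_resid, lag = 0L,
                               controls = TRUE) {
  if (lag < 0L) stop("lag must be nonnegative")
  al <- align_series(visits_resid, expr_resid)
  v <- al$a; x <- al$b
  n <- length(v)
  t0 <- max(lag, 1L) + 1L
  if (n - t0 + 1L < 12L) stop("insufficient overlap after shifting (< 12 months)")
  tt <- seq.int(t0, n)
  std <- function(z, what) {
    if (stats::sd(z) == 0) stop(sprintf("zero-variance regressor: %s", what))
    as.numeric(scale(z))
  }
  y <- std(v[tt], "visits")
  x1 <- std(x[tt - lag], "lagged expressions")
  if (controls) {
    dat <- data.frame(y = y, x1 = x1, prev_visits = std(v[tt - 1L],
                                                        "previous visits"))
    if (lag != 1L) dat$prev_expr <- std(x[tt - 1L], "previous expressions")
  } else {
    dat <- data.frame(y = y, x1 = x1)
  }
  fit <- stats::lm(y ~ . - 1, data = dat)
  co <- summary(fit)$coefficients
  e <- unname(co["x1", "Estimate"])
  p <- unname(co["x1", "Pr(>|t|)"])
  # a numerically perfect fit has zero residual variance and an undefined t;
  # report it as an exact association
  if (!is.finite(p)) p <- if (abs(e) > 0) 0 else 1
  structure(list(lag = as.integer(lag), e = e,
                 p_value = p, n = length(tt),
                 controls = controls),
            class = "lag_association")
}

#' Scan lagged associations over a range of lags
#'
#' @inheritParams lagged_association
#' @param max_lag Largest lag scanned (default 6).
#' @return A `lag_scan` data frame with columns `lag`, `e`, `p_value`, `n`.
#' @export
lag_scan <- function(visits_resid, expr_resid, max_lag = 6L, controls = TRUE) {
  rows <- lapply(0:max_lag, function(l)
    lagged_association(visits_resid, expr_resid, l, controls))
  out <- data.frame(lag = vapply(rows, `[[`, 0L, "lag"),
                    e = vapply(rows, `[[`, 0, "e"),
                    p_value = vapply(rows, `[[`, 0, "p_value"),
                    n = vapply(rows, `[[`, 0L, "n"))
  class(out) <- c("lag_scan", "data.frame")
  out
}

#' @export
plot.lag_scan <- function(x, ...) {
  graphics::plot(x$lag, x$e, type = "b", pch = 19,
                 xlab = "lag (months, social media behind ground truth)",
                 ylab = "standardized coefficient e", ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}
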