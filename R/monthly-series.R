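#' Monthly time-series container
#'
#' A light container for month-indexed real-valued series: a data frame with
#' columns `month` (`"YYYY-MM"` strings, strictly increasing and gap-free) and
#' `value`, carrying a `kind` attribute that records what the values are
#' (`"rate_percent"` for normalized consultation rates, `"prevalence"` for
#' monthly expression prevalence, `"residual"` after trend/seasonality
#' removal).
#'
#' @param months Character vector of `"YYYY-MM"` labels.
#' @param values Numeric values, one per month. `NA` marks a missing month
#'   (e.g. a month with zero posts) to be filled with [fill_month_gaps()].
#' @param kind One of `"rate_percent"`, `"prevalence"`, `"residual"`,
#'   `"other"`.
#' @return An object of class `monthly_series` (a data frame).
#' @examples
#' monthly_series(c("2011-05", "2011-06"), c(1.2, 1.4), "rate_percent")
#' @export
monthly_series <- function(months, values,
                           kind = c("other", "rate_percent", "prevalence",
                                    "residual")) {
  kind <- match.arg(kind)
  months <- as.character(months)
  if (length(months) != length(values))
    stop("months and values must have the same length")
  if (!all(grepl("^\\d{4}-\\d{2}$", months)))
    stop("months must be 'YYYY-MM' strings")
  idx <- month_number(months)
  if (length(idx) > 1L) {
    if (any(diff(idx) <= 0L)) stop("month index must be strictly increasing")
    if (any(diff(idx) > 1L))
      stop("month index has gaps; ingest through fill_month_gaps()")
  }
  structure(data.frame(month = months, value = as.numeric(values),
                       stringsAsFactors = FALSE),
            kind = kind, class = c("monthly_series", "data.frame"))
}

#' @exportS3Method base::print
print.monthly_series <- function(x, ...) {
  cat(sprintf("<monthly_series[%s]> %d months (%s .. %s)\n",
              attr(x, "kind"), nrow(x), x$month[1L], x$month[nrow(x)]))
  print.data.frame(utils::head(as.data.frame(x), 6L), row.names = FALSE)
  if (nrow(x) > 6L) cat("...\n")
  invisible(x)
}

# month arithmetic on a flat integer index (year * 12 + month - 1)
month_number <- function(m) {
  as.integer(substr(m, 1L, 4L)) * 12L + as.integer(substr(m, 6L, 7L)) - 1L
}

month_label <- function(n) sprintf("%04d-%02d", n %/% 12L, n %% 12L + 1L)

#' Sequence of consecutive month labels
#'
#' @param start First month as `"YYYY-MM"`.
#' @param n Number of months.
#' @return Character vector of `n` consecutive `"YYYY-MM"` labels.
#' @export
month_seq <- function(start, n) month_label(month_number(start) + seq_len(n) - 1L)

month_of_year <- function(months) month_number(months) %% 12L + 1L

#' Fill gaps and missing values in a monthly series
#'
#' Completes the month index between the first and last observed month and
#' linearly interpolates missing values (months absent from the input or with
#' `NA` values). Leading/trailing missing values are filled with the nearest
#' observed value. A warning reports how many months were imputed; the spec
#' for downstream residualization requires a gap-free series.
#'
#' @param x A `monthly_series` or a data frame with `month` and `value`.
#' @return A gap-free `monthly_series` of the same kind.
#' @export
fill_month_gaps <- function(x) {
  kind <- attr(x, "kind")
  if (is.null(kind)) kind <- "other"
  idx <- month_number(x$month)
  full <- seq(min(idx), max(idx))
  v <- rep(NA_real_, length(full))
  v[match(idx, full)] <- x$value
  miss <- is.na(v)
  if (any(miss)) {
    warning(sprintf("imputing %d missing month(s) by linear interpolation",
                    sum(miss)))
    v <- stats::approx(full[!miss], v[!miss], xout = full, rule = 2)$y
  }
  monthly_series(month_label(full), v, kind)
}

#' @export
as.ts.monthly_series <- function(x, ...) {
  first <- month_number(x$month[1L])
  stats::ts(x$value, start = c(first %/% 12L, first %% 12L + 1L),
            frequency = 12)
}

# restrict two series to their common months, preserving order
align_series <- function(a, b) {
  common <- intersect(a$month, b$month)
  if (length(common) == 0L) stop("series share no months")
  list(months = common,
       a = a$value[match(common, a$month)],
       b = b$value[match(common, b$month)])
}
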