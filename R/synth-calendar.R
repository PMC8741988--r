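#' Academic-calendar seasonal profile
#'
#' Builds the deterministic scaffold the synthetic consultation and post
#' generators share: a period-12 seasonal load encoding academic-cycle stress
#' (peaks before the spring/summer/fall examination periods, troughs in the
#' winter, spring and fall holidays) plus a slow linear trend. The seasonal
#' pattern is centered so its mean over any 12 consecutive months is zero.
#' The first listed peak is the annual maximum (subsequent peaks are scaled
#' by 0.85, troughs analogously), so `which.max` within a year lands on
#' `peak_months[1]`. A small seeded jitter keeps the twelve month effects
#' distinct without disturbing that ordering.
#'
#' @param n_months Number of months (at least 24, two full seasonal cycles).
#' @param seed Integer seed; the profile is deterministic given it.
#' @param start First month, `"YYYY-MM"`.
#' @param peak_months Months of year (1-12) with elevated load; first entry
#'   is the annual peak. Defaults to April, July, November.
#' @param trough_months Months of year with depressed load. Defaults to
#'   December, February, October.
#' @param seasonal_amplitude Load of the main peak, in the same percentage
#'   points as the consultation rate.
#' @param trend_slope Linear trend increment per month (percentage points).
#' @return A `calendar_profile`: months, month_of_year, seasonal_load, trend.
#' @examples
#' cal <- make_calendar(36, seed = 7)
#' mean(cal$seasonal_load[1:12]) # ~0 by construction
#' @export
make_calendar <- function(n_months, seed = 1L, start = "2011-05",
                          peak_months = c(4L, 7L, 11L),
                          trough_months = c(12L, 2L, 10L),
                          seasonal_amplitude = 2, trend_slope = 0.02) {
  if (n_months < 24L) stop("insufficient history for seasonal modeling")
  stopifnot(length(peak_months) >= 1L, seasonal_amplitude >= 0)
  base12 <- numeric(12L)
  base12[peak_months] <- seasonal_amplitude *
    c(1, rep(0.85, length(peak_months) - 1L))
  base12[trough_months] <- -0.8 * seasonal_amplitude *
    c(1, rep(0.85, max(0L, length(trough_months) - 1L)))
  base12 <- base12 +
    withr::with_seed(seed, stats::rnorm(12L, 0, seasonal_amplitude / 40))
  base12 <- base12 - mean(base12)
  months <- month_seq(start, n_months)
  moy <- month_of_year(months)
  structure(list(n_months = as.integer(n_months), start = start,
                 months = months, month_of_year = moy,
                 seasonal_load = base12[moy],
                 trend = trend_slope * (seq_len(n_months) - 1L),
                 seed = as.integer(seed)),
            class = "calendar_profile")
}

#' @exportS3Method base::print
print.calendar_profile <- function(x, ...) {
  cat(sprintf("<calendar_profile> %d months from %s; peak load %.2f\n",
              x$n_months, x$start, max(x$seasonal_load)))
  invisible(x)
}
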