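#' Bimonthly calendar
#'
#' The pipeline's fixed temporal grid: six two-calendar-month periods per
#' year, period k covering months (2k-1, 2k). The 2000--2022 production
#' calendar has 23 x 6 = 138 periods.
#'
#' @param start_year,end_year inclusive year range.
#' @return a data.frame with columns `year`, `period` (1--6), `start`, `end`
#'   (Dates; `end` is the first day after the period, so membership is tested
#'   against the half-open interval `[start, end)`), classed
#'   `bimonthly_calendar`.
#' @examples
#' nrow(bimonthly_calendar(2000, 2022))  # 138
#' @export
bimonthly_calendar <- function(start_year, end_year) {
  stopifnot(end_year >= start_year)
  years <- seq.int(start_year, end_year)
  df <- expand.grid(period = 1:6, year = years)[, c("year", "period")]
  m0 <- 2L * df$period - 1L
  df$start <- as.Date(sprintf("%d-%02d-01", df$year, m0))
  nxt_y <- ifelse(df$period == 6L, df$year + 1L, df$year)
  nxt_m <- ifelse(df$period == 6L, 1L, m0 + 2L)
  df$end <- as.Date(sprintf("%d-%02d-01", nxt_y, nxt_m))
  class(df) <- c("bimonthly_calendar", "data.frame")
  df
}

#' Map dates to bimonthly periods
#'
#' @param dates a Date vector (or coercible).
#' @return data.frame with `year` and `period` per date.
#' @export
period_of_date <- function(dates) {
  dates <- as.Date(dates)
  lt <- as.POSIXlt(dates)
  data.frame(year = lt$year + 1900L, period = (lt$mon %/% 2L) + 1L)
}

period_key <- function(year, period) sprintf("%d_p%d", year, period)
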