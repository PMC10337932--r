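#' @title Idealised 365-day calendar
#' @description Time is carried as fractional hours since 00:00 on day 1 of
#'   year 1 of an idealised no-leap calendar (8760 h per year). This matches
#'   the 73 five-day departure slots per year of the voyage schedule and
#'   keeps seasonal phase identical across simulated years.
#' @name calendar
NULL

HOURS_PER_YEAR <- 365 * 24

#' Day of year from an hour stamp
#'
#' @param t_hours hours since the calendar origin.
#' @return day of year in `[1, 365]` (fractional days floor to the day).
#' @export
day_of_year <- function(t_hours) (floor(t_hours / 24) %% 365) + 1

#' Hour of day (UTC) from an hour stamp
#' @param t_hours hours since the calendar origin.
#' @return fractional hour in `[0, 24)`.
#' @export
hour_of_day <- function(t_hours) t_hours %% 24

#' Simulated year index (1-based) from an hour stamp
#' @param t_hours hours since the calendar origin.
#' @return integer year index.
#' @export
year_index <- function(t_hours) floor(t_hours / HOURS_PER_YEAR) + 1

# cumulative month ends in a 365-day year (Jan..Dec)
.month_ends <- cumsum(c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31))

#' Month number from a day of year
#' @param doy day of year, 1--365.
#' @return month 1--12.
#' @export
month_of_doy <- function(doy) {
  stopifnot(all(doy >= 1 & doy <= 365))
  findInterval(doy - 1, c(0, .month_ends)[-14]) |> pmin(12)
}

#' Meteorological season of a day of year
#'
#' Southern-hemisphere convention by default: DJF is summer, JJA winter.
#' Labels are the month triplets themselves so the convention is explicit.
#'
#' @param doy day of year, 1--365.
#' @return factor with levels DJF, MAM, JJA, SON.
#' @export
season_of_doy <- function(doy) {
  m <- month_of_doy(doy)
  s <- c("DJF", "DJF", "MAM", "MAM", "MAM", "JJA",
         "JJA", "JJA", "SON", "SON", "SON", "DJF")[m]
  factor(s, levels = c("DJF", "MAM", "JJA", "SON"))
}
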