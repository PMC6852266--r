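# Dates are stored as integer days since 2000-01-01 so that the 5-day
# flood-fill rule and time-since-last-fire arithmetic are exact across year
# boundaries and leap years.

.FR_EPOCH <- as.Date("2000-01-01")

#' Convert dates to integer days since 2000-01-01
#' @param date a `Date` vector (or something coercible via [as.Date()]).
#' @return integer vector of day numbers (2000-01-01 is day 0).
#' @export
day_from_date <- function(date) {
  as.integer(as.Date(date) - .FR_EPOCH)
}

#' Convert integer day numbers back to dates
#' @param day integer days since 2000-01-01.
#' @return a `Date` vector.
#' @export
date_from_day <- function(day) {
  .FR_EPOCH + day
}

#' Calendar year of a day number
#' @param day integer days since 2000-01-01.
#' @export
calendar_year_of <- function(day) {
  as.integer(format(date_from_day(day), "%Y"))
}

#' Calendar month of a day number
#' @param day integer days since 2000-01-01.
#' @export
month_of <- function(day) {
  as.integer(format(date_from_day(day), "%m"))
}

#' Zero-based day of year
#'
#' January 1st maps to 0; December 31st maps to 364 (365 in leap years).
#'
#' @param day integer days since 2000-01-01.
#' @return integer in 0..365.
#' @export
day_of_year0 <- function(day) {
  as.POSIXlt(date_from_day(day))$yday
}

#' Rainfall year of a date
#'
#' A rainfall year runs from October (the onset of the short rains) through
#' the following September, and is labelled by the calendar year in which it
#' ends: October 2005 through September 2006 is rainfall year 2006.
#'
#' @param date a `Date` vector or integer day numbers (days since 2000-01-01).
#' @return integer rainfall-year labels.
#' @export
rainfall_year <- function(date) {
  if (is.numeric(date)) date <- date_from_day(date)
  date <- as.Date(date)
  y <- as.integer(format(date, "%Y"))
  m <- as.integer(format(date, "%m"))
  ifelse(m >= 10L, y + 1L, y)
}

#' First day of a rainfall year
#' @param label integer rainfall-year label.
#' @return integer day number of October 1st of `label - 1`.
#' @export
rainfall_year_start <- function(label) {
  day_from_date(as.Date(sprintf("%d-10-01", label - 1L)))
}

# (year, month) pairs from one month to another, inclusive, chronological
month_seq <- function(year_from, month_from, year_to, month_to) {
  a <- year_from * 12L + (month_from - 1L)
  b <- year_to * 12L + (month_to - 1L)
  if (b < a) return(data.frame(year = integer(), month = integer()))
  k <- a:b
  data.frame(year = k %/% 12L, month = k %% 12L + 1L)
}
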