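#' Season-day time scale
#'
#' Harvest campaigns span the calendar year boundary (observations run from
#' early October into December or January), so all within-season arithmetic is
#' done on a "season day" scale: days elapsed since July 1 of the season year.
#' On this scale October 1 is day 92 and January 5 of the following calendar
#' year is day 188, and ordered calendar dates always map to strictly
#' increasing values.
#'
#' @param date a `Date` vector (or string coercible with [as.Date()]).
#' @param season_year integer season label; the season covers July 1 of
#'   `season_year` through June 30 of `season_year + 1`.
#' @return `season_day()`: numeric days since July 1 of the season year.
#'   `season_date()`: the `Date` corresponding to a (possibly fractional)
#'   season day, rounded to the nearest calendar day.
#' @examples
#' season_day(as.Date("2014-10-01"), 2014) # 92
#' season_date(188, 2013)                  # "2014-01-05"
#' @export
season_day <- function(date, season_year) {
  date <- as.Date(date)
  origin <- as.Date(sprintf("%d-07-01", season_year))
  d <- as.numeric(date - origin)
  bad <- !is.na(d) & (d < 0 | d >= as.numeric(as.Date(sprintf("%d-07-01", season_year + 1)) - origin))
  if (any(bad)) {
    stop(sprintf(
      "date(s) %s outside season %d (July 1 %d .. June 30 %d)",
      paste(format(date[bad]), collapse = ", "), season_year[1],
      season_year[1], season_year[1] + 1
    ), call. = FALSE)
  }
  d
}

#' @rdname season_day
#' @param day numeric season day (days since July 1 of `season_year`).
#' @export
season_date <- function(day, season_year) {
  as.Date(sprintf("%d-07-01", season_year)) + round(day)
}
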