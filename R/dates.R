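#' Calendar-month arithmetic with day-of-month clamping
#'
#' Adds whole calendar months to a date; when the target month is shorter than
#' the source day-of-month, the day is clamped to the last day of the target
#' month (e.g. Jan 31 + 1 month = Feb 28/29). All schedule windows in the
#' adherence rubric ("12 +/- 3 months", "+/- 2 months of treatment completion")
#' use this convention, at day resolution with no time-of-day component.
#'
#' @param date a `Date` vector (or scalar).
#' @param n integer vector of months to add (may be negative). `date` and `n`
#'   are recycled to a common length.
#' @return a `Date` vector.
#' @examples
#' add_months(as.Date("2020-06-15"), c(-3, 9, 15))
#' add_months(as.Date("2020-01-31"), 1) # clamped to Feb 29
#' @export
add_months <- function(date, n) {
  stopifnot(inherits(date, "Date"))
  n <- as.numeric(n)
  len <- max(length(date), length(n))
  if (length(date) < len) date <- rep_len(date, len)
  if (length(n) < len) n <- rep_len(n, len)
  cv <- civil_from_days(floor(as.numeric(date)))
  tot <- cv$y * 12 + (cv$m - 1) + n
  y <- tot %/% 12
  m <- tot %% 12 + 1
  d <- pmin(cv$d, days_in_month(y, m))
  structure(days_from_civil(y, m, d), class = "Date")
}

# days-since-epoch <-> proleptic Gregorian (y, m, d); pure floor-division
# arithmetic, no POSIXlt, so the scoring hot path stays cheap
civil_from_days <- function(z) {
  z <- z + 719468
  era <- z %/% 146097
  doe <- z - era * 146097
  yoe <- (doe - doe %/% 1460 + doe %/% 36524 - doe %/% 146096) %/% 365
  y <- yoe + era * 400
  doy <- doe - (365 * yoe + yoe %/% 4 - yoe %/% 100)
  mp <- (5 * doy + 2) %/% 153
  d <- doy - (153 * mp + 2) %/% 5 + 1
  m <- mp + ifelse(mp < 10, 3, -9)
  list(y = y + (m <= 2), m = m, d = d)
}

days_from_civil <- function(y, m, d) {
  y <- y - (m <= 2)
  era <- y %/% 400
  yoe <- y - era * 400
  mp <- m + ifelse(m > 2, -3, 9)
  doy <- (153 * mp + 2) %/% 5 + d - 1
  doe <- yoe * 365 + yoe %/% 4 - yoe %/% 100 + doy
  era * 146097 + doe - 719468
}

days_in_month <- function(year, month) {
  dm <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  out <- dm[month]
  leap <- (year %% 4 == 0 & year %% 100 != 0) | year %% 400 == 0
  out[month == 2 & leap] <- 29L
  out
}

# Strict ISO-8601 (YYYY-MM-DD) parser; returns NA for anything else,
# including syntactically valid strings naming impossible dates.
parse_iso_date <- function(x) {
  x <- as.character(x)
  out <- rep(as.Date(NA), length(x))
  ok <- !is.na(x) & grepl("^\\d{4}-\\d{2}-\\d{2}$", x)
  if (any(ok)) {
    d <- as.Date(x[ok], format = "%Y-%m-%d")
    # as.Date() maps "2021-02-31" to NA already; keep only real round-trips
    good <- !is.na(d) & format(d, "%Y-%m-%d") == x[ok]
    d[!good] <- NA
    out[ok] <- d
  }
  out
}
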