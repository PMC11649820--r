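`%||%` <- function(a, b) if (is.null(a)) b else a

#' Parse ISO-8601 date-times at minute resolution
#'
#' Accepts `YYYY-MM-DDTHH:MM[:SS]`, the space-separated equivalent, or a bare
#' date (midnight assumed). Unparseable entries yield `NA`. All times are
#' treated as clock times in a single zone (UTC internally); the registry is
#' single-country so no zone arithmetic is performed. Seconds are truncated.
#'
#' @param x character vector
#' @return POSIXct vector (UTC), truncated to the minute
#' @keywords internal
parse_dt <- function(x) {
  x <- as.character(x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  fmts <- c("%Y-%m-%dT%H:%M:%S", "%Y-%m-%d %H:%M:%S",
            "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")
  for (f in fmts) {
    miss <- is.na(out) & !is.na(x) & nzchar(x)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = f, tz = "UTC")
  }
  trunc_minute(out)
}

trunc_minute <- function(t) {
  as.POSIXct(floor(as.numeric(t) / 60) * 60, origin = "1970-01-01", tz = "UTC")
}

format_dt <- function(t) format(t, "%Y-%m-%dT%H:%M", tz = "UTC")

#' Completed years between a date of birth and a later date
#'
#' Age in whole (completed) years, the convention used for the adult
#' eligibility window: the birthday itself counts as having completed the
#' year.
#'
#' @param dob Date vector
#' @param at Date or POSIXct vector of the same length (or length 1)
#' @return integer vector; `NA` where either input is missing
#' @export
#' @examples
#' whole_years(as.Date("2000-06-15"), as.Date("2018-06-14")) # 17
#' whole_years(as.Date("2000-06-15"), as.Date("2018-06-15")) # 18
whole_years <- function(dob, at) {
  dob <- as.Date(dob)
  at <- as.Date(at)
  db <- as.POSIXlt(dob)
  dd <- as.POSIXlt(at)
  y <- dd$year - db$year
  before_bday <- (dd$mon < db$mon) | (dd$mon == db$mon & dd$mday < db$mday)
  as.integer(y - before_bday)
}

round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# first day of the calendar month, as "YYYY-MM"
month_key <- function(t) format(t, "%Y-%m", tz = "UTC")
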