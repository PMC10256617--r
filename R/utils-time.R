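# Time handling: all timestamps are POSIXct in UTC. Minutes, hours and days
# are half-open bins [t, t + width) aligned to the clock.

.posix <- function(x) as.POSIXct(x, origin = "1970-01-01", tz = "UTC")

#' Floor timestamps to clock-aligned bins
#'
#' Minutes and hours are half-open bins `[t, t + 60 s)` / `[t, t + 3600 s)`;
#' days are UTC calendar days.
#'
#' @param t a POSIXct vector (UTC).
#' @return POSIXct vector of bin starts.
#' @keywords internal
floor_minute <- function(t) .posix(floor(as.numeric(t) / 60) * 60)

#' @rdname floor_minute
#' @keywords internal
floor_hour <- function(t) .posix(floor(as.numeric(t) / 3600) * 3600)

#' @rdname floor_minute
#' @keywords internal
floor_day <- function(t) .posix(floor(as.numeric(t) / 86400) * 86400)

#' Fractional month of the year
#'
#' Maps a timestamp to `[0, 12)`: 0 = start of January, 11.5 = mid December.
#' Used as the covariate for the cyclic month smooth, so that the smooth
#' wraps continuously at the new year.
#'
#' @param t POSIXct vector (UTC).
#' @return numeric vector in `[0, 12)`.
#' @export
monthFraction <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  days_in_month <- c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)
  dim <- days_in_month[lt$mon + 1]
  leap <- (lt$year %% 4 == 0 & lt$year %% 100 != 0) | (lt$year %% 400 == 0)
  dim[lt$mon == 1 & leap] <- 29
  frac <- (lt$mday - 1 + (lt$hour + lt$min / 60 + lt$sec / 3600) / 24) / dim
  lt$mon + frac
}

#' Hour of day as a decimal
#' @param t POSIXct vector (UTC).
#' @return numeric in `[0, 24)`.
#' @keywords internal
hour_of_day <- function(t) {
  lt <- as.POSIXlt(t, tz = "UTC")
  lt$hour + lt$min / 60 + lt$sec / 3600
}

#' Calendar date (UTC) of a timestamp
#' @param t POSIXct vector.
#' @return Date vector.
#' @keywords internal
utc_date <- function(t) as.Date(t, tz = "UTC")

# ISO-8601 with microseconds, fixed format for byte-stable exports
format_iso_us <- function(t) {
  secs <- as.numeric(t)
  whole <- floor(secs)
  us <- round((secs - whole) * 1e6)
  carry <- us >= 1e6
  whole[carry] <- whole[carry] + 1
  us[carry] <- 0
  sprintf("%s.%06dZ", format(.posix(whole), "%Y-%m-%dT%H:%M:%S", tz = "UTC"), us)
}

parse_iso_us <- function(x) {
  out <- as.POSIXct(strptime(x, "%Y-%m-%dT%H:%M:%OSZ", tz = "UTC"))
  bad <- !is.na(x) & x != "" & is.na(out)
  if (any(bad)) {
    stop("unparseable ISO-8601 timestamp at entry ", which(bad)[1], ": ", x[bad][1])
  }
  out
}

# round times to whole microseconds so write -> read round-trips exactly
round_us <- function(t) .posix(round(as.numeric(t) * 1e6) / 1e6)
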