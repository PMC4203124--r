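#' Astronomical day length for a given day of year and latitude
#'
#' Computes the daily photoperiod (hours between sunrise and sunset,
#' extended below the geometric horizon by `sun_angle` degrees) from a
#' standard solar-geometry model: solar declination as a sinusoidal function
#' of the day of year and the hour angle at which the solar altitude equals
#' `-sun_angle`. The default `sun_angle = 6` follows the convention that
#' photoperiod-effective radiation starts and ends when the sun is 6 degrees
#' below the horizon (civil twilight).
#'
#' @param doy Day of year, 1..366. Vectorised.
#' @param latitude Latitude in degrees north, in \[-90, 90\].
#' @param sun_angle Depression of the sun below the horizon, in degrees, at
#'   which the photoperiod starts/ends. 0 gives geometric sunrise/sunset.
#' @return Photoperiod in hours, in \[0, 24\]. Polar day returns 24, polar
#'   night 0.
#' @examples
#' photoperiod(172, 48.7)        # midsummer at Le Moulon latitude
#' photoperiod(355, 48.7)        # midwinter
#' @export
photoperiod <- function(doy, latitude, sun_angle = 6) {
  if (any(!is.finite(latitude)) || any(latitude < -90) || any(latitude > 90))
    stop("latitude must be within [-90, 90]")
  if (any(doy < 1 | doy > 366))
    stop("doy must be within 1..366")
  rad <- pi / 180
  # Forsythe et al. (1995) revolution-angle declination (accurate to
  # ~0.2 degrees, against ~1 degree for the simple sine form)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  decl <- asin(0.39795 * cos(theta)) / rad
  cos_h <- (sin(-sun_angle * rad) - sin(latitude * rad) * sin(decl * rad)) /
    (cos(latitude * rad) * cos(decl * rad))
  h <- acos(pmin(1, pmax(-1, cos_h)))  # half day arc, radians
  24 * h / pi
}

#' Day of year from a calendar date
#'
#' Proleptic Gregorian day-of-year (1..366), leap years respected.
#'
#' @param date A `Date` (or coercible) vector.
#' @return Integer day of year.
#' @export
day_of_year <- function(date) {
  as.POSIXlt(as.Date(date))$yday + 1L
}
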