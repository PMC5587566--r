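#' City configuration
#'
#' Bundles the geographic and demographic description of one city: its name,
#' coordinates (degrees, north/east positive), fixed UTC offset in hours
#' (local standard time; daylight-saving changes are deliberately ignored so
#' that clock-time comparisons across the year are not distorted by a one-hour
#' civil artifact), and population.
#'
#' @param name City name.
#' @param lat Latitude in degrees, positive north. Must lie in \[-90, 90\].
#' @param lon Longitude in degrees, positive east. Must lie in \[-180, 180\].
#' @param utc_offset Hours to add to UTC to obtain local standard time.
#' @param population Number of inhabitants (> 0).
#'
#' @return An object of class `city_config`.
#' @examples
#' city_config("testville", lat = 40, lon = 0, utc_offset = 0, population = 6e5)
#' @export
city_config <- function(name, lat, lon, utc_offset = 0, population = 1e5) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.finite(lat) || lat < -90 || lat > 90)
    stop("latitude must lie in [-90, 90]")
  if (!is.finite(lon) || lon < -180 || lon > 180)
    stop("longitude must lie in [-180, 180]")
  if (!is.finite(population) || population <= 0)
    stop("population must be > 0")
  structure(
    list(name = name, lat = lat, lon = lon,
         utc_offset = utc_offset, population = population),
    class = "city_config"
  )
}

#' @export
print.city_config <- function(x, ...) {
  cat(sprintf("<city_config> %s  (%.3f N, %.3f E), UTC%+g, pop %s\n",
              x$name, x$lat, x$lon, x$utc_offset,
              format(x$population, big.mark = ",")))
  invisible(x)
}

.check_solar_latitude <- function(lat) {
  if (abs(lat) >= 66)
    stop("unsupported latitude: |lat| must be < 66 degrees ",
         "(polar day/night is not handled)")
}

# NOAA solar-position geometry (Julian-century form, after Meeus): solar
# declination (degrees) and equation of time (minutes) at a given UTC
# instant. The daily daylight extremum around a solstice is decided by
# margins of about a second, so the declination phase must be good to a few
# hours across the year; the Julian-century series delivers that, where the
# one-term-per-harmonic day-of-year series does not.
.solar_eqtime_decl <- function(date, hour_utc = 12) {
  jd <- as.numeric(date) + 2440587.5 + hour_utc / 24  # Unix epoch -> JD
  t <- (jd - 2451545) / 36525

  L0 <- (280.46646 + t * (36000.76983 + 0.0003032 * t)) %% 360
  M <- 357.52911 + t * (35999.05029 - 0.0001537 * t)
  e <- 0.016708634 - t * (0.000042037 + 0.0000001267 * t)
  Mr <- M * pi / 180
  C <- sin(Mr) * (1.914602 - t * (0.004817 + 0.000014 * t)) +
    sin(2 * Mr) * (0.019993 - 0.000101 * t) +
    sin(3 * Mr) * 0.000289
  omega <- (125.04 - 1934.136 * t) * pi / 180
  app_long <- (L0 + C - 0.00569 - 0.00478 * sin(omega)) * pi / 180
  eps0 <- 23 + (26 + (21.448 - t * (46.815 + t * (0.00059 - t * 0.001813))) / 60) / 60
  eps <- (eps0 + 0.00256 * cos(omega)) * pi / 180

  decl <- asin(sin(eps) * sin(app_long))
  y <- tan(eps / 2)^2
  L0r <- L0 * pi / 180
  eqtime <- 4 * (180 / pi) * (y * sin(2 * L0r) - 2 * e * sin(Mr) +
    4 * e * y * sin(Mr) * cos(2 * L0r) -
    0.5 * y^2 * sin(4 * L0r) - 1.25 * e^2 * sin(2 * Mr))
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset for one city and date
#'
#' Computes sunrise and sunset in local standard clock hours from the
#' standard solar declination / hour-angle geometry, using the conventional
#' refraction-corrected solar altitude of -0.833 degrees at the horizon.
#'
#' @param city A [city_config()].
#' @param date A `Date` (or string coercible to one). Vectorised.
#'
#' @return A data.frame with columns `date`, `sunrise`, `sunset` (local
#'   clock hours; `0 <= sunrise < sunset < 24`).
#' @examples
#' eq <- city_config("equator", 0, 0, 0, 1e5)
#' sun_events(eq, as.Date("2007-03-21"))
#' @export
sun_events <- function(city, date) {
  stopifnot(inherits(city, "city_config"))
  .check_solar_latitude(city$lat)
  date <- as.Date(date)
  lat_r <- city$lat * pi / 180
  zen <- (90 + 0.833) * pi / 180
  hour_angle <- function(decl) {
    cos_ha <- cos(zen) / (cos(lat_r) * cos(decl)) - tan(lat_r) * tan(decl)
    if (any(abs(cos_ha) > 1))
      stop("sun does not rise or set on the requested date at this latitude")
    acos(cos_ha) * 180 / pi  # degrees
  }

  # First pass at 12:00 UTC, then refine the solar terms at the event times
  # themselves (the declination drifts enough within a day to matter when
  # locating the solstices to the exact calendar day).
  sun <- .solar_eqtime_decl(date)
  ha <- hour_angle(sun$decl)
  sunrise_utc <- 720 - 4 * (city$lon + ha) - sun$eqtime
  sunset_utc  <- 720 - 4 * (city$lon - ha) - sun$eqtime
  for (i in 1:3) {
    sun_r <- .solar_eqtime_decl(date, sunrise_utc / 60)
    sun_s <- .solar_eqtime_decl(date, sunset_utc / 60)
    sunrise_utc <- 720 - 4 * (city$lon + hour_angle(sun_r$decl)) - sun_r$eqtime
    sunset_utc  <- 720 - 4 * (city$lon - hour_angle(sun_s$decl)) - sun_s$eqtime
  }
  sunrise <- (sunrise_utc / 60 + city$utc_offset) %% 24
  sunset  <- (sunset_utc / 60 + city$utc_offset) %% 24
  data.frame(date = date, sunrise = sunrise, sunset = sunset)
}

#' Night length across a year
#'
#' Builds the astronomical night-length series N_length(d) for every day of
#' a (non-leap) year: 24 hours minus the daylight duration of day d, where
#' daylight is the interval between that day's own sunrise and sunset. Day
#' index d = 1 is January 1. At mid latitudes N_length peaks near the winter
#' solstice (d = 356 in 2007) and bottoms out near the summer solstice
#' (d = 172).
#'
#' @param city A [city_config()].
#' @param year Calendar year (non-leap; default 2007).
#'
#' @return A `night_length_series`: data.frame with columns `d`, `date`,
#'   `sunrise`, `sunset`, `n_length` (hours), plus attributes `city`, `year`.
#' @examples
#' nl <- night_length_series(city_config("mid", 40, 0, 0, 1e5), 2007)
#' nl$d[which.max(nl$n_length)]  # winter solstice
#' @export
night_length_series <- function(city, year = 2007) {
  stopifnot(inherits(city, "city_config"))
  .check_solar_latitude(city$lat)
  if (as.integer(strftime(as.Date(sprintf("%d-12-31", year)), "%j")) != 365L)
    stop("leap years are not supported")
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year)), by = "day")
  ev <- sun_events(city, dates)
  daylight <- ev$sunset - ev$sunrise
  out <- data.frame(d = seq_along(dates), date = dates,
                    sunrise = ev$sunrise, sunset = ev$sunset,
                    n_length = 24 - daylight)
  attr(out, "city") <- city
  attr(out, "year") <- year
  class(out) <- c("night_length_series", "data.frame")
  out
}
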