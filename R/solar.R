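# Solar geometry: NOAA solar-position equations (Spencer Fourier series for
# declination and the equation of time), zenith 90.833 deg for sunrise/sunset
# (standard refraction plus the solar radius).

ZENITH_SUNRISE_DEG <- 90.833

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Fractional year, equation of time and solar declination
#'
#' Evaluates the NOAA (Spencer) series at a given day of year and clock hour.
#'
#' @param doy day of year (1-366).
#' @param hour decimal clock hour used to refine the fractional year.
#' @return list with `eqtime` (minutes) and `decl` (radians).
#' @keywords internal
solar_coefficients <- function(doy, hour = 12) {
  g <- 2 * pi / 365 * (doy - 1 + (hour - 12) / 24)
  eqtime <- 229.18 * (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
                        0.014615 * cos(2 * g) - 0.040849 * sin(2 * g))
  decl <- 0.006918 - 0.399912 * cos(g) + 0.070257 * sin(g) -
    0.006758 * cos(2 * g) + 0.000907 * sin(2 * g) -
    0.002697 * cos(3 * g) + 0.00148 * sin(3 * g)
  list(eqtime = eqtime, decl = decl)
}

#' Sunrise and sunset times for a site and date
#'
#' Computes local-standard-time sunrise, sunset and day length from the NOAA
#' solar-position equations with a zenith of 90.833 degrees. Vectorised over
#' `date`.
#'
#' @param lat,lon site coordinates in decimal degrees.
#' @param utc_offset offset of site standard time from UTC in hours.
#' @param date `Date` vector (or anything coercible by [as.Date()]).
#' @return data.frame with columns `date`, `sunrise_local` and `sunset_local`
#'   (decimal hours, site standard time) and `day_length` (hours).
#' @details Polar day or polar night (the sun never crossing the sunrise
#'   zenith) raises an error naming the offending date; latitudes beyond the
#'   polar circles are the usual cause.
#' @examples
#' sun_times(45, -90, -6, as.Date("2012-06-21"))
#' @export
sun_times <- function(lat, lon, utc_offset, date) {
  stopifnot(abs(lat) <= 90)
  date <- as.Date(date)
  doy <- as.integer(strftime(date, "%j"))
  sc <- solar_coefficients(doy)
  lat_r <- deg2rad(lat)
  cos_ha <- cos(deg2rad(ZENITH_SUNRISE_DEG)) / (cos(lat_r) * cos(sc$decl)) -
    tan(lat_r) * tan(sc$decl)
  bad <- abs(cos_ha) > 1
  if (any(bad)) {
    stop("no sunrise/sunset (polar day or night) at lat ", lat,
         " on ", paste(format(date[bad][1]), collapse = ", "))
  }
  ha_deg <- rad2deg(acos(cos_ha))
  sunrise_utc <- 720 - 4 * (lon + ha_deg) - sc$eqtime       # minutes UTC
  sunset_utc  <- 720 - 4 * (lon - ha_deg) - sc$eqtime
  sunrise <- (sunrise_utc / 60 + utc_offset) %% 24
  sunset  <- (sunset_utc / 60 + utc_offset) %% 24
  data.frame(date = date,
             sunrise_local = sunrise,
             sunset_local = sunset,
             day_length = 2 * 4 * ha_deg / 60)
}

#' Solar elevation angle
#'
#' Elevation of the sun above the horizon for vectors of date-times expressed
#' in site standard time.
#'
#' @param lat,lon degrees; `utc_offset` hours.
#' @param date `Date` vector; `hour` decimal clock hour (site standard time).
#' @return elevation in degrees (negative below the horizon).
#' @keywords internal
solar_elevation <- function(lat, lon, utc_offset, date, hour) {
  doy <- as.integer(strftime(as.Date(date), "%j"))
  sc <- solar_coefficients(doy, hour)
  # true solar time in minutes
  tst <- (hour * 60 + sc$eqtime + 4 * lon - 60 * utc_offset) %% 1440
  ha <- deg2rad(tst / 4 - 180)
  lat_r <- deg2rad(lat)
  cos_zen <- sin(lat_r) * sin(sc$decl) + cos(lat_r) * cos(sc$decl) * cos(ha)
  90 - rad2deg(acos(pmin(1, pmax(-1, cos_zen))))
}

#' Label hourly records as daytime or nighttime
#'
#' An hour belongs to the daytime when its midpoint falls inside
#' \[sunrise, sunset) of its calendar date. Night hours are anchored to the
#' sunset that started them: hours after sunset keep their calendar date as
#' `diel_date`, hours before sunrise belong to the previous date, so the
#' "night of date d" spans sunset(d) to sunrise(d+1). This pairing unit is
#' what the paired day-night tests operate on.
#'
#' @param series hourly flux data.frame with columns `date` (`Date`) and
#'   `hour` (integer clock hour, start of the bin), or a `timestamp` POSIXct
#'   column from which both are derived.
#' @param meta site metadata from [make_site_meta()].
#' @return `series` with added columns `period` ("day"/"night") and
#'   `diel_date`.
#' @export
label_hours <- function(series, meta) {
  series <- ensure_date_hour(series)
  dates <- sort(unique(series$date))
  st <- sun_times(meta$lat, meta$lon, meta$utc_offset, dates)
  idx <- match(series$date, st$date)
  mid <- series$hour + 0.5
  is_day <- mid >= st$sunrise_local[idx] & mid < st$sunset_local[idx]
  series$period <- ifelse(is_day, "day", "night")
  series$diel_date <- series$date
  before_sunrise <- !is_day & mid < st$sunrise_local[idx]
  series$diel_date[before_sunrise] <- series$date[before_sunrise] - 1L
  series
}

#' Select a season from a labelled series
#'
#' Summer is June-August in the Northern Hemisphere and December-February in
#' the Southern Hemisphere; the remaining seasons rotate accordingly.
#' Selection is on `diel_date` so whole nights stay together.
#'
#' @param series labelled series (see [label_hours()]).
#' @param meta site metadata (hemisphere is taken from the latitude sign).
#' @param season one of "summer", "autumn", "winter", "spring".
#' @return the filtered series.
#' @export
season_filter <- function(series, meta,
                          season = c("summer", "autumn", "winter", "spring")) {
  season <- match.arg(season)
  north <- list(summer = 6:8, autumn = 9:11, winter = c(12, 1, 2),
                spring = 3:5)
  months <- north[[season]]
  if (identical(meta$hemisphere, "S")) {
    months <- (months + 5) %% 12 + 1   # shift by six months
  }
  if (!"diel_date" %in% names(series)) {
    stop("series must be labelled with label_hours() first")
  }
  series[as.integer(strftime(series$diel_date, "%m")) %in% months, ,
         drop = FALSE]
}

# Accept either (date, hour) columns or a POSIXct timestamp.
ensure_date_hour <- function(series) {
  if (!all(c("date", "hour") %in% names(series))) {
    if (!"timestamp" %in% names(series)) {
      stop("series needs either (date, hour) or a timestamp column")
    }
    series$date <- as.Date(series$timestamp, tz = "UTC")
    series$hour <- as.integer(strftime(series$timestamp, "%H", tz = "UTC"))
  }
  series
}
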