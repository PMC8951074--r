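#' Saturation vapour pressure of air
#'
#' Tetens-type exponential used throughout FAO-56:
#' \eqn{e_s(T) = 0.611 \exp(17.27 T / (T + 237.3))} kPa.
#'
#' @param ta Air temperature, degrees C. Vectorised.
#' @return Saturation vapour pressure, kPa.
#' @examples
#' svp(20)   # ~2.34 kPa
#' @export
svp <- function(ta) {
  if (!is.numeric(ta) || any(!is.finite(ta))) {
    stop("`ta` must be finite numeric air temperature (degrees C)", call. = FALSE)
  }
  if (any(ta <= -40)) stop("`ta` below -40 C is outside the valid range", call. = FALSE)
  0.611 * exp(17.27 * ta / (ta + 237.3))
}

#' Construct a daily weather record
#'
#' Validates one or more daily weather records. All arguments are recycled to
#' a common length, so a whole season can be built in one call.
#'
#' @param date Date vector (or coercible).
#' @param tmax,tmin Daily maximum/minimum air temperature, degrees C.
#' @param rhmax,rhmin Daily maximum/minimum relative humidity, percent.
#' @param srad Incoming solar radiation, MJ m-2 d-1.
#' @param wind Mean wind speed, m s-1 (at the anemometer height of the site).
#' @param rain Precipitation, mm.
#' @return A `data.frame` with class `weather_series`.
#' @export
weather_series <- function(date, tmax, tmin, rhmax, rhmin, srad, wind, rain) {
  date <- as.Date(date)
  w <- data.frame(date = date, tmax = tmax, tmin = tmin, rhmax = rhmax,
                  rhmin = rhmin, srad = srad, wind = wind, rain = rain)
  num <- w[setdiff(names(w), "date")]
  if (any(!vapply(num, is.numeric, logical(1))) || any(!is.finite(as.matrix(num)))) {
    stop("weather fields must be finite numerics; missing values are not imputed",
         call. = FALSE)
  }
  if (any(w$tmax < w$tmin)) stop("tmax < tmin in weather record", call. = FALSE)
  if (any(w$rhmin < 0 | w$rhmax > 100 | w$rhmin > w$rhmax)) {
    stop("relative humidity must satisfy 0 <= rhmin <= rhmax <= 100", call. = FALSE)
  }
  if (any(w$srad < 0)) stop("solar radiation must be >= 0", call. = FALSE)
  if (any(w$rain < 0)) stop("rain must be >= 0", call. = FALSE)
  if (any(w$wind < 0)) stop("wind must be >= 0", call. = FALSE)
  class(w) <- c("weather_series", "data.frame")
  w
}

#' Read a weather CSV
#'
#' Expects the header `date,tmax,tmin,rhmax,rhmin,srad,wind,rain` with
#' ISO-8601 dates; units as in [weather_series()].
#'
#' @param path Path to a CSV file.
#' @return A `weather_series`.
#' @export
read_weather_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "tmax", "tmin", "rhmax", "rhmin", "srad", "wind", "rain")
  if (!all(need %in% names(d))) {
    stop("weather CSV must have columns: ", paste(need, collapse = ","), call. = FALSE)
  }
  do.call(weather_series, d[need])
}

#' Write a weather series to CSV
#' @param w A `weather_series`.
#' @param path Output path.
#' @export
write_weather_csv <- function(w, path) {
  utils::write.csv(as.data.frame(w), path, row.names = FALSE, quote = FALSE)
}

#' Site description for reference evapotranspiration
#'
#' @param latitude Decimal degrees, negative south.
#' @param altitude Metres above sea level.
#' @param anemometer_height Wind measurement height, m (FAO-56 standard 2 m).
#' @return A list with class `site_info`.
#' @export
site_info <- function(latitude, altitude, anemometer_height = 2) {
  if (abs(latitude) > 90) stop("|latitude| must be <= 90", call. = FALSE)
  if (altitude < -430) stop("altitude below -430 m is not a land surface", call. = FALSE)
  if (anemometer_height <= 0) stop("anemometer height must be > 0", call. = FALSE)
  structure(list(latitude = latitude, altitude = altitude,
                 anemometer_height = anemometer_height), class = "site_info")
}

#' Daily vapour pressure deficit
#'
#' VPD = mean of saturation vapour pressure at Tmax and Tmin minus the actual
#' vapour pressure derived from extreme humidities:
#' \eqn{e_a = (e_s(T_{min}) RH_{max}/100 + e_s(T_{max}) RH_{min}/100)/2}.
#' Returned in Pascal, the unit the seasonal water-balance tables use.
#'
#' @param day A one-row `weather_series` (or data.frame with the same fields).
#' @return VPD in Pa (>= 0). Vectorised over rows.
#' @export
daily_vpd <- function(day) {
  if (any(day$rhmin < 0 | day$rhmax > 100 | day$rhmin > day$rhmax)) {
    stop("relative humidity outside [0, 100]", call. = FALSE)
  }
  es_mean <- (svp(day$tmax) + svp(day$tmin)) / 2
  ea <- (svp(day$tmin) * day$rhmax / 100 + svp(day$tmax) * day$rhmin / 100) / 2
  pmax(0, es_mean - ea) * 1000
}

#' FAO-56 grass reference evapotranspiration
#'
#' Daily Penman-Monteith reference ETo for a well-watered clipped grass
#' surface (albedo 0.23, surface resistance 70 s m-1), with the standard
#' FAO-56 sub-computations: psychrometric constant from site altitude,
#' extraterrestrial radiation from latitude and day of year, net longwave
#' from relative shortwave and actual vapour pressure, soil heat flux zero at
#' the daily step, wind log-profile adjustment to 2 m.
#'
#' @param day A `weather_series` (vectorised over rows).
#' @param site A [site_info()].
#' @param doy Day of year; defaults to the date column.
#' @return ETo in mm d-1, clamped at >= 0.
#' @export
reference_eto <- function(day, site, doy = as.integer(strftime(day$date, "%j"))) {
  stopifnot(inherits(site, "site_info"))
  tmean <- (day$tmax + day$tmin) / 2
  # slope of the saturation vapour pressure curve, kPa / C
  delta <- 4098 * (0.6108 * exp(17.27 * tmean / (tmean + 237.3))) / (tmean + 237.3)^2
  patm <- 101.3 * ((293 - 0.0065 * site$altitude) / 293)^5.26
  gamma <- 0.000665 * patm
  es <- (svp(day$tmax) + svp(day$tmin)) / 2
  ea <- (svp(day$tmin) * day$rhmax / 100 + svp(day$tmax) * day$rhmin / 100) / 2

  phi <- site$latitude * pi / 180
  dr <- 1 + 0.033 * cos(2 * pi * doy / 365)
  decl <- 0.409 * sin(2 * pi * doy / 365 - 1.39)
  x <- -tan(phi) * tan(decl)
  if (any(x <= -1 | x >= 1)) {
    stop("polar day/night: extraterrestrial radiation undefined for this latitude/date",
         call. = FALSE)
  }
  ws <- acos(x)
  ra <- 24 * 60 / pi * 0.0820 * dr *
    (ws * sin(phi) * sin(decl) + cos(phi) * cos(decl) * sin(ws))
  if (any(ra <= 0)) stop("non-positive extraterrestrial radiation", call. = FALSE)

  rso <- (0.75 + 2e-5 * site$altitude) * ra
  rns <- (1 - 0.23) * day$srad
  # relative shortwave bounded to [0.3, 1] (standardized-reference convention)
  rel <- pmin(pmax(day$srad / rso, 0.3), 1)
  rnl <- 4.903e-9 * ((day$tmax + 273.16)^4 + (day$tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(pmax(ea, 0))) * (1.35 * rel - 0.35)
  rn <- rns - rnl

  u2 <- if (abs(site$anemometer_height - 2) < 1e-9) day$wind else
    day$wind * 4.87 / log(67.8 * site$anemometer_height - 5.42)

  eto <- (0.408 * delta * rn + gamma * 900 / (tmean + 273) * u2 * (es - ea)) /
    (delta + gamma * (1 + 0.34 * u2))
  pmax(0, eto)
}

#' Daily growing degree days
#'
#' Thermal time from the daily mean temperature above a base temperature.
#' Days with mean temperature at or below the base contribute zero; the mean
#' is capped at the maximum developmental temperature before subtracting.
#'
#' @param tmax,tmin Daily temperature extremes, degrees C.
#' @param t_base Base temperature, degrees C (10 for pearl millet).
#' @param t_cutoff Maximum temperature, degrees C (45 for pearl millet).
#' @return Degree days, degrees C d. Vectorised.
#' @export
daily_gdd <- function(tmax, tmin, t_base = 10, t_cutoff = 45) {
  if (t_cutoff <= t_base) stop("t_cutoff must exceed t_base", call. = FALSE)
  if (any(tmax < tmin)) stop("tmax < tmin", call. = FALSE)
  tmean <- (tmax + tmin) / 2
  ifelse(tmean <= t_base, 0, pmin(tmean, t_cutoff) - t_base)
}

#' Cumulative growing degree days from a start date
#'
#' @param w A `weather_series` with contiguous daily dates.
#' @param t_base,t_cutoff Cardinal temperatures, degrees C.
#' @param start_date Accumulation start (e.g. sowing); defaults to first day.
#' @return Data frame of `date` and the running `gdd` (degrees C d) from
#'   `start_date` to the end of the series.
#' @export
cumulative_gdd <- function(w, t_base = 10, t_cutoff = 45,
                           start_date = w$date[1]) {
  start_date <- as.Date(start_date)
  if (nrow(w) > 1 && any(diff(as.integer(w$date)) != 1)) {
    stop("weather series has gaps in dates", call. = FALSE)
  }
  if (start_date < min(w$date) || start_date > max(w$date)) {
    stop("start_date outside weather coverage", call. = FALSE)
  }
  sub <- w[w$date >= start_date, , drop = FALSE]
  data.frame(date = sub$date,
             gdd = cumsum(daily_gdd(sub$tmax, sub$tmin, t_base, t_cutoff)))
}
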