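# Independent step-by-step FAO-56 daily reference ET computation, written as
# the literal worked-example sequence (each numbered step its own local
# variable). Kept deliberately separate from the package implementation so
# the two can disagree.
fao56_eto_oracle <- function(tmax, tmin, rhmax, rhmin, rs, uz,
                             lat_deg, alt_m, doy, z_wind = 2) {
  tmean <- (tmax + tmin) / 2

  # step 1: slope of saturation vapour pressure curve
  es_tmean <- 0.6108 * exp(17.27 * tmean / (tmean + 237.3))
  slope <- 4098 * es_tmean / (tmean + 237.3)^2

  # step 2: psychrometric constant from atmospheric pressure
  pres <- 101.3 * ((293 - 0.0065 * alt_m) / 293)^5.26
  psy <- 0.665e-3 * pres

  # step 3: vapour pressures from temperature/humidity extremes
  e0 <- function(t) 0.6108 * exp(17.27 * t / (t + 237.3))
  es <- (e0(tmax) + e0(tmin)) / 2
  ea <- (e0(tmin) * rhmax / 100 + e0(tmax) * rhmin / 100) / 2

  # step 4: extraterrestrial and clear-sky radiation
  lat <- pi / 180 * lat_deg
  inv_dist <- 1 + 0.033 * cos(2 * pi / 365 * doy)
  sol_dec <- 0.409 * sin(2 * pi / 365 * doy - 1.39)
  sunset <- acos(pmin(1, pmax(-1, -tan(lat) * tan(sol_dec))))
  ra <- (24 * 60 / pi) * 0.0820 * inv_dist *
    (sunset * sin(lat) * sin(sol_dec) + cos(lat) * cos(sol_dec) * sin(sunset))
  rso <- (0.75 + 2e-5 * alt_m) * ra

  # step 5: net radiation
  rns <- 0.77 * rs
  sb <- 4.903e-9
  cloud <- 1.35 * min(max(rs / rso, 0.3), 1) - 0.35
  rnl <- sb * ((tmax + 273.16)^4 + (tmin + 273.16)^4) / 2 *
    (0.34 - 0.14 * sqrt(ea)) * cloud
  rn <- rns - rnl

  # step 6: wind at 2 m
  u2 <- if (z_wind == 2) uz else uz * 4.87 / log(67.8 * z_wind - 5.42)

  # step 7: combination equation, G = 0 at the daily step
  num <- 0.408 * slope * rn + psy * (900 / (tmean + 273)) * u2 * (es - ea)
  den <- slope + psy * (1 + 0.34 * u2)
  max(0, num / den)
}

# shared small inputs for tests
test_site <- function() site_info(-25.75, 1327)

test_weather_long <- function(seed = 7) {
  generate_weather(climate_spec(season_length = 220, big_event_day = NULL,
                                seed = seed),
                   start_date = "2017-11-15")
}
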