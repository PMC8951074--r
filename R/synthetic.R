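# Synthetic weather seasons and growth-analysis trials with known ground
# truth. Generators are pure functions of (spec, seed): the global RNG state
# is saved and restored around every draw.

.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
            rm(".Random.seed", envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

#' Specification of a synthetic semi-arid summer season
#'
#' Defaults emulate a 130-day highveld summer season: daily mean
#' temperatures sweeping 13-32 degrees C over a half-sinusoid, a 12 degree
#' diurnal range, humid-subtropical humidities giving a seasonal mean VPD
#' near 0.8 kPa, episodic convective rain, and one ~208 mm three-day rain
#' event late in the season.
#'
#' @param season_length Days.
#' @param t_mean_range Bounds of the seasonal daily-mean temperature
#'   sinusoid, degrees C.
#' @param diurnal_range Mean daily tmax - tmin, degrees C.
#' @param rh_range Mean (rhmin, rhmax), percent.
#' @param srad_clear Clear-sky solar radiation, MJ m-2 d-1.
#' @param cloud_prob Probability a rainless day is cloudy.
#' @param rain_prob Daily rain probability.
#' @param rain_mean,rain_shape Gamma rain-depth mean (mm) and shape.
#' @param big_event_day Start day of the ~208 mm three-day event, or NULL
#'   to disable it.
#' @param seed RNG seed.
#' @return List with class `climate_spec`.
#' @export
climate_spec <- function(season_length = 130, t_mean_range = c(13, 32),
                         diurnal_range = 12, rh_range = c(65, 95),
                         srad_clear = 28, cloud_prob = 0.4,
                         rain_prob = 0.30, rain_mean = 8, rain_shape = 0.8,
                         big_event_day = 95, seed = 1) {
  stopifnot(season_length >= 1, diff(t_mean_range) > 0, diff(rh_range) > 0,
            cloud_prob >= 0, cloud_prob <= 1, rain_prob >= 0, rain_prob <= 1,
            rain_mean > 0, rain_shape > 0)
  structure(as.list(environment()), class = "climate_spec")
}

#' Generate a synthetic daily weather season
#'
#' @param spec A [climate_spec()].
#' @param start_date First day of the series.
#' @return A `weather_series` of `spec$season_length` days; identical for
#'   identical (spec, seed).
#' @export
generate_weather <- function(spec = climate_spec(), start_date = "2017-12-01") {
  stopifnot(inherits(spec, "climate_spec"))
  n <- spec$season_length
  .with_seed(spec$seed, {
    d <- seq_len(n)
    lo <- spec$t_mean_range[1]; hi <- spec$t_mean_range[2]
    tmean <- lo + (hi - lo) * sin(pi * (d - 0.5) / n)
    tmean <- pmin(hi, pmax(lo, tmean + stats::rnorm(n, 0, 1.2)))
    half <- pmax(2, spec$diurnal_range / 2 + stats::rnorm(n, 0, 1)) / 1
    tmax <- tmean + half
    tmin <- tmean - half

    rain_day <- stats::runif(n) < spec$rain_prob
    rain <- ifelse(rain_day,
                   stats::rgamma(n, shape = spec$rain_shape,
                                 scale = spec$rain_mean / spec$rain_shape), 0)
    if (!is.null(spec$big_event_day) && spec$big_event_day + 2 <= n) {
      rain[spec$big_event_day + 0:2] <- rain[spec$big_event_day + 0:2] +
        c(90, 80, 38)
    }

    rhmin <- pmin(100, pmax(5, spec$rh_range[1] + stats::rnorm(n, 0, 6) +
                                 ifelse(rain > 0, 8, 0)))
    rhmax <- pmin(100, pmax(rhmin, spec$rh_range[2] + stats::rnorm(n, 0, 3)))

    cloudy <- rain > 0 | stats::runif(n) < spec$cloud_prob
    season_shape <- 0.8 + 0.2 * sin(pi * (d - 0.5) / n)
    srad <- spec$srad_clear * season_shape *
      ifelse(cloudy, stats::runif(n, 0.35, 0.7), stats::runif(n, 0.85, 1.0))

    wind <- pmax(0.3, stats::rlnorm(n, log(1.6), 0.35))

    weather_series(date = as.Date(start_date) + d - 1,
                   tmax = tmax, tmin = tmin, rhmax = rhmax, rhmin = rhmin,
                   srad = srad, wind = wind, rain = round(rain, 1))
  })
}

#' Specification of a synthetic growth-analysis trial
#'
#' Emulates fortnightly destructive harvests of a well-watered growth
#' analysis: the forward crop model is run under weekly refill irrigation,
#' sampled at a fixed interval, and multiplicative lognormal noise
#' (coefficient of variation `noise_cv`) is applied to the biomass pools and
#' LAI; fractional PAR interception is derived from the true extinction
#' coefficient before noising on the logit scale.
#'
#' Three conventions make the noiseless trial an exact forward model of the
#' derivation pipeline: the forward run uses the radiation-limited
#' production branch (growth analyses are conducted under optimal water);
#' assimilate allocation to roots is switched off (the regressions concern
#' above-ground matter only, which is why the measured RUE and DWR are
#' lower limits); and the emergence seed endowment is credited to the
#' radiation ledger at its RUE-equivalent interception, so above-ground dry
#' matter is exactly proportional to cumulative intercepted radiation.
#'
#' @param true_params A [crop_parameters()] used as ground truth; its
#'   `root_fraction_initial` is forced to 0.
#' @param sampling_interval Days between destructive harvests.
#' @param noise_cv Coefficient of variation of the observation noise.
#' @param seed RNG seed.
#' @return List with class `trial_spec`.
#' @export
trial_spec <- function(true_params = millet_variety("kantana"),
                       sampling_interval = 14, noise_cv = 0.05, seed = 1) {
  stopifnot(inherits(true_params, "crop_parameters"),
            sampling_interval >= 1, noise_cv >= 0)
  true_params$root_fraction_initial <- 0
  structure(list(true_params = true_params,
                 sampling_interval = sampling_interval,
                 noise_cv = noise_cv, seed = seed), class = "trial_spec")
}

#' Generate a synthetic growth-analysis trial
#'
#' @param spec A [trial_spec()].
#' @param weather A `weather_series` long enough to reach crop maturity.
#' @param sim Optional precomputed forward simulation (as produced
#'   internally: weekly refill, radiation-limited branch); lets Monte-Carlo
#'   noise replicates share one forward run.
#' @param ... Further arguments to [simulate_season()] (`site`, `soil`).
#' @return List of class `growth_trial` with `observations` (one row per
#'   destructive harvest: `date, day, lai, leaf_area, ldm, sdm, cdm, agdm,
#'   hdm, fi_par, cum_fi_rs`), `truth` (the true [crop_parameters()]) and
#'   `sim` (the noiseless forward simulation).
#' @export
generate_growth_trial <- function(spec = trial_spec(), weather, sim = NULL, ...) {
  stopifnot(inherits(spec, "trial_spec"))
  pars <- spec$true_params
  if (is.null(sim)) {
    sim <- simulate_season(pars, weather, management = "weekly_refill",
                           limitation = "radiation", ...)
  }
  if (sim$status != "mature") {
    stop("forward simulation did not reach maturity (status: ", sim$status, ")",
         call. = FALSE)
  }
  tr <- sim$trace
  # radiation ledger: interception counts only while the canopy is green and
  # growing; the seed endowment is credited at its RUE-equivalent interception
  growing <- tr$stage %in% c("emerged", "vegetative", "reproductive")
  cum_fi_rs <- cumsum(tr$fi_rad * weather$srad[tr$day] * growing) +
    ifelse(tr$stage != "sown", pars$dm_at_emergence / pars$rue, 0)

  idx <- seq(spec$sampling_interval, nrow(tr), by = spec$sampling_interval)
  obs <- tr[idx, c("date", "day", "lai", "ldm", "sdm", "hdm", "agdm")]
  obs$cum_fi_rs <- cum_fi_rs[idx]
  fi_true <- fractional_interception(pars$k_par, obs$lai)

  .with_seed(spec$seed, {
    noisy <- function(x) {
      if (spec$noise_cv == 0) return(x)
      sdlog <- sqrt(log(1 + spec$noise_cv^2))
      x * stats::rlnorm(length(x), -sdlog^2 / 2, sdlog)
    }
    obs$lai <- noisy(obs$lai)
    obs$ldm <- noisy(obs$ldm)
    obs$sdm <- noisy(obs$sdm)
    obs$agdm <- noisy(obs$agdm)
    obs$hdm <- noisy(obs$hdm)
    obs$fi_par <- if (spec$noise_cv == 0) fi_true else {
      z <- stats::qlogis(pmin(pmax(fi_true, 1e-12), 1 - 1e-12)) +
        stats::rnorm(length(fi_true), 0, spec$noise_cv)
      pmin(1 - 1e-9, pmax(1e-9, stats::plogis(z)))
    }
  })
  obs$cdm <- obs$ldm + obs$sdm
  obs$leaf_area <- obs$lai  # per m2 of sampling area
  rownames(obs) <- NULL
  structure(list(observations = obs, truth = pars, sim = sim),
            class = "growth_trial")
}

#' Write trial observations to CSV
#' @param trial A `growth_trial` (or its `observations` data.frame).
#' @param path Output path.
#' @export
write_trial_csv <- function(trial, path) {
  obs <- if (inherits(trial, "growth_trial")) trial$observations else trial
  cols <- c("date", "lai", "leaf_area", "ldm", "sdm", "cdm", "agdm", "hdm",
            "fi_par", "cum_fi_rs")
  utils::write.csv(obs[intersect(cols, names(obs))], path,
                   row.names = FALSE, quote = FALSE)
}
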