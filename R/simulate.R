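#' Simulate a full growing season
#'
#' Runs the coupled daily crop growth and soil water balance from sowing
#' until crop maturity or the end of the weather record. Each day, in order:
#' reference ETo, VPD and thermal time are derived from the weather; the
#' irrigation rule is evaluated on the root-zone deficit; rain plus
#' irrigation infiltrate through the cascading profile (excess past the
#' bottom layer is drainage, runoff is held at zero); canopy interception of
#' solar radiation splits ETo into potential soil evaporation and potential
#' transpiration; both are extracted supply-limited from the profile; the
#' stress index, phenology, dry-matter production (minimum of the
#' radiation- and transpiration-limited rates) and organ partitioning follow.
#' At the emergence transition the shoot pool is seeded with the emergence
#' dry matter, split between leaf and stem by the partitioning relation.
#'
#' @param params A [crop_parameters()].
#' @param weather A `weather_series` covering the season from sowing.
#' @param site A [site_info()].
#' @param soil A [soil_profile()]; initial condition is taken as given.
#' @param management Irrigation mode: `"weekly_refill"`,
#'   `"fortnightly_refill"` or `"rainfed"`.
#' @param first_irrigation_day First scheduled irrigation day (see
#'   [irrigation_decision()]).
#' @param limitation `"dual"` (default) takes the daily minimum of the
#'   radiation- and transpiration-limited production rates; `"radiation"`
#'   uses the radiation-limited rate alone, the appropriate branch for
#'   optimally watered growth-analysis trials.
#' @return A list of class `swb_simulation` with elements `trace` (one row
#'   per simulated day), `status` (`"mature"`, `"weather_exhausted"` or
#'   `"incomplete_before_emergence"`), `soil` (final profile) and `params`.
#' @export
simulate_season <- function(params, weather, site = site_info(-25.75, 1327),
                            soil = soil_profile(),
                            management = c("weekly_refill", "fortnightly_refill",
                                           "rainfed"),
                            first_irrigation_day = NULL,
                            limitation = c("dual", "radiation")) {
  stopifnot(inherits(params, "crop_parameters"), inherits(weather, "weather_series"))
  management <- match.arg(management)
  limitation <- match.arg(limitation)
  state <- crop_state(params)
  eto_all <- reference_eto(weather, site)
  vpd_all <- daily_vpd(weather)
  gdd_all <- daily_gdd(weather$tmax, weather$tmin, params$t_base, params$t_cutoff)

  n <- nrow(weather)
  num_cols <- c("rain", "irrigation", "runoff", "drainage", "soil_evap",
                "transpiration", "storage_start", "storage_end", "eto", "vpd",
                "gdd_inc", "gdd_cum", "fi_rad", "si", "dm_inc", "ldm", "sdm",
                "hdm", "rdm", "agdm", "lai", "root_depth")
  out <- lapply(num_cols, function(.) numeric(n))
  names(out) <- num_cols
  stage_col <- character(n)
  status <- "weather_exhausted"
  last <- 0L
  for (i in seq_len(n)) {
    storage_start <- profile_storage(soil)

    irr <- irrigation_decision(soil, management, i, params$rd_max,
                               first_irrigation_day)
    inf <- infiltrate_cascade(soil, weather$rain[i] + irr)
    soil <- inf$profile

    fi_rad <- fractional_interception(params$k_s, state$lai)
    et <- partition_et(eto_all[i], fi_rad)
    ev <- extract_evaporation(soil, et$e_pot)
    soil <- ev$profile
    tr <- extract_transpiration(soil, et$t_pot, state$root_depth,
                                params$t_max_rate, params$stress_threshold)
    soil <- tr$profile
    si <- stress_index(tr$t_act, et$t_pot)
    state$si_today <- si

    was_emerged <- state$stage != "sown"
    state <- advance_phenology(state, gdd_all[i], params, si)
    if (!was_emerged && state$stage != "sown") {
      # emergence: seed the shoot pool and split leaf/stem
      cdm0 <- params$dm_at_emergence
      state$ldm <- cdm0 / (1 + params$p * cdm0)
      state$sdm <- cdm0 - state$ldm
      state$lai <- update_lai(state$ldm, params$sla)
    }
    state$root_depth <- root_depth_from_gdd(state$gdd_cum, params)

    dm_inc <- 0
    if (state$stage %in% c("emerged", "vegetative", "reproductive")) {
      dm_inc <- if (limitation == "radiation") {
        params$rue * fi_rad * weather$srad[i]
      } else {
        dm_increment(tr$t_act, vpd_all[i], fi_rad, weather$srad[i], params)
      }
      state <- partition_dm(state, dm_inc, params)
    }

    vals <- c(weather$rain[i], irr, 0, inf$drainage, ev$e_act, tr$t_act,
              storage_start, profile_storage(soil), eto_all[i], vpd_all[i],
              gdd_all[i], state$gdd_cum, fi_rad, si, dm_inc,
              state$ldm, state$sdm, state$hdm, state$rdm,
              state$ldm + state$sdm + state$hdm, state$lai, state$root_depth)
    for (k in seq_along(num_cols)) out[[k]][i] <- vals[k]
    stage_col[i] <- state$stage
    last <- i
    if (state$stage == "mature") { status <- "mature"; break }
  }
  keep <- seq_len(last)
  trace <- data.frame(date = weather$date[keep], day = keep,
                      lapply(out, `[`, keep), stage = stage_col[keep])
  if (status != "mature" && state$stage == "sown") {
    status <- "incomplete_before_emergence"
  }
  structure(list(trace = trace, status = status, soil = soil, params = params),
            class = "swb_simulation")
}

#' @export
print.swb_simulation <- function(x, ...) {
  tr <- x$trace
  cat("<swb_simulation>", if (!is.null(x$params$name)) x$params$name else "", "\n")
  cat(sprintf("  %d days, status: %s\n", nrow(tr), x$status))
  cat(sprintf("  GDD %.0f C d, final AGDM %.3f kg m-2, grain %.3f kg m-2, peak LAI %.2f\n",
              tr$gdd_cum[nrow(tr)], tr$agdm[nrow(tr)], tr$hdm[nrow(tr)], max(tr$lai)))
  cat(sprintf("  water: P %.0f + I %.0f = ET %.0f + D %.0f + dS %.0f mm\n",
              sum(tr$rain), sum(tr$irrigation),
              sum(tr$soil_evap + tr$transpiration), sum(tr$drainage),
              tr$storage_end[nrow(tr)] - tr$storage_start[1]))
  invisible(x)
}

#' Write a daily simulation trace to CSV
#' @param sim A `swb_simulation`.
#' @param path Output path.
#' @export
write_trace_csv <- function(sim, path) {
  utils::write.csv(sim$trace, path, row.names = FALSE, quote = FALSE)
}

#' Seasonal water-balance summary of a simulation
#'
#' Aggregates the daily ledger into the seasonal components of a
#' water-balance table: precipitation, irrigation, ET, drainage, runoff,
#' seasonal reference ETo and mean VPD.
#'
#' @param sim A `swb_simulation`.
#' @return One-row data.frame (mm; VPD in kPa).
#' @export
seasonal_balance <- function(sim) {
  tr <- sim$trace
  data.frame(P = sum(tr$rain), I = sum(tr$irrigation),
             ET = sum(tr$soil_evap + tr$transpiration),
             D = sum(tr$drainage), R = sum(tr$runoff),
             ETo = sum(tr$eto), avg_vpd_kpa = mean(tr$vpd) / 1000)
}
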