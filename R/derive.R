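# Growth-analysis parameter derivation: each fit is a least-squares slope
# forced through the origin, with r-squared defined as 1 - SSres / sum(y^2)
# (the no-intercept convention, stated explicitly because r-squared
# definitions differ once the origin is forced).

.origin_fit <- function(x, y, what) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 2) stop("need at least 2 points to fit ", what, call. = FALSE)
  sxx <- sum(x^2)
  if (sxx <= 0) stop("degenerate fit for ", what, ": all predictors are zero",
                     call. = FALSE)
  slope <- sum(x * y) / sxx
  ss_res <- sum((y - slope * x)^2)
  ss_tot <- sum(y^2)
  r2 <- if (ss_tot > 0) 1 - ss_res / ss_tot else 1
  structure(list(estimate = slope, r_squared = r2, n = length(x)),
            class = "swb_fit")
}

#' @export
print.swb_fit <- function(x, ...) {
  cat(sprintf("through-origin fit: slope %.6g (r2 = %.4f, n = %d)\n",
              x$estimate, x$r_squared, x$n))
  invisible(x)
}

#' Fit radiation use efficiency
#'
#' RUE is the slope, forced through the origin, of above-ground dry matter
#' on the cumulative product of fractional interception and incoming solar
#' radiation. Because roots are excluded from destructive-harvest dry
#' matter, the estimate is a lower limit on the whole-plant value.
#'
#' @param obs A growth-trial data.frame with columns `agdm` (kg m-2) and
#'   `cum_fi_rs` (MJ m-2).
#' @return A fit object with `estimate` (kg MJ-1), `r_squared`, `n`.
#' @export
fit_rue <- function(obs) {
  .origin_fit(obs$cum_fi_rs, obs$agdm, "RUE")
}

#' Fit the canopy extinction coefficient for PAR
#'
#' Linearised Beer-Bouguer inversion: the through-origin slope of
#' \eqn{-\log(1 - FI_{PAR})} on LAI.
#'
#' @param lai Leaf area indices (m2 m-2).
#' @param fi_par Fractional PAR interception, each < 1.
#' @return A fit object (dimensionless estimate).
#' @export
fit_kpar <- function(lai, fi_par) {
  if (any(fi_par >= 1)) stop("fi_par = 1 cannot be linearised", call. = FALSE)
  if (any(fi_par < 0)) stop("fi_par must be >= 0", call. = FALSE)
  .origin_fit(lai, -log(1 - fi_par), "K_PAR")
}

#' Fit the leaf-stem partitioning parameter
#'
#' The partitioning relation \eqn{LDM = CDM/(1 + p\,CDM)} with
#' \eqn{LAI = SLA \cdot LDM} implies \eqn{SLA \cdot CDM / LAI - 1 = p\,CDM};
#' p is the through-origin slope of that transform on canopy dry matter.
#'
#' @param cdm Canopy (leaf + stem) dry matter, kg m-2.
#' @param sla Season-mean specific leaf area, m2 kg-1.
#' @param lai Leaf area indices (> 0).
#' @return A fit object (m2 kg-1).
#' @export
fit_partition_p <- function(cdm, sla, lai) {
  if (any(lai <= 0)) stop("lai must be > 0", call. = FALSE)
  .origin_fit(cdm, sla * cdm / lai - 1, "p")
}

#' Season-mean specific leaf area
#'
#' Unweighted mean over sampling events of leaf area divided by leaf dry
#' matter. Events with zero leaf mass are skipped with a warning.
#'
#' @param leaf_area Leaf area per sampling area, m2.
#' @param ldm Leaf dry matter per sampling area, kg.
#' @return Mean SLA, m2 kg-1.
#' @export
mean_sla <- function(leaf_area, ldm) {
  stopifnot(length(leaf_area) == length(ldm))
  keep <- ldm > 0
  if (!all(keep)) warning("skipping ", sum(!keep), " sampling(s) with zero leaf mass")
  if (!any(keep)) stop("no sampling with positive leaf mass", call. = FALSE)
  mean(leaf_area[keep] / ldm[keep])
}

#' Lower-limit dry matter water ratio
#'
#' Seasonal form of the VPD-corrected water-productivity relation,
#' \eqn{DWR = DM \cdot VPD / ET}, evaluated with above-ground dry matter at
#' physiological maturity and seasonal ET. Using ET instead of transpiration
#' and excluding roots both inflate the denominator / shrink the numerator,
#' so the value is a lower bound that model calibration adjusts upwards.
#'
#' @param agdm_at_maturity Above-ground dry matter at maturity, kg m-2.
#' @param seasonal_et Seasonal evapotranspiration, mm (= kg water m-2).
#' @param seasonal_mean_vpd Season-average vapour pressure deficit, Pa.
#' @return DWR lower limit, Pa.
#' @export
dwr_lower_limit <- function(agdm_at_maturity, seasonal_et, seasonal_mean_vpd) {
  if (seasonal_et <= 0 || seasonal_mean_vpd <= 0) {
    stop("ET and VPD must be positive", call. = FALSE)
  }
  if (agdm_at_maturity < 0) stop("agdm must be >= 0", call. = FALSE)
  agdm_at_maturity * seasonal_mean_vpd / seasonal_et
}

#' Stage thermal-time thresholds from phenology dates
#'
#' Evaluates cumulative thermal time at each observed phenology date,
#' yielding the stage thresholds a simulation needs. Accumulation starts the
#' day after sowing, so a stage reached n days after sowing carries n daily
#' increments.
#'
#' @param phenology_dates Named list/vector of dates with elements `sowing`,
#'   and any of `emergence`, `transition`, `flowering`, `maturity`.
#' @param weather A `weather_series` covering all dates.
#' @param t_base,t_cutoff Cardinal temperatures, degrees C.
#' @return Named numeric vector of degrees C d from sowing (sowing itself 0).
#' @export
stage_gdd <- function(phenology_dates, weather, t_base = 10, t_cutoff = 45) {
  dates <- lapply(phenology_dates, as.Date)
  if (is.null(dates$sowing)) stop("phenology_dates must include `sowing`", call. = FALSE)
  if (any(unlist(dates) < min(weather$date)) || any(unlist(dates) > max(weather$date))) {
    stop("phenology date outside weather coverage", call. = FALSE)
  }
  cg <- cumulative_gdd(weather, t_base, t_cutoff, start_date = dates$sowing)
  vapply(dates, function(d) {
    if (d == dates$sowing) 0 else cg$gdd[match(d, cg$date)] - cg$gdd[1]
  }, numeric(1))
}

#' Water use efficiency
#'
#' Yield (or biomass) per unit of water evapotranspired, in kg per cubic
#' metre of water (1 mm of ET over 1 m2 = 0.001 m3).
#'
#' @param yield Dry matter, kg m-2.
#' @param seasonal_et Seasonal ET, mm (> 0).
#' @return WUE, kg m-3.
#' @export
wue <- function(yield, seasonal_et) {
  if (any(seasonal_et <= 0)) stop("seasonal_et must be > 0", call. = FALSE)
  if (any(yield < 0)) stop("yield must be >= 0", call. = FALSE)
  yield / (seasonal_et / 1000)
}

#' Sweep the dry matter water ratio against deficit observations
#'
#' Calibration helper mirroring the manual upward adjustment of the DWR
#' lower limit: re-runs the season simulation over a grid of DWR values and
#' scores the simulated root-zone deficit against observations with the
#' Willmott index of agreement. No automatic optimiser - the scored grid is
#' returned for inspection.
#'
#' @param dwr_values Candidate DWR values, Pa.
#' @param params Base [crop_parameters()] (its `dwr` is replaced).
#' @param observed Data.frame with columns `day` and `deficit` (mm).
#' @param ... Passed on to [simulate_season()] (`weather`, `site`, `soil`,
#'   `management`, ...).
#' @return Data.frame of `dwr` and `willmott_d`, best first.
#' @export
sweep_dwr <- function(dwr_values, params, observed, ...) {
  score <- vapply(dwr_values, function(v) {
    p2 <- params; p2$dwr <- v
    sim <- simulate_season(p2, ...)
    dtr <- sim$trace$storage_start  # deficit proxy: recompute from storage
    fcmm <- sum(sim$soil$fc * sim$soil$thickness * 1000)
    def_sim <- fcmm - sim$trace$storage_end
    idx <- match(observed$day, sim$trace$day)
    ok <- !is.na(idx)
    willmott_d(observed$deficit[ok], def_sim[idx[ok]])
  }, numeric(1))
  out <- data.frame(dwr = dwr_values, willmott_d = score)
  out[order(-out$willmott_d), ]
}

#' Read a growth-trial CSV
#'
#' Expects header `date,lai,leaf_area,ldm,sdm,agdm,hdm,fi_par` and, when
#' produced by [generate_growth_trial()], also `cdm` and `cum_fi_rs`.
#'
#' @param path Path to CSV.
#' @return Data.frame of observations.
#' @export
read_trial_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("date", "lai", "leaf_area", "ldm", "sdm", "agdm", "hdm", "fi_par")
  if (!all(need %in% names(d))) {
    stop("trial CSV must have columns: ", paste(need, collapse = ","), call. = FALSE)
  }
  d$date <- as.Date(d$date)
  d
}

#' Run the full derivation pipeline on a growth trial
#'
#' Fits RUE, K_PAR, the leaf-stem partitioning parameter and the season-mean
#' SLA from fortnightly destructive-harvest observations, in the same order
#' the growth analysis does (SLA first, since the p-transform needs it).
#'
#' @param obs Trial observations (see [read_trial_csv()]).
#' @return List with elements `rue`, `k_par`, `p` (fit objects) and `sla`
#'   (numeric).
#' @export
derive_parameters <- function(obs) {
  sla <- mean_sla(obs$leaf_area, obs$ldm)
  grow <- obs$lai > 0 & obs$fi_par > 0 & obs$fi_par < 1
  cdm <- if ("cdm" %in% names(obs)) obs$cdm else obs$ldm + obs$sdm
  list(rue = fit_rue(obs),
       k_par = fit_kpar(obs$lai[grow], obs$fi_par[grow]),
       p = fit_partition_p(cdm[grow], sla, obs$lai[grow]),
       sla = sla)
}
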