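#' Layered soil profile
#'
#' A top-down stack of soil layers, each with its own thickness, volumetric
#' water content and hydraulic limits. The default mirrors the measurement
#' layout of a neutron-probe trial: five 0.20 m layers to 1.0 m in a sandy
#' clay loam (field capacity 0.27, permanent wilting point 0.13 m3 m-3,
#' bulk density 1350 kg m-3), initialised at field capacity.
#'
#' @param thickness Layer thicknesses, m (top first).
#' @param fc Volumetric water content at field capacity, m3 m-3.
#' @param pwp Volumetric water content at permanent wilting point, m3 m-3.
#' @param theta Initial volumetric water content; defaults to `fc`.
#' @param bulk_density Bulk density, kg m-3.
#' @return A `data.frame` with class `soil_profile`.
#' @export
soil_profile <- function(thickness = rep(0.20, 5), fc = 0.27, pwp = 0.13,
                         theta = fc, bulk_density = 1350) {
  n <- length(thickness)
  p <- data.frame(thickness = thickness,
                  theta = rep_len(theta, n),
                  fc = rep_len(fc, n),
                  pwp = rep_len(pwp, n),
                  bulk_density = rep_len(bulk_density, n))
  if (any(p$thickness <= 0)) stop("layer thickness must be > 0", call. = FALSE)
  if (any(p$pwp <= 0 | p$pwp >= p$fc | p$fc >= 1)) {
    stop("layers must satisfy 0 < pwp < fc < 1", call. = FALSE)
  }
  if (any(p$theta < 0 | p$theta > 1)) stop("theta outside [0, 1]", call. = FALSE)
  class(p) <- c("soil_profile", "data.frame")
  p
}

#' Total water stored in a profile
#' @param profile A [soil_profile()].
#' @return Storage in mm over the whole profile.
#' @export
profile_storage <- function(profile) {
  sum(profile$theta * profile$thickness * 1000)
}

#' Evapotranspiration from the mass balance
#'
#' The conservation-of-mass ledger of a weekly water-balance table:
#' \eqn{ET = P + I - R - D - \Delta S} with \eqn{\Delta S = Q_{end} - Q_{start}}.
#' A negative result signals inconsistent measurements and is returned with a
#' warning rather than suppressed.
#'
#' @param p Precipitation, mm. @param i Irrigation, mm.
#' @param r Runoff, mm. @param d Drainage (deep percolation), mm.
#' @param q_start,q_end Root-zone storage at the start/end of the period, mm.
#' @return ET in mm (may be negative, with a warning). Vectorised.
#' @export
et_from_balance <- function(p, i, r, d, q_start, q_end) {
  args <- list(p, i, r, d, q_start, q_end)
  if (any(!vapply(args, function(x) all(is.finite(x)), logical(1)))) {
    stop("all water-balance terms must be finite", call. = FALSE)
  }
  if (any(c(p, i, r, d) < 0)) stop("p, i, r, d must be >= 0", call. = FALSE)
  et <- p + i - r - d - (q_end - q_start)
  if (any(et < 0)) warning("negative ET: water-balance terms are inconsistent")
  et
}

#' Infiltrate water through a cascading profile
#'
#' Classic tipping-bucket scheme: infiltrating water fills the top layer up
#' to field capacity, the excess cascades to the next layer, and whatever
#' passes the bottom layer leaves as deep drainage. Drainage to field
#' capacity is instantaneous at the daily step.
#'
#' @param profile A [soil_profile()].
#' @param water_in Infiltrating water (rain + irrigation), mm (>= 0).
#' @return List with `profile` (updated) and `drainage` (mm).
#' @export
infiltrate_cascade <- function(profile, water_in) {
  if (water_in < 0) stop("water_in must be >= 0", call. = FALSE)
  excess <- water_in
  for (l in seq_len(nrow(profile))) {
    cap <- max(0, (profile$fc[l] - profile$theta[l])) * profile$thickness[l] * 1000
    absorbed <- min(cap, excess)
    profile$theta[l] <- profile$theta[l] + absorbed / (profile$thickness[l] * 1000)
    excess <- excess - absorbed
    if (excess <= 0) break
  }
  list(profile = profile, drainage = excess)
}

# depth-weighted layer coverage of a root zone, pro-rata for partial layers
.layer_cover <- function(profile, depth) {
  bottom <- cumsum(profile$thickness)
  top <- c(0, bottom[-length(bottom)])
  pmax(0, pmin(bottom, depth) - top)
}

#' Root-zone deficit to field capacity
#'
#' @param profile A [soil_profile()].
#' @param depth Depth over which to integrate, m (<= profile depth).
#' @return Deficit in mm; layers wetter than field capacity contribute zero.
#' @export
profile_deficit <- function(profile, depth = sum(profile$thickness)) {
  if (depth <= 0 || depth > sum(profile$thickness) + 1e-9) {
    stop("depth must lie in (0, profile depth]", call. = FALSE)
  }
  cover <- .layer_cover(profile, depth)
  sum(pmax(0, profile$fc - profile$theta) * cover * 1000)
}

#' Partition reference evapotranspiration by canopy cover
#'
#' The canopy's fractional interception of total solar radiation splits the
#' evaporative demand: the intercepted share drives potential transpiration,
#' the transmitted share potential soil evaporation.
#'
#' @param eto Reference evapotranspiration, mm d-1.
#' @param fi_rad Fractional interception of solar radiation, [0, 1).
#' @return List with `e_pot` and `t_pot` (mm), summing to `eto`.
#' @export
partition_et <- function(eto, fi_rad) {
  if (any(eto < 0)) stop("eto must be >= 0", call. = FALSE)
  if (any(fi_rad < 0 | fi_rad >= 1)) stop("fi_rad must lie in [0, 1)", call. = FALSE)
  list(e_pot = (1 - fi_rad) * eto, t_pot = fi_rad * eto)
}

#' Extract transpiration from the root zone
#'
#' Demand is the potential transpiration capped at the crop's maximum rate.
#' Supply is limited through the root-zone plant-available water fraction
#' \eqn{f = (\bar\theta - PWP)/(FC - PWP)}: below the stress threshold the
#' uptake is reduced linearly (multiplier \eqn{\min(1, f/threshold)}).
#' Water is removed from root-zone layers in proportion to each layer's
#' plant-available water; no layer is drawn below wilting point.
#'
#' @param profile A [soil_profile()].
#' @param t_pot Potential transpiration, mm.
#' @param root_depth Rooting depth, m.
#' @param t_max_rate Maximum transpiration rate, mm d-1.
#' @param stress_threshold Plant-available-water fraction below which uptake
#'   is linearly reduced (Table value 0.30 for pearl millet).
#' @return List with `profile` (updated) and `t_act` (mm).
#' @export
extract_transpiration <- function(profile, t_pot, root_depth,
                                  t_max_rate = 9, stress_threshold = 0.30) {
  if (root_depth <= 0) stop("root_depth must be > 0", call. = FALSE)
  if (t_pot < 0) stop("t_pot must be >= 0", call. = FALSE)
  if (stress_threshold <= 0 || stress_threshold >= 1) {
    stop("stress_threshold must lie in (0, 1)", call. = FALSE)
  }
  cover <- .layer_cover(profile, min(root_depth, sum(profile$thickness)))
  paw <- pmax(0, profile$theta - profile$pwp) * cover * 1000      # mm available
  cap <- (profile$fc - profile$pwp) * cover * 1000                # mm at FC
  if (sum(cap) <= 0) return(list(profile = profile, t_act = 0))
  f <- sum(paw) / sum(cap)
  demand <- min(t_pot, t_max_rate)
  t_act <- min(demand * min(1, f / stress_threshold), sum(paw))
  if (t_act > 0) {
    take <- t_act * paw / sum(paw)
    profile$theta <- profile$theta - take / (profile$thickness * 1000)
  }
  list(profile = profile, t_act = t_act)
}

#' Extract soil evaporation from the surface layer
#'
#' Supply-limited evaporation from the top layer only: the actual flux is the
#' potential demand capped at the top layer's plant-available water. No
#' staged drying curve is applied.
#'
#' @param profile A [soil_profile()].
#' @param e_pot Potential soil evaporation, mm.
#' @return List with `profile` (updated) and `e_act` (mm).
#' @export
extract_evaporation <- function(profile, e_pot) {
  if (e_pot < 0) stop("e_pot must be >= 0", call. = FALSE)
  avail <- max(0, profile$theta[1] - profile$pwp[1]) * profile$thickness[1] * 1000
  e_act <- min(e_pot, avail)
  profile$theta[1] <- profile$theta[1] - e_act / (profile$thickness[1] * 1000)
  list(profile = profile, e_act = e_act)
}

#' Crop water stress index
#'
#' \eqn{SI = 1 - T_{act}/T_{pot}}, ranging from 0 (ample water) to 1
#' (maximum stress); zero demand means zero stress.
#'
#' @param t_act Actual transpiration, mm.
#' @param t_pot Potential transpiration, mm.
#' @return Stress index in [0, 1].
#' @export
stress_index <- function(t_act, t_pot) {
  if (any(t_act < 0) || any(t_pot < t_act)) {
    stop("need 0 <= t_act <= t_pot", call. = FALSE)
  }
  ifelse(t_pot == 0, 0, 1 - t_act / t_pot)
}

#' Irrigation scheduling decision
#'
#' Refill-to-field-capacity scheduling: on scheduled days the application
#' equals the current root-zone deficit; otherwise (and always under
#' rainfed management) zero.
#'
#' @param profile A [soil_profile()].
#' @param mode `"weekly_refill"`, `"fortnightly_refill"` or `"rainfed"`.
#' @param day_index Day number since sowing (1-based).
#' @param root_depth Depth over which the deficit is computed, m.
#' @param first_irrigation_day First scheduled day (default 7 weekly,
#'   14 fortnightly).
#' @return Irrigation amount, mm.
#' @export
irrigation_decision <- function(profile, mode, day_index, root_depth = 1,
                                first_irrigation_day = NULL) {
  mode <- match.arg(mode, c("weekly_refill", "fortnightly_refill", "rainfed"))
  if (mode == "rainfed") return(0)
  interval <- if (mode == "weekly_refill") 7L else 14L
  first <- if (is.null(first_irrigation_day)) interval else as.integer(first_irrigation_day)
  if (day_index >= first && (day_index - first) %% interval == 0) {
    profile_deficit(profile, min(root_depth, sum(profile$thickness)))
  } else 0
}
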