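#' Crop-specific growth parameters
#'
#' The full parameter set needed to simulate one variety. The solar-radiation
#' extinction coefficient `k_s` is always derived from `k_par` and the leaf
#' absorptances via [kpar_to_ks()], never supplied directly.
#'
#' @param rue Radiation use efficiency, kg MJ-1.
#' @param dwr Dry matter / transpiration ratio corrected for VPD, Pa.
#' @param k_par Canopy extinction coefficient for PAR.
#' @param a_p,a_n Leaf absorptance of PAR / NIR.
#' @param sla Specific leaf area, m2 kg-1.
#' @param p Leaf-stem partitioning parameter, m2 kg-1.
#' @param rd_max Maximum root depth, m.
#' @param h_max Maximum crop height, m (stored, not used in dynamics).
#' @param t_max_rate Maximum transpiration rate, mm d-1.
#' @param t_base,t_opt,t_cutoff Cardinal temperatures, degrees C.
#' @param gdd_emerge,gdd_transition,gdd_flower,gdd_maturity Stage thermal
#'   times from sowing, degrees C d. The transition threshold marks the
#'   switch from canopy to harvestable-organ allocation, ahead of flowering.
#' @param dm_at_emergence Shoot dry matter at emergence, kg m-2.
#' @param stress_threshold Plant-available-water fraction triggering
#'   transpiration reduction.
#' @param root_fraction_initial Assimilate share to roots at emergence,
#'   declining linearly to zero at flowering.
#' @param vpd_floor Lower bound on daily VPD in the transpiration-limited
#'   growth term, Pa.
#' @param name Optional variety name.
#' @return A list with class `crop_parameters`; element `k_s` is derived.
#' @export
crop_parameters <- function(rue, dwr, k_par, a_p = 0.8, a_n = 0.2, sla, p,
                            rd_max = 1.0, h_max, t_max_rate = 9,
                            t_base = 10, t_opt = 33, t_cutoff = 45,
                            gdd_emerge, gdd_transition, gdd_flower, gdd_maturity,
                            dm_at_emergence = 0.0019, stress_threshold = 0.30,
                            root_fraction_initial = 0.25, vpd_floor = 100,
                            name = NULL) {
  pars <- list(rue = rue, dwr = dwr, k_par = k_par, a_p = a_p, a_n = a_n,
               sla = sla, p = p, rd_max = rd_max, h_max = h_max,
               t_max_rate = t_max_rate, t_base = t_base, t_opt = t_opt,
               t_cutoff = t_cutoff, gdd_emerge = gdd_emerge,
               gdd_transition = gdd_transition, gdd_flower = gdd_flower,
               gdd_maturity = gdd_maturity, dm_at_emergence = dm_at_emergence,
               stress_threshold = stress_threshold,
               root_fraction_initial = root_fraction_initial,
               vpd_floor = vpd_floor)
  pos <- setdiff(names(pars), "root_fraction_initial")
  if (any(vapply(pars[pos], function(x) !is.numeric(x) || x <= 0, logical(1)))) {
    stop("all crop parameters except root_fraction_initial must be positive numbers",
         call. = FALSE)
  }
  if (root_fraction_initial < 0 || root_fraction_initial >= 1) {
    stop("root_fraction_initial must lie in [0, 1)", call. = FALSE)
  }
  if (!(gdd_emerge < gdd_transition && gdd_transition < gdd_flower &&
        gdd_flower < gdd_maturity)) {
    stop("stage thermal times must be ordered emerge < transition < flower < maturity",
         call. = FALSE)
  }
  if (!(t_base < t_opt && t_opt < t_cutoff)) {
    stop("cardinal temperatures must satisfy t_base < t_opt < t_cutoff", call. = FALSE)
  }
  pars$k_s <- kpar_to_ks(k_par, a_p, a_n)
  pars$name <- name
  structure(pars, class = "crop_parameters")
}

#' Packaged pearl millet variety parameter sets
#'
#' Measured parameter sets for the landrace Kantana, the improved variety
#' Kangara and the hybrid Agrigreen, loaded from the flat key-value files
#' shipped with the package.
#'
#' @param name `"kantana"`, `"kangara"` or `"agrigreen"`.
#' @return A [crop_parameters()] object.
#' @export
millet_variety <- function(name = c("kantana", "kangara", "agrigreen")) {
  name <- match.arg(name)
  path <- system.file("extdata", paste0(name, ".txt"), package = "milletswb",
                      mustWork = TRUE)
  read_crop_parameters(path)
}

#' Read crop parameters from a flat key-value file
#'
#' One `key = value` pair per line; `#` starts a comment. Keys are the
#' argument names of [crop_parameters()] (`name` may be quoted).
#'
#' @param path File path.
#' @return A [crop_parameters()] object.
#' @export
read_crop_parameters <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "\\s*=\\s*")
  bad <- lengths(kv) != 2
  if (any(bad)) stop("malformed parameter line: ", lines[bad][1], call. = FALSE)
  keys <- vapply(kv, `[`, "", 1)
  vals <- vapply(kv, `[`, "", 2)
  args <- as.list(suppressWarnings(as.numeric(vals)))
  names(args) <- keys
  if ("name" %in% keys) args$name <- gsub("\"", "", vals[keys == "name"])
  unknown <- setdiff(keys, names(formals(crop_parameters)))
  if (length(unknown)) stop("unknown parameter(s): ", paste(unknown, collapse = ", "),
                            call. = FALSE)
  do.call(crop_parameters, args)
}

#' Write crop parameters to a flat key-value file
#'
#' The inverse of [read_crop_parameters()]; the derived `k_s` is omitted so
#' a round-trip re-derives it.
#'
#' @param params A [crop_parameters()].
#' @param path Output path.
#' @export
write_crop_parameters <- function(params, path) {
  keep <- setdiff(names(params), c("k_s", "name"))
  lines <- sprintf("%s = %.15g", keep, unlist(params[keep]))
  if (!is.null(params$name)) lines <- c(sprintf("name = \"%s\"", params$name), lines)
  writeLines(lines, path)
}

#' Initial crop state at sowing
#' @param params A [crop_parameters()].
#' @return A list with class `crop_state`.
#' @export
crop_state <- function(params) {
  structure(list(gdd_cum = 0, stage = "sown",
                 ldm = 0, sdm = 0, hdm = 0, rdm = 0,
                 lai = 0, root_depth = 0.05, si_today = 0),
            class = "crop_state")
}

.stages <- c("presow", "sown", "emerged", "vegetative", "reproductive", "mature")

.stage_from_gdd <- function(gdd, params) {
  if (gdd >= params$gdd_maturity) "mature"
  else if (gdd >= params$gdd_transition) "reproductive"
  else if (gdd > params$gdd_emerge) "vegetative"
  else if (gdd >= params$gdd_emerge) "emerged"
  else "sown"
}

#' Advance phenology by one day
#'
#' Accumulates thermal time and moves the development stage through the
#' variety's thresholds. Stage transitions are irreversible. A hook exists to
#' slow thermal-time accumulation under water stress
#' (`gdd_inc * (1 - si * stress_modifier)`) but ships disabled
#' (`stress_modifier = 0`).
#'
#' @param state A `crop_state`.
#' @param gdd_inc Day's thermal time, degrees C d.
#' @param params A [crop_parameters()].
#' @param si Day's stress index in [0, 1].
#' @param stress_modifier Strength of the stress slow-down (default 0 = off).
#' @return Updated `crop_state`.
#' @export
advance_phenology <- function(state, gdd_inc, params, si = 0, stress_modifier = 0) {
  if (gdd_inc < 0) stop("gdd_inc must be >= 0", call. = FALSE)
  if (si < 0 || si > 1) stop("si must lie in [0, 1]", call. = FALSE)
  state$gdd_cum <- state$gdd_cum + gdd_inc * (1 - si * stress_modifier)
  new <- .stage_from_gdd(state$gdd_cum, params)
  if (match(new, .stages) > match(state$stage, .stages)) state$stage <- new
  state
}

#' Daily dry-matter increment
#'
#' The day's production is the lesser of the radiation-limited rate
#' (\eqn{RUE \cdot FI_{RAD} \cdot R_s}) and the transpiration-limited rate
#' (\eqn{DWR \cdot T_{act} / VPD}), the daily form of the VPD-corrected
#' water-productivity relation. The VPD is floored (default 100 Pa) so very
#' humid days do not produce unbounded water-limited growth.
#'
#' @param t_act Actual transpiration, mm.
#' @param vpd Daily vapour pressure deficit, Pa.
#' @param fi_rad Fractional interception of total solar radiation.
#' @param solar_rad Incoming solar radiation, MJ m-2 d-1.
#' @param params A [crop_parameters()].
#' @return Dry-matter increment, kg m-2 d-1.
#' @export
dm_increment <- function(t_act, vpd, fi_rad, solar_rad, params) {
  if (any(c(t_act, vpd, fi_rad, solar_rad) < 0)) {
    stop("inputs must be >= 0", call. = FALSE)
  }
  dm_rad <- params$rue * fi_rad * solar_rad
  dm_water <- params$dwr * t_act / max(vpd, params$vpd_floor)
  min(dm_rad, dm_water)
}

# assimilate share to roots: linear decline from the initial fraction at
# emergence to zero at flowering
.root_share <- function(gdd, params) {
  span <- params$gdd_flower - params$gdd_emerge
  params$root_fraction_initial * max(0, min(1, (params$gdd_flower - gdd) / span))
}

#' Partition a dry-matter increment among organs
#'
#' A declining share goes to roots. Before the transition threshold the
#' shoot share enters the canopy pool, which is re-split between leaf and
#' stem through the leaf-stem partitioning relation
#' \eqn{LDM = CDM/(1 + p \cdot CDM)}, \eqn{SDM = CDM - LDM}; afterwards the
#' shoot share accrues to the harvestable (grain) pool. LAI tracks leaf mass
#' through the specific leaf area. Mass is conserved exactly.
#'
#' @param state A `crop_state` (its `gdd_cum`/`stage` decide the routing).
#' @param dm_inc Dry-matter increment, kg m-2.
#' @param params A [crop_parameters()].
#' @return Updated `crop_state`.
#' @export
partition_dm <- function(state, dm_inc, params) {
  if (dm_inc < 0) stop("dm_inc must be >= 0", call. = FALSE)
  fr <- .root_share(state$gdd_cum, params)
  state$rdm <- state$rdm + fr * dm_inc
  shoot <- (1 - fr) * dm_inc
  if (state$stage %in% c("reproductive", "mature")) {
    state$hdm <- state$hdm + shoot
  } else {
    cdm <- state$ldm + state$sdm + shoot
    state$ldm <- cdm / (1 + params$p * cdm)
    state$sdm <- cdm - state$ldm
  }
  state$lai <- update_lai(state$ldm, params$sla)
  state
}

#' Leaf area index from leaf mass
#'
#' @param ldm Leaf dry matter, kg m-2.
#' @param sla Specific leaf area, m2 kg-1.
#' @return LAI, m2 m-2.
#' @export
update_lai <- function(ldm, sla) {
  if (any(ldm < 0)) stop("ldm must be >= 0", call. = FALSE)
  if (any(sla <= 0)) stop("sla must be > 0", call. = FALSE)
  sla * ldm
}

#' Root depth from thermal time
#'
#' Linear deepening from 0.05 m (the seed zone) at emergence to the maximum
#' root depth at flowering, constant thereafter.
#'
#' @param gdd_cum Cumulative thermal time from sowing, degrees C d.
#' @param params A [crop_parameters()].
#' @return Root depth, m.
#' @export
root_depth_from_gdd <- function(gdd_cum, params) {
  if (any(gdd_cum < 0)) stop("gdd_cum must be >= 0", call. = FALSE)
  frac <- pmax(0, pmin(1, (gdd_cum - params$gdd_emerge) /
                            (params$gdd_flower - params$gdd_emerge)))
  0.05 + frac * (params$rd_max - 0.05)
}
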