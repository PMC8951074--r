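---
title: "Model structure, parameter derivation and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Model structure, parameter derivation and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(milletswb)
```

`milletswb` simulates pearl millet growth coupled to a root-zone water
balance at a daily step, ships measured parameter sets for three varieties
(the landrace Kantana, the improved Kangara, the hybrid Agrigreen), and
inverts the same process relations to derive those parameters from
destructive-harvest growth analyses. This vignette documents the model
equations and their assumptions, the parameters that matter, what the
synthetic-data generator does and does not emulate, and the numerical and
design choices made where the formulation was genuinely open.

## The daily loop

For each day the simulation proceeds in a fixed order: (1) derive ETo, VPD
and the thermal-time increment from the weather record; (2) evaluate the
irrigation rule on the current root-zone deficit; (3) infiltrate rain plus
irrigation through the layer cascade; (4) split ETo by canopy cover into
potential soil evaporation and potential transpiration; (5) extract both
from the profile, supply-limited; (6) advance phenology; (7) produce and
partition dry matter. Every flux is logged so the ledger
`P + I − R − D − E − T = ΔS` closes to 1e-9 mm each day — the conservation
tests assert exactly this.

### Atmospheric demand

Reference evapotranspiration follows the FAO-56 Penman–Monteith daily
formulation for a clipped grass surface: albedo 0.23, psychrometric
constant from site-altitude pressure, extraterrestrial radiation from
latitude and day of year, net longwave from the relative shortwave and the
actual vapour pressure, zero soil heat flux at the daily step, and a
log-profile wind adjustment when the anemometer is not at 2 m. One
numerical convention deserves mention: the relative shortwave `Rs/Rso` in
the net-longwave term is bounded to [0.3, 1.0] (the standardized-reference
convention). Without the lower bound a zero-radiation day yields a
spurious longwave *gain* and roughly half a millimetre of ETo out of thin
air; with it, an energy-free saturated day evaporates nothing. The test
suite checks the implementation against a separately coded step-by-step
worked computation on 50 randomized days to ±0.05 mm d⁻¹.

Vapour pressure deficit is computed from the daily temperature and
humidity extremes, `VPD = (es(Tmax)+es(Tmin))/2 − ea` with
`ea = (es(Tmin)·RHmax + es(Tmax)·RHmin)/200`. The saturation curve
operates in kPa; VPD is returned in Pa because the seasonal water-balance
tables and the dry-matter water ratio both use Pascal.

### Thermal time and phenology

The daily increment is `max(0, min(Tmean, 45) − 10)` °C d for pearl
millet's cardinal temperatures (base 10, optimum 33, maximum 45 °C). Days
with mean temperature at or below base contribute zero. The cap applies to
the daily mean before subtracting the base — the simplest monotone
reading, since no capping rule is specified beyond the maximum
temperature; the optimum is stored but plays no role in thermal time.
Stages advance irreversibly at the variety's thresholds: emergence
(60–64 °C d), a *transition* threshold (655–780 °C d) at which assimilate
allocation switches from canopy to harvestable organs, flowering
(832–1058 °C d) and maturity (1480–2124 °C d). We read the transition
threshold as the vegetative→reproductive partitioning switch preceding
flowering; whether it instead marks another internal node (e.g. canopy
senescence onset) cannot be resolved from the source material, so the
choice is documented rather than hidden. A hook to slow thermal-time
accumulation under water stress exists but ships disabled (modifier 0):
the mechanism is described qualitatively in the literature but no
coefficient is given, and we prefer an inert, visible hook to an invented
constant.

For parameter *derivation* the convention differs by one day:
`stage_gdd()` starts accumulating the day after sowing, so a stage reached
n days after sowing carries exactly n daily increments (emergence five days
after sowing under constant 22 °C days gives 5 × 12 = 60 °C d, the
emergence requirement). `cumulative_gdd()` itself includes its start day.

### Canopy radiation

Interception follows Beer–Bouguer, `FI = 1 − e^{−K·LAI}`. The ceptometer
measures PAR interception, so the fitted coefficient is K_PAR; the model
needs the total-solar coefficient Ks both for radiation-limited growth and
for splitting ET. The conversion removes PAR absorptance to get the
black-leaf diffuse coefficient `K_bd = K_PAR/√a_p`, forms the geometric
mean absorptance `a_s = √(a_p·a_n)` over the PAR and NIR bands, and
rescales: `Ks = K_bd·√a_s`. The printed equations for this conversion are
typeset ambiguously; the implemented reading is the only one consistent
with "geometric mean" and with the published coefficient pairs
(0.40 → 0.28, 0.42 → 0.30). With the standard absorptances (0.8, 0.2) it
collapses to `Ks = K_PAR·√0.5`. For the hybrid, 0.43·√0.5 = 0.304 rounds
to 0.30 while the published table prints 0.31; we keep the conversion and
document the one-digit discrepancy rather than fitting to it. The same
source also quotes a Ks range of 0.32–0.53 in its narrative that
contradicts its own parameter table; the table is taken as authoritative.

### Soil water

The profile is a top-down stack of buckets, by default five 0.20 m layers
of Hutton sandy clay loam to 1.0 m — the neutron-probe measurement layout.
Field capacity 0.27 and wilting point 0.13 m³ m⁻³ are package defaults
(the source prints bulk density, 1152–1506 kg m⁻³, but not FC/PWP; the
defaults are representative for the texture and configurable per layer).
Infiltration fills each layer to field capacity and cascades the excess;
drainage to field capacity is instantaneous at the daily step, consistent
with the weekly drainage events of a freely draining profile and the
absence of any published rate constant. Runoff is held at zero (flat,
bunded plots, drip irrigation below infiltrability) but kept as an
explicit ledger column so output matches the published table format.

Transpiration demand is potential transpiration capped at the crop maximum
(9 mm d⁻¹). Supply is governed by the root-zone plant-available-water
fraction `f = (θ̄ − PWP)/(FC − PWP)`: below the threshold 0.30 uptake is
reduced by `f/0.30`. This reads the published "stress index 0.30" as the
available-water fraction at which transpiration becomes supply-limited —
the reading consistent with the SWB model lineage and with a stress index
`SI = 1 − T/T_pot` spanning 0 (ample) to 1 (maximal), which is how the
garbled printed stress-index equation is interpreted here. Water is
removed from root-zone layers in proportion to each layer's available
water, never below wilting point. Soil evaporation draws on the top layer
only, capped at its available water, with no staged drying curve — a
documented simplification; none is published.

The storage-change sign convention follows `ΔS = Q_end − Q_start`; the
packaged weekly table stores its ΔS column exactly as printed, which
carries the opposite sign (±1 mm rounding), and the fixture documentation
says so.

### Dry matter production and partitioning

Daily production is `min(RUE·FI·Rs, DWR·T_act/VPD)` — radiation-limited or
transpiration-limited, whichever binds. The transpiration-limited term is
the daily form of the seasonal water-productivity relation
`DWR = DM·VPD/ET`; the VPD in the denominator is floored at 100 Pa so a
near-saturated day cannot produce unbounded water-limited growth. A
`limitation = "radiation"` switch runs the radiation branch alone, the
appropriate setting for optimally watered growth-analysis conditions.

A root share, starting at 0.25 at emergence and declining linearly to zero
at flowering, is diverted first; root mass is tracked but excluded from
above-ground outputs, because the published DWR values are themselves
adjusted upwards to account for unmeasured roots. Before the transition
threshold the shoot share enters the canopy pool, re-split every day by
`LDM = CDM/(1 + p·CDM)`, `SDM = CDM − LDM`; afterwards it accrues to
grain. Whether grain receives *all* post-transition assimilate or stems
continue growing is unspecified in the source; all-to-grain is the simpler
choice and is stated here. `LAI = SLA·LDM` holds after every update, with
a single season-mean SLA — the source notes SLA declines through the
season, so a constant value overestimates early-season leaf area slightly.
At emergence the shoot pool is seeded with 0.0019 kg m⁻² and split by the
same relation. Leaf senescence after maturity is not modelled: LAI freezes
when the simulation stops at maturity. Root depth ramps linearly from
0.05 m at emergence to the 1.0 m maximum at flowering (root depth was not
measured in the field; it was inferred from extraction depth, and a linear
thermal-time ramp is the minimal defensible law).

## Parameter derivation

All growth-analysis fits are least-squares slopes forced through the
origin, `slope = Σxy/Σx²`, with `r² = 1 − SSres/Σy²` — stated explicitly
because r² conventions differ once the origin is forced:

- **RUE**: above-ground dry matter on cumulative `FI·Rs`. A lower limit,
  since roots are excluded.
- **K_PAR**: `−log(1 − FI_PAR)` on LAI (the log-linearised interception
  law; a nonlinear refinement is deliberately out of scope).
- **p**: `SLA·CDM/LAI − 1` on CDM, which the partitioning relation makes
  equal to `p·CDM`.
- **SLA**: unweighted mean of per-harvest leaf-area/leaf-mass ratios.
- **DWR lower limit**: `AGDM·VPD/ET` at maturity, flagged as a lower bound
  (ET exceeds transpiration; AGDM excludes roots). `sweep_dwr()` exposes
  the manual upward adjustment as a scored grid — scored by Willmott's D
  against deficit observations, never auto-optimised. Note that deficit
  trajectories only discriminate DWR once supply limits uptake: under
  refill-to-field-capacity management total extraction equals ETo
  regardless of canopy state, and all candidates tie.

## The synthetic-data generator

`generate_weather()` emulates the study's semi-arid highveld summer
season: 130 days; daily mean temperature sweeping 13–32 °C along a
half-sinusoid with 1.2 °C day-to-day noise; a 12 °C mean diurnal range;
mean minimum/maximum humidities of 65/95 %, which together put the
seasonal mean VPD near 0.8 kPa as reported; clear-sky radiation of
28 MJ m⁻² d⁻¹ with cloudy-day reduction; convective rain on 30 % of days
(gamma, mean 8 mm, shape 0.8); and one 208 mm three-day storm starting on
day 95, mirroring the late-season event in the field record. These
defaults give seasonal rainfall totals of roughly 300–700 mm across seeds.
Generators are pure functions of (spec, seed): the caller's RNG stream is
saved and restored, and identical seeds give byte-identical output.

`generate_growth_trial()` runs the forward crop model under weekly refill
irrigation, samples the state every 14 days (fortnightly destructive
harvests), and perturbs LAI and the biomass pools with multiplicative
lognormal noise (errors in destructive harvests scale with magnitude);
interception is derived from the true K_PAR and noised on the logit scale,
clamped to (0, 1). Three conventions make the noiseless trial an *exact*
forward model of the derivation pipeline, so that round-trip recovery is a
machine-precision identity rather than an approximation: the forward run
uses the radiation-limited branch (optimal water), the root share is zero
(the regressions concern above-ground matter), and the emergence seed
endowment is credited to the radiation ledger at its RUE-equivalent
interception, which also stops accruing once the crop is mature. With
those conventions, noiseless derivation recovers RUE, K_PAR, p and SLA to
better than one part in 10⁶, and with 5 % noise the median relative errors
over 200 replicates stay near 2 %.

What the generator does *not* emulate: spatial rainfall structure, real
Pretoria climate statistics, instrument-specific error models,
within-season SLA drift, frost, pest or nutrient limitation. Passing the
recovery tests therefore demonstrates that the derivation pipeline inverts
the model's own relations correctly under realistic noise magnitudes — not
that the model captures every process in a real field trial.

## Problem sizes and runtime choices

The test suite simulates 220-day seasons (weather long enough for the
slowest variety, Kantana at 2124 °C d, to mature with margin), runs the
ETo oracle comparison on 50 randomized days, the climate-envelope check on
100 seeds, and the noisy-recovery study with 200 Monte-Carlo replicates
that share one forward simulation and differ only in observation noise. A
full season simulates in well under a second, and the whole suite runs in
a few seconds.

## Known limitations

- No leaf senescence, tillering, nitrogen balance, photoperiod response or
  plant-height dynamics (height is stored, unused).
- No Richards-equation flow, capillary rise, water table or salinity; the
  cascade is instantaneous.
- A single season-mean SLA.
- The grain pool receives all post-transition shoot assimilate.
- Weekly published water-balance rows are measurement ledgers, not model
  output; only the mass-balance arithmetic that links their columns is
  reproduced exactly.
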