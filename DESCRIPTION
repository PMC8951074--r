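Package: milletswb
Title: Mechanistic Crop Growth and Soil Water Balance Modelling for Pearl Millet
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Daily mechanistic simulation of pearl millet growth and the root-zone
    soil water balance in the SWB (Soil Water Balance) model tradition: FAO-56
    Penman-Monteith grass reference evapotranspiration, Beer-Bouguer canopy
    radiation interception, thermal-time phenology, dual radiation- and
    transpiration-limited dry-matter production with leaf-stem-grain
    partitioning, and a layered cascading soil water store with refill-to-field-
    capacity irrigation scheduling. Ships measured parameter sets for three
    pearl millet varieties (the landrace Kantana, the improved Kangara and the
    hybrid Agrigreen), the growth-analysis pipeline that derives those
    parameters (radiation use efficiency, canopy extinction coefficients,
    leaf-stem partitioning, specific leaf area, dry matter water ratio, stage
    thermal times, water use efficiency) from destructive-harvest trials, a
    synthetic semi-arid weather and trial generator with known ground truth,
    and the goodness-of-fit statistics (R squared, Willmott index of agreement,
    mean absolute error percentage) used to evaluate the model.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
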