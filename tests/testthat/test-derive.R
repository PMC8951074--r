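test_that("through-origin slope equals the closed form sum(xy)/sum(x^2)", {
  set.seed(5)
  x <- runif(12, 0, 300)
  y <- 0.002 * x + rnorm(12, 0, 0.01)
  f <- fit_rue(data.frame(cum_fi_rs = x, agdm = y))
  expect_equal(f$estimate, sum(x * y) / sum(x^2), tolerance = 1e-14)
  expect_equal(f$n, 12)
  expect_lte(f$r_squared, 1)
})

test_that("RUE fitting recovers exact lines and the two-point worked example", {
  x <- c(50, 120, 400, 900)
  f <- fit_rue(data.frame(cum_fi_rs = x, agdm = 0.002 * x))
  expect_equal(f$estimate, 0.002, tolerance = 1e-14)
  expect_equal(f$r_squared, 1)
  two <- fit_rue(data.frame(cum_fi_rs = c(100, 200), agdm = c(0.19, 0.41)))
  expect_equal(two$estimate, (100 * 0.19 + 200 * 0.41) / (100^2 + 200^2))
  expect_equal(round(two$estimate, 5), 0.00202)
  expect_error(fit_rue(data.frame(cum_fi_rs = c(0, 0), agdm = c(0, 0))),
               "degenerate")
})

test_that("extinction coefficient fitting inverts the interception law", {
  lai <- c(0.5, 2, 4, 8)
  f <- fit_kpar(lai, fractional_interception(0.42, lai))
  expect_equal(f$estimate, 0.42, tolerance = 1e-12)
  expect_equal(f$r_squared, 1)
  # single-pair consistency with the landrace peak measurement
  expect_equal(-log(1 - 0.978) / 9.59, 0.398, tolerance = 1e-3)
  expect_error(fit_kpar(c(1, 2), c(0.5, 1)), "linearised")
})

test_that("partitioning parameter fitting inverts the leaf-stem relation", {
  p_true <- 2.76
  sla <- 22.49
  cdm <- c(0.2, 0.6, 1.1, 1.8)
  ldm <- cdm / (1 + p_true * cdm)
  f <- fit_partition_p(cdm, sla, lai = sla * ldm)
  expect_equal(f$estimate, p_true, tolerance = 1e-12)
  # hand-checked transform: cdm=1, p=2, sla=20 gives y = 2 = p * cdm
  ldm1 <- 1 / (1 + 2 * 1)
  expect_equal(20 * 1 / (20 * ldm1) - 1, 2)
  # zero-slope data fits zero
  f0 <- fit_partition_p(cdm, sla, lai = sla * cdm)
  expect_equal(f0$estimate, 0)
})

test_that("season-mean SLA averages per-sampling ratios, skipping zero leaf mass", {
  expect_equal(mean_sla(c(4.498, 2.249), c(0.2, 0.1)), 22.49)
  expect_equal(mean_sla(c(24, 40, 48), c(1, 2, 3)), 20)
  expect_equal(mean_sla(5, 0.25), 20)
  expect_warning(got <- mean_sla(c(24, 5), c(1, 0)), "zero leaf mass")
  expect_equal(got, 24)
  expect_error(suppressWarnings(mean_sla(1, 0)), "no sampling")
})

test_that("DWR lower limit follows the seasonal water-productivity relation", {
  expect_equal(dwr_lower_limit(1.0, 200, 1000), 5)
  expect_equal(dwr_lower_limit(1.0, 200, 2000), 10)  # linear in VPD
  expect_equal(dwr_lower_limit(0, 200, 1000), 0)
  # the landrace season: 6.14 kg m-2 biomass, 670 mm ET, 780 Pa VPD
  expect_equal(dwr_lower_limit(6.14, 670, 780), 7.148, tolerance = 1e-3)
})

test_that("stage thermal times are read off the cumulative curve at phenology dates", {
  w <- weather_series(seq(as.Date("2018-01-01"), by = 1, length.out = 60),
                      35, 25, 90, 50, 20, 1, 0)  # 20 C d per day
  got <- stage_gdd(list(sowing = "2018-01-01", emergence = "2018-01-05",
                        flowering = "2018-02-15"), w)
  expect_equal(unname(got["sowing"]), 0)
  expect_equal(unname(got["emergence"]), 80)   # 4 days after sowing
  expect_equal(unname(got["flowering"]), 900)  # 45 days after sowing
  # constant 22 C days: emergence after 5 days matches the 60 C d requirement
  w22 <- weather_series(seq(as.Date("2018-01-01"), by = 1, length.out = 10),
                        22, 22, 90, 50, 20, 1, 0)
  got22 <- stage_gdd(list(sowing = "2018-01-01", emergence = "2018-01-06"), w22)
  expect_equal(unname(got22["emergence"]), 60)
  expect_error(stage_gdd(list(sowing = "2017-01-01"), w), "coverage")
})

test_that("water use efficiency converts yield per mm to kg per cubic metre", {
  expect_equal(wue(0.934, 653), 1.430, tolerance = 1e-3)
  expect_equal(wue(0, 500), 0)
  expect_equal(wue(1, 250), 2 * wue(1, 500))
  expect_error(wue(1, 0), "seasonal_et")
})

test_that("the noiseless pipeline recovers the generator's truth to 1e-6", {
  w <- test_weather_long()
  tri <- generate_growth_trial(trial_spec(noise_cv = 0), w)
  d <- derive_parameters(tri$observations)
  truth <- tri$truth
  expect_lt(abs(d$rue$estimate - truth$rue) / truth$rue, 1e-6)
  expect_lt(abs(d$k_par$estimate - truth$k_par) / truth$k_par, 1e-6)
  expect_lt(abs(d$p$estimate - truth$p) / truth$p, 1e-6)
  expect_lt(abs(d$sla - truth$sla) / truth$sla, 1e-6)
  expect_equal(d$rue$r_squared, 1, tolerance = 1e-12)
  # chained conversion lands on the printed solar extinction value
  ks <- kpar_to_ks(d$k_par$estimate, truth$a_p, truth$a_n)
  expect_equal(ks, 0.40 * sqrt(0.5), tolerance = 1e-6)
  expect_equal(round(ks, 2), 0.28)
})

test_that("the DWR sweep ranks candidates by agreement with deficit observations", {
  w <- test_weather_long()
  kan <- millet_variety("kantana")
  # rainfed drydown: deficits only discriminate DWR once supply limits uptake
  sim <- simulate_season(kan, w, management = "rainfed")
  fcmm <- sum(sim$soil$fc * sim$soil$thickness * 1000)
  obs <- data.frame(day = seq(10, nrow(sim$trace), by = 10),
                    deficit = fcmm - sim$trace$storage_end[
                      seq(10, nrow(sim$trace), by = 10)])
  sweep <- sweep_dwr(c(3, 8, 15.8), kan, obs, weather = w,
                     management = "rainfed")
  expect_equal(nrow(sweep), 3)
  expect_true(all(sweep$willmott_d <= 1 & sweep$willmott_d >= 0))
  # truth reproduces its own deficits perfectly and beats the worst candidate
  expect_equal(sweep$willmott_d[sweep$dwr == 15.8], 1, tolerance = 1e-12)
  expect_gt(sweep$willmott_d[sweep$dwr == 15.8], min(sweep$willmott_d))
})
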