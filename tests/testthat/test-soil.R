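test_that("mass-balance ET reproduces printed weekly ledger rows", {
  expect_equal(et_from_balance(26, 0, 0, 0, 315, 328), 13)
  expect_equal(et_from_balance(209, 0, 0, 88, 357, 434), 44)
  expect_equal(et_from_balance(0, 0, 0, 0, 300, 300), 0)
  expect_warning(et_from_balance(0, 0, 0, 0, 300, 350), "negative ET")
  expect_error(et_from_balance(-1, 0, 0, 0, 300, 300), ">= 0")
})

test_that("infiltration cascade conserves water and drains a full profile", {
  full <- soil_profile()
  res <- infiltrate_cascade(full, 15)
  expect_equal(res$drainage, 15)
  expect_equal(res$profile$theta, full$theta)

  one <- soil_profile(thickness = 0.2, fc = 0.30, pwp = 0.10, theta = 0.25)
  res <- infiltrate_cascade(one, 20)
  expect_equal(res$profile$theta, 0.30)
  expect_equal(res$drainage, 10)

  dry <- soil_profile(theta = 0.18)
  res0 <- infiltrate_cascade(dry, 0)
  expect_equal(res0$drainage, 0)
  expect_equal(res0$profile$theta, dry$theta)
  # conservation for arbitrary amounts
  for (amt in c(3, 47.5, 200)) {
    r <- infiltrate_cascade(dry, amt)
    gain <- profile_storage(r$profile) - profile_storage(dry)
    expect_equal(gain + r$drainage, amt, tolerance = 1e-9)
  }
})

test_that("infiltration is path-independent at the daily step", {
  dry <- soil_profile(theta = c(0.14, 0.16, 0.20, 0.22, 0.27))
  once <- infiltrate_cascade(dry, 60)
  split <- infiltrate_cascade(infiltrate_cascade(dry, 25)$profile, 35)
  expect_equal(once$profile$theta, split$profile$theta, tolerance = 1e-12)
  expect_equal(once$drainage,
               infiltrate_cascade(dry, 25)$drainage + split$drainage)
})

test_that("root-zone deficit integrates clamped layer deficits pro-rata", {
  expect_equal(profile_deficit(soil_profile()), 0)
  p <- soil_profile(theta = 0.22)
  expect_equal(profile_deficit(p, 1.0), 50)
  expect_equal(profile_deficit(p, 0.5), 25)  # half of layer 3 pro-rata
  wet <- soil_profile(theta = c(0.30, 0.22, 0.22, 0.22, 0.22))
  expect_equal(profile_deficit(wet, 1.0), 40)  # super-FC layer contributes 0
  expect_error(profile_deficit(p, 2), "depth")
})

test_that("ET partitioning splits by canopy cover and sums back", {
  expect_equal(partition_et(6, 0), list(e_pot = 6, t_pot = 0))
  expect_equal(partition_et(6, 0.5), list(e_pot = 3, t_pot = 3))
  nearly <- partition_et(6, 1 - 1e-9)
  expect_equal(nearly$t_pot, 6, tolerance = 1e-8)
  for (fi in c(0, 0.3, 0.7, 0.99)) {
    pe <- partition_et(5.5, fi)
    expect_equal(pe$e_pot + pe$t_pot, 5.5)
  }
})

test_that("transpiration extraction is demand-, supply- and stress-limited", {
  fc <- soil_profile()
  expect_equal(extract_transpiration(fc, 5, 1)$t_act, 5)
  expect_equal(extract_transpiration(fc, 12, 1, t_max_rate = 9)$t_act, 9)
  wilted <- soil_profile(theta = 0.13)
  expect_equal(extract_transpiration(wilted, 5, 1)$t_act, 0)
  # f = 0.15 against threshold 0.30 halves the demand of 4 mm
  p15 <- soil_profile(theta = 0.13 + 0.15 * (0.27 - 0.13))
  expect_equal(extract_transpiration(p15, 4, 1, stress_threshold = 0.30)$t_act,
               2, tolerance = 1e-12)
  # theta never drops below wilting point even under huge demand
  r <- extract_transpiration(soil_profile(theta = 0.15), 500, 1,
                             t_max_rate = 500)
  expect_true(all(r$profile$theta >= r$profile$pwp - 1e-12))
  expect_error(extract_transpiration(fc, 5, 0), "root_depth")
})

test_that("soil evaporation draws only on the surface layer", {
  top_dry <- soil_profile(theta = c(0.13, 0.27, 0.27, 0.27, 0.27))
  expect_equal(extract_evaporation(top_dry, 5)$e_act, 0)
  # top layer holding 3 mm above wilting supplies only 3 of 5 mm demanded
  p3 <- soil_profile(theta = c(0.13 + 3 / 200, 0.27, 0.27, 0.27, 0.27))
  r <- extract_evaporation(p3, 5)
  expect_equal(r$e_act, 3, tolerance = 1e-12)
  expect_equal(r$profile$theta[1], 0.13, tolerance = 1e-12)
  expect_equal(r$profile$theta[-1], rep(0.27, 4))
  expect_equal(extract_evaporation(soil_profile(), 0)$e_act, 0)
})

test_that("stress index spans ample water to full stress", {
  expect_equal(stress_index(4, 4), 0)
  expect_equal(stress_index(0, 4), 1)
  expect_equal(stress_index(2, 4), 0.5)
  expect_equal(stress_index(0, 0), 0)  # no demand, no stress
  expect_error(stress_index(5, 4), "t_act")
})

test_that("irrigation rules refill to field capacity only on schedule", {
  p <- soil_profile(theta = 0.22)  # deficit 50 mm over 1 m
  expect_equal(irrigation_decision(p, "rainfed", 7), 0)
  expect_equal(irrigation_decision(p, "weekly_refill", 7), 50)
  expect_equal(irrigation_decision(p, "weekly_refill", 14), 50)
  expect_equal(irrigation_decision(p, "weekly_refill", 8), 0)
  expect_equal(irrigation_decision(p, "fortnightly_refill", 7), 0)
  expect_equal(irrigation_decision(p, "fortnightly_refill", 14), 50)
  expect_equal(irrigation_decision(p, "fortnightly_refill", 5,
                                   first_irrigation_day = 5), 50)
})
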