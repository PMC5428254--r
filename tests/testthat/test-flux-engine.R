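test_that("suckled milk declines linearly from 10 to the 5 kg/d weaning plateau", {
  expect_equal(suckled_milk(0), 10)
  expect_equal(suckled_milk(100), 8)
  expect_equal(suckled_milk(250), 5)
  expect_equal(suckled_milk(400), 5) # floored at weaning
  expect_equal(suckled_milk(NA), 0) # no calf
  expect_error(suckled_milk(-1), "non-negative")
})

test_that("metabolizable energy is 82% of digestible energy", {
  expect_equal(me_from_de(100), 82)
  en <- dry_matter_intake(600, 4, 0, default_feed()$grass)
  expect_equal(en$me / en$de, 0.82)
})

test_that("maintenance-only intake equals the hand-evaluated default formula", {
  en <- dry_matter_intake(600, 0, 0, default_feed()$grass)
  # independent hand evaluation of the documented defaults:
  # 0.53 MJ/kg^0.75 maintenance, grass ME density 10.5 MJ/kg DM
  expect_equal(en$me_requirement, 0.53 * 600^0.75)
  expect_equal(en$dmi, 0.53 * 600^0.75 / 10.5)
})

test_that("energy requirement is strictly increasing in milk yield", {
  lo <- dry_matter_intake(600, 4, 0, default_feed()$grass)
  hi <- dry_matter_intake(600, 8, 0, default_feed()$grass)
  expect_gt(hi$me_requirement, lo$me_requirement)
  expect_gt(
    dry_matter_intake(600, 0, 250, default_feed()$grass)$me_requirement,
    dry_matter_intake(600, 0, 0, default_feed()$grass)$me_requirement
  )
  expect_error(
    dry_matter_intake(600, 0, 0, default_feed(
      grass = list(me_mj_per_kg_dm = 0))$grass),
    "positive"
  )
})

test_that("pasture drinking water rises by exactly 0.1 kg per kg body weight", {
  base <- list(t_av = 15, t_min = 8, rh = 75, precip = 2, keeping = "pasture",
               dmi = 11, milk_kg = 5, soil_water = 50)
  d600 <- do.call(drinking_water, c(base, list(bw = 600)))
  d700 <- do.call(drinking_water, c(base, list(bw = 700)))
  expect_equal(d700$drinking_kg - d600$drinking_kg, 10)
})

test_that("stall drinking water at the centering values equals the intercept", {
  co <- default_coefficients()
  st <- co$drinking_stall
  d <- drinking_water(t_av = 0, t_min = st$center_t_min, rh = st$center_rh,
                      precip = 0, keeping = "stall", dmi = st$center_dmi,
                      milk_kg = st$center_milk, bw = 600, soil_water = NA)
  expect_equal(d$drinking_kg, st$intercept_kg)
  expect_equal(d$adhering_rain_kg, 0)
  expect_equal(d$dew_kg, 0)
})

test_that("adhering water is zero without rain and with the dew coefficient off", {
  co <- default_coefficients(list(drinking_pasture = list(dew_max_kg = 0)))
  d <- drinking_water(15, 8, 95, precip = 0, keeping = "pasture", dmi = 11,
                      milk_kg = 5, bw = 600, soil_water = 50, coeffs = co)
  expect_equal(d$adhering_rain_kg + d$dew_kg, 0)
})

test_that("drinking-water branch contracts hold", {
  expect_error(
    drinking_water(15, 8, 75, 0, "pasture", 11, 5, 600, soil_water = NA),
    "soil_water"
  )
  expect_error(
    drinking_water(15, 8, 75, 0, "outdoors", 11, 5, 600, 50),
    "keeping"
  )
  expect_warning(
    d <- drinking_water(-30, -80, 20, 0, "stall", 2, 0, 600, NA),
    "clipped"
  )
  expect_equal(d$drinking_kg, 0)
})

test_that("respiratory water splits exactly 2/3 oral to 1/3 nasal", {
  r <- respiration_fluxes(t_av = c(-5, 10, 25), vp = c(3, 9, 20),
                          rh = c(70, 75, 65), bw = 600)
  expect_equal(r$m_oral / r$m_nasal, rep(2, 3))
  expect_true(all(r$m_vapor_in >= 0))
})

test_that("inhaled vapor vanishes at zero ambient vapor pressure", {
  r <- respiration_fluxes(10, vp = 0, rh = 0, bw = 600)
  expect_equal(r$m_vapor_in, 0)
  expect_gt(r$m_oral, 0) # exhalation still saturated
})

test_that("respiration warns outside the validated temperature range", {
  expect_warning(respiration_fluxes(41, 10, 50, 600), "validated range")
  expect_warning(respiration_fluxes(-13, 1, 50, 600), "validated range")
  expect_error(respiration_fluxes(20, 10, rh = 101, bw = 600), "100")
})

test_that("transcutaneous vapor matches its documented form and is monotone in T", {
  # hand evaluation: area 0.14*600^0.57 m2, flux 8*exp(0.085*20) W/m2,
  # latent heat 2.43 MJ/kg, 55.51 mol O per kg
  expected <- 0.14 * 600^0.57 * 8 * exp(0.085 * 20) * 86400 / 2.43e6 * 55.51
  expect_equal(transcutaneous_vapor(20, 600), expected)
  expect_gt(transcutaneous_vapor(25, 600), transcutaneous_vapor(15, 600))
  co <- default_coefficients(list(transcutaneous = list(e0_w_per_m2 = 0)))
  expect_equal(transcutaneous_vapor(20, 600, co), 0)
})

test_that("bound O, CO2, products and urea follow the documented stoichiometry", {
  zero <- co2_and_products(list(dmi = 0, me = 0), 0.72, 0.15, 0, 0)
  expect_equal(unlist(zero), c(m_co2 = 0, m_products = 0, m_bO = 0,
                               m_urea = 0))

  en <- list(dmi = 12, me = 120)
  g <- co2_and_products(en, 0.72, 0.15, milk_kg = 8, gravidity_day = 0)
  # hand evaluation: 12 kg DM * 0.72 digested * 20 mol O per kg
  expect_equal(g$m_bO, 12 * 0.72 * 20)
  # CO2 counted as 2 mol O per mol CO2 at RQ 0.95 and 2.2197 mol O2/MJ
  expect_equal(g$m_co2, 2 * 0.95 * 2.2197 * 120 - g$m_products)
  expect_error(co2_and_products(en, 1.2, 0.15, 0, 0), "digestibility")
})

test_that("balance closure sets the residual by subtraction and closes O exactly", {
  fl <- balanced_fluxes()
  water_in <- fl$m_vapor + fl$m_fw + fl$m_dw + fl$m_metabolic
  other <- fl$m_oral + fl$m_nasal + fl$m_cutan + fl$m_milk
  expect_equal(fl$m_residual_water, water_in - other)

  s_in <- fl$m_air + fl$m_vapor + fl$m_bO + fl$m_fw + fl$m_dw
  s_out <- fl$m_co2 + fl$m_oral + fl$m_nasal + fl$m_cutan + fl$m_milk +
    fl$m_products + fl$m_urea + fl$m_residual_water
  expect_lt(abs(s_in - s_out) / s_in, 1e-9)
})

test_that("losses exceeding intake raise an error naming the dominating flux", {
  expect_error(
    balanced_fluxes(m_fw = 10, m_dw = 10, m_vapor = 0, m_milk = 900,
                    m_oral = 10, m_nasal = 5, m_cutan = 20),
    "milk"
  )
  expect_error(
    close_balances(data.frame(m_air = 1)),
    "missing flux columns"
  )
})
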