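test_that("water vapor pressure matches the hand-evaluated fit", {
  # frozen from independent evaluation of the published fit
  expect_equal(water_vapor_pressure(298.15, 35), 0.03065529, tolerance = 1e-6)
  # salinity dependence is exactly exp(0.000544 * dS)
  expect_equal(water_vapor_pressure(298.15, 0) / water_vapor_pressure(298.15, 35),
               exp(0.000544 * 35))
  # monotone increasing in temperature across the valid range
  Tgrid <- seq(271, 319, by = 1)
  expect_true(all(diff(water_vapor_pressure(Tgrid, 35)) > 0))
  expect_error(water_vapor_pressure(25, 35), "kelvin")
  expect_error(water_vapor_pressure(298, 60), "salinity")
})

test_that("equilibrator pCO2 follows the dry-air dilution correction", {
  expect_equal(pco2_equilibrator(400, 0, 1, 0), 400)
  expect_equal(pco2_equilibrator(400, 0.02, 1, 0.03), 400 / 0.98 * 0.97)
  expect_equal(pco2_equilibrator(400, 0, 1, 1), 0)  # f = P_eq degenerate limit
  expect_error(pco2_equilibrator(400, 1, 1, 0.03), "xH2O")
})

test_that("temperature correction is an exact exponential in SST - T_eq", {
  expect_equal(pco2_temperature_correction(350, 20, 20), 350)
  expect_equal(pco2_temperature_correction(350, 21, 20), 350 * exp(0.0423))
  # +1 then -1 degree returns the input
  once <- pco2_temperature_correction(350, 21, 20)
  expect_equal(pco2_temperature_correction(once, 20, 21), 350)
  expect_error(pco2_temperature_correction(350, 40, 20), "check units")
})

test_that("Schmidt numbers reproduce the published quartic", {
  expect_equal(schmidt_number(20, "CO2"), 668, tolerance = 1e-3)
  # strictly decreasing over 0-30 C for both gases
  Tgrid <- seq(0, 30, by = 0.5)
  expect_true(all(diff(schmidt_number(Tgrid, "CO2")) < 0))
  expect_true(all(diff(schmidt_number(Tgrid, "CH4")) < 0))
  expect_error(schmidt_number(20, "N2O"))
  expect_error(schmidt_number(60, "CO2"), "fit range")
})

test_that("transfer velocity is the quadratic wind law normalized at Sc 660", {
  u <- c(0, 2, 7.31, 12)
  expect_equal(gas_transfer_velocity(u, 660), 0.251 * u^2)
  expect_equal(gas_transfer_velocity(7.31, 660), 13.4125, tolerance = 1e-4)
  expect_equal(gas_transfer_velocity(0, 700), 0)
  # Sc scaling: quadrupling Sc halves k
  expect_equal(gas_transfer_velocity(5, 4 * 660),
               gas_transfer_velocity(5, 660) / 2)
  expect_error(gas_transfer_velocity(-1, 660), ">= 0")
})

test_that("equilibrium CH4 declines with temperature and scales with ppb", {
  Tgrid <- seq(0, 30, by = 1)
  ceq <- ch4_equilibrium_concentration(Tgrid, 35, 1900)
  expect_true(all(diff(ceq) < 0))  # warmer water holds less methane
  expect_true(all(ceq > 0))
  expect_equal(ch4_equilibrium_concentration(20, 35, 3800),
               2 * ch4_equilibrium_concentration(20, 35, 1900))
  expect_equal(ch4_equilibrium_concentration(20, 35, 0), 0)
  # plausible magnitude at modern atmospheric CH4: ~2-3 nmol per litre
  expect_gt(ch4_equilibrium_concentration(15, 34, 1900), 1.5)
  expect_lt(ch4_equilibrium_concentration(15, 34, 1900), 4)
})

test_that("CH4 flux converts cm/h x nmol/l to areal units correctly", {
  f <- ch4_flux(10, 2, 1)  # k = 10 cm/h, delta = 1 nmol/l
  expect_equal(f$umol_m2_h, 0.1)
  expect_equal(f$mmol_m2_y, 0.8766)
  expect_equal(f$mmol_m2_d, 0.1 * 24 / 1000)
  # zero at equilibrium, odd in the concentration difference
  expect_equal(ch4_flux(10, 2, 2)$mmol_m2_y, 0)
  expect_equal(ch4_flux(10, 1, 2)$mmol_m2_y, -ch4_flux(10, 3, 2)$mmol_m2_y)
})

test_that("CO2 flux is linear and sign-follows the pCO2 difference", {
  kh <- co2_solubility(20, 35)
  expect_gt(kh, 0.025)  # published fit gives ~0.033 mol/l/atm at 20 C, S 35
  expect_lt(kh, 0.040)
  expect_equal(co2_flux(10, kh, 0)$mmol_m2_y, 0)
  expect_lt(co2_flux(10, kh, -55.3)$mol_m2_y, 0)  # ocean uptake is negative
  expect_equal(co2_flux(10, kh, -20)$mmol_m2_y,
               -co2_flux(10, kh, 20)$mmol_m2_y)
  expect_equal(co2_flux(20, kh, 20)$mmol_m2_y,
               2 * co2_flux(10, kh, 20)$mmol_m2_y)
})

test_that("saturation percentage is the water/equilibrium ratio", {
  expect_equal(saturation_pct(2, 2), 100)
  expect_equal(saturation_pct(2.2, 2), 110)
  # inverse property
  expect_equal(saturation_pct(2.2, 2) / 100 * 2, 2.2)
  expect_error(saturation_pct(2, 0), "positive")
})

test_that("unit round trips are exact", {
  # cm/h <-> m/d
  k_cm_h <- 13.41
  expect_equal(k_cm_h / 100 * 24 * 100 / 24, k_cm_h)
  # per-day <-> per-year through the flux table
  f <- ch4_flux(10, 3, 2)
  expect_equal(f$mmol_m2_d * 365.25, f$mmol_m2_y, tolerance = 1e-3)
  expect_equal(f$mmol_m2_y / 8.766 * 1000, f$umol_m2_h * 1000)
})

test_that("underway processing reproduces generator ground truth exactly", {
  cfg <- scenario_config(seed = 21, n_underway = 60)
  uw <- generate_underway(cfg)
  out <- process_underway(uw)
  expect_equal(out$f_ch4_mmol_m2_y, uw$true_f_ch4_mmol_m2_y, tolerance = 1e-9)
  expect_equal(out$f_co2_mol_m2_y, uw$true_f_co2_mol_m2_y, tolerance = 1e-9)
  expect_equal(out$saturation_pct, uw$true_saturation_pct, tolerance = 1e-9)
  # independent spot check of one record through the formula chain
  r <- out[17, ]
  f <- exp(24.4543 - 6745.09 / r$t_eq_k - 4.8489 * log(r$t_eq_k / 100) -
             0.000544 * r$S)
  pco2_eq <- r$xco2_umol_mol / (1 - r$xh2o_mol_frac) * (r$p_eq_atm - f)
  pco2_w <- pco2_eq * exp(0.0423 * (r$SST - (r$t_eq_k - 273.15)))
  expect_equal(r$pco2_water_uatm, pco2_w, tolerance = 1e-9)
  expect_equal(r$k_ch4_cm_h,
               0.251 * r$wind_m_s^2 * (r$sc_ch4 / 660)^-0.5,
               tolerance = 1e-12)
})
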