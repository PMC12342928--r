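test_that("pure-endmember sections reproduce endmember properties exactly", {
  n_st <- 3
  prof <- array(0, dim = c(n_st, 2, 2))
  prof[, , 1] <- 1  # endmember 1 everywhere
  cfg <- scenario_config(seed = 1, n_stations = n_st, depths = c(5, 50),
                         mixing_profile = prof,
                         noise_sd = c(T = 0, S = 0, O = 0, P = 0, N = 0,
                                      Si = 0, ch4 = 0))
  sec <- generate_section(cfg)
  em <- cfg$endmembers$properties
  for (p in colnames(em)) {
    expect_equal(sec$samples[[p]], rep(em[1, p], n_st * 2),
                 ignore_attr = TRUE)
  }
  expect_equal(sec$samples$ch4_nmol_l,
               rep(unname(cfg$ch4_endmember[1]), n_st * 2))
})

test_that("a noiseless 50/50 mixture has the arithmetic-mean salinity", {
  prof <- array(0.5, dim = c(1, 1, 2))
  cfg <- scenario_config(seed = 1, n_stations = 1, depths = 5,
                         mixing_profile = prof,
                         noise_sd = c(T = 0, S = 0, O = 0, P = 0, N = 0,
                                      Si = 0, ch4 = 0))
  sec <- generate_section(cfg)
  # endmember salinities 35.1 and 33.2 -> 34.15
  expect_equal(sec$samples$S, 34.15)
})

test_that("section generation is bit-identical under the same seed", {
  cfg <- scenario_config(seed = 17, n_stations = 4, depths = c(5, 50))
  expect_identical(generate_section(cfg), generate_section(cfg))
  uw <- generate_underway(cfg)
  expect_identical(uw, generate_underway(cfg))
  # different seeds decorrelate
  cfg2 <- scenario_config(seed = 18, n_stations = 4, depths = c(5, 50))
  expect_false(identical(generate_section(cfg)$samples,
                         generate_section(cfg2)$samples))
})

test_that("non-simplex mixing profiles are rejected with a location", {
  prof <- array(0.6, dim = c(2, 1, 2))  # sums to 1.2
  expect_error(
    scenario_config(seed = 1, n_stations = 2, depths = 5,
                    mixing_profile = prof),
    "station 1 depth 5")
  prof2 <- array(c(1.2, -0.2), dim = c(1, 1, 2))
  expect_error(
    scenario_config(seed = 1, n_stations = 1, depths = 5,
                    mixing_profile = prof2),
    "simplex")
})

test_that("tracer simulation produces exact counts when noise is off", {
  inc <- generate_tracer_incubations(true_k = 0.01, ch4 = 3, t = 2,
                                     dpm_total = 1e5, seed = 1,
                                     background_dpm = 0, noise = FALSE)
  live <- inc[!inc$is_control, ]
  expect_equal(live$dpm_product, rep(2000, 3))
  expect_equal(inc$dpm_product[inc$is_control], 0)
  # true_k = 0 -> background only
  inc0 <- generate_tracer_incubations(true_k = 0, ch4 = 3, seed = 1,
                                      background_dpm = 40, noise = FALSE)
  expect_equal(unique(inc0$dpm_product), 40)
  # infeasible turnover rejected
  expect_error(generate_tracer_incubations(true_k = 0.6, ch4 = 3, t = 2),
               "outside \\[0, 1\\]")
})

test_that("counting noise has the configured Poisson-like moments", {
  inc <- generate_tracer_incubations(true_k = 0.02, ch4 = 3, seed = 55,
                                     n_reps = 10000, background_dpm = 0)
  live <- inc$dpm_product[!inc$is_control]
  mu <- 0.02 * 2 * 1e5
  expect_lt(abs(mean(live) - mu) / mu, 0.005)
  expect_lt(abs(sd(live) - sqrt(mu)) / sqrt(mu), 0.05)
})

test_that("underway transects honor limiting cases and gradients", {
  cfg <- scenario_config(seed = 9, n_underway = 30, wind_mean = 0,
                         wind_sd = 0)
  uw <- generate_underway(cfg)
  # zero wind everywhere -> all true fluxes zero
  expect_equal(uw$true_f_ch4_mmol_m2_y, rep(0, 30))
  expect_equal(uw$true_f_co2_mol_m2_y, rep(0, 30))
  # no equilibrator warming -> temperature correction is identity
  uw2 <- generate_underway(scenario_config(seed = 9, n_underway = 10),
                           eq_warming = 0)
  out2 <- process_underway(uw2)
  expect_equal(out2$pco2_water_uatm, out2$pco2_eq_uatm)
  # monotone latitude grid and configured endpoint gradients
  expect_true(all(diff(uw$lat) < 0))
  expect_equal(uw$SST[c(1, 30)], c(16.8, 30.2))
  expect_equal(uw$ch4_water_nmol_l[c(1, 30)], c(6.11, 5.15))
})

test_that("amendment series follow baseline, lag, and clipping rules", {
  tt <- seq(0, 12, by = 2)
  # noiseless: treatment flat until the lag, then linear at `rate`
  am <- generate_amendment_timeseries(5, 107 / 12, 0, tt, noise_sd = 0,
                                      seed = 1)
  trt <- am[am$treatment == "amended" & am$replicate == 1, ]
  expect_equal(trt$ch4_nmol_l, 5 + 107 / 12 * tt)
  expect_equal(trt$ch4_nmol_l[trt$t_days == 12] - trt$ch4_nmol_l[1], 107)
  am8 <- generate_amendment_timeseries(5, 8, 8, tt, noise_sd = 0, seed = 1)
  trt8 <- am8[am8$treatment == "amended" & am8$replicate == 1, ]
  expect_equal(trt8$ch4_nmol_l[trt8$t_days <= 8], rep(5, 5))
  # zero rate: treatment indistinguishable from control
  am0 <- generate_amendment_timeseries(5, 0, 0, tt, noise_sd = 1, seed = 2)
  t_end <- am0[am0$t_days == 12, ]
  tst <- t.test(ch4_nmol_l ~ treatment, data = t_end)
  expect_gt(tst$p.value, 0.01)
  # negative concentrations clip at zero with a flag
  expect_warning(
    amc <- generate_amendment_timeseries(0.1, 0, 0, tt, noise_sd = 5,
                                         seed = 3),
    "clipped")
  expect_true(all(amc$ch4_nmol_l >= 0))
  expect_true(any(amc$clipped))
})
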