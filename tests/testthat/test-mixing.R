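test_that("dilution line interpolates linearly between endmembers", {
  m <- dilution_model(33.2, 6.11, 35.1, 5.15)
  expect_equal(as.numeric(dilution_predict(m, 33.2)), 6.11)
  expect_equal(as.numeric(dilution_predict(m, 35.1)), 5.15)
  expect_equal(as.numeric(dilution_predict(m, 34.15)), 5.63)
  # midpoint equals mean of endpoints
  expect_equal(as.numeric(dilution_predict(m, (33.2 + 35.1) / 2)),
               (6.11 + 5.15) / 2)
  # exact linearity in S
  s <- seq(33.2, 35.1, length.out = 7)
  pred <- as.numeric(dilution_predict(m, s))
  expect_equal(diff(pred, differences = 2), rep(0, 5), tolerance = 1e-12)
  expect_error(dilution_model(34, 6, 34, 5), "equal")
  expect_warning(dilution_predict(m, 36), "extrapolated")
})

test_that("residuals vanish on the line and recover an imposed anomaly", {
  m <- dilution_model(33.2, 6.11, 35.1, 5.15)
  s <- seq(33.2, 35.1, length.out = 11)
  on_line <- as.numeric(dilution_predict(m, s))
  out <- dilution_residuals(m, s, on_line)
  expect_equal(out$residuals$residual, rep(0, 11), tolerance = 1e-12)

  # synthetic section with a -0.3 nmol/l consumption anomaly at interior
  # stations; endpoints stay conservative so the fitted line is unbiased
  n_st <- 21
  anom <- matrix(-0.3, n_st, 1)
  anom[c(1, n_st), 1] <- 0
  cfg <- scenario_config(seed = 31, n_stations = n_st, depths = 5,
                         production_anomaly = anom)
  sec <- generate_section(cfg)
  surf <- sec$samples
  mod <- dilution_model_from_extremes(surf$S, surf$ch4_nmol_l)
  res <- dilution_residuals(mod, surf$S, surf$ch4_nmol_l, lat = surf$lat)
  interior <- res$residuals$residual[-c(1, n_st)]
  expect_lt(abs(mean(interior) - (-0.3)), 0.1)
  expect_gt(res$summary$frac_negative, 0.8)
  expect_true(!is.null(res$summary$by_band))
})

test_that("conservative synthetic mixtures give residuals centred on zero", {
  cfg <- scenario_config(seed = 32, n_stations = 40, depths = 5)
  sec <- generate_section(cfg)
  mod <- dilution_model_from_extremes(sec$samples$S, sec$samples$ch4_nmol_l)
  res <- dilution_residuals(mod, sec$samples$S, sec$samples$ch4_nmol_l)
  # noise sd 0.05 / sqrt(40) ~ 0.008; endpoint noise adds a comparable term
  expect_lt(abs(res$summary$mean_residual), 0.05)
})

test_that("a single-driver response yields a 100% share and R2 = 1", {
  set.seed(1)
  d <- data.frame(SST = runif(40, 10, 30))
  d$ch4 <- 2 - 0.04 * d$SST
  att <- suppressWarnings(driver_regression(d, "ch4", "SST"))
  expect_equal(att$adjusted_r2, 1, tolerance = 1e-10)
  expect_equal(unname(att$shares_pct), 100, tolerance = 1e-8)
  expect_equal(unname(att$shares_of_explained_pct), 100, tolerance = 1e-8)
})

test_that("orthogonal predictors split shares by their variance contributions", {
  # exactly orthogonal, zero-mean regressors; y = sqrt(2) x1 + x2 gives a
  # closed-form 2:1 variance split -> shares 66.7% / 33.3%
  x1 <- rep(c(1, -1), 8)
  x2 <- rep(c(1, 1, -1, -1), 4)
  d <- data.frame(x1 = x1, x2 = x2, y = sqrt(2) * x1 + x2)
  att <- suppressWarnings(driver_regression(d, "y", c("x1", "x2")))
  expect_equal(unname(att$shares_of_explained_pct), c(200 / 3, 100 / 3),
               tolerance = 1e-8)
  expect_equal(sum(att$shares_pct), 100 * att$r_squared, tolerance = 1e-8)
  # permutation symmetry in predictor order
  att_rev <- suppressWarnings(driver_regression(d, "y", c("x2", "x1")))
  expect_equal(att$shares_pct[["x1"]], att_rev$shares_pct[["x1"]])
})

test_that("pure-noise responses give near-zero adjusted R2 and full tables", {
  set.seed(99)
  d <- data.frame(a = rnorm(200), b = rnorm(200), y = rnorm(200))
  att <- driver_regression(d, "y", c("a", "b"))
  expect_lt(abs(att$adjusted_r2), 0.05)
  expect_true(all(att$shares_pct >= 0))
  expect_lte(sum(att$shares_pct), 100)
  expect_equal(nrow(att$coefficients), 3)
})

test_that("collinear predictors are flagged but shares still computed", {
  set.seed(5)
  d <- data.frame(a = rnorm(50))
  d$b <- d$a + rnorm(50, 0, 1e-8)
  d$y <- d$a + rnorm(50, 0, 0.1)
  att <- driver_regression(d, "y", c("a", "b"))
  expect_true(att$collinearity_flag)
  expect_true(all(is.finite(att$shares_pct)))
})

test_that("correlations return Pearson r with two-sided p per pair", {
  d <- data.frame(k = c(0.01, 0.02, 0.03, 0.04, 0.05))
  d$mox <- d$k * 3.77  # structural proportionality
  d$temp <- c(12, 15, 19, 24, 28)
  out <- correlations(d, list(c("k", "mox"), c("k", "temp")))
  expect_equal(out$r[1], 1)
  expect_lt(out$p[1], 0.01)
  # missing values handled pairwise-complete
  d2 <- d; d2$temp[2] <- NA
  out2 <- correlations(d2, list(c("k", "temp")))
  expect_equal(out2$n, 4)
  expect_error(correlations(d[1:2, ], list(c("k", "mox"))), "fewer than 3")
})

test_that("sample correlation concentrates around the population value", {
  set.seed(77)
  n <- 500; rho <- 0.5
  x <- rnorm(n)
  y <- rho * x + sqrt(1 - rho^2) * rnorm(n)
  out <- correlations(data.frame(x = x, y = y), list(c("x", "y")))
  expect_lt(abs(out$r - rho), 0.08)
})
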