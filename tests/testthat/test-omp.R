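test_that("property rows are standardized by across-endmember sd times weight", {
  em <- endmember_set(c("a", "b"), T = c(5, 25), S = c(33, 35),
                      O = c(200, 300), P = c(0.1, 2), N = c(1, 20),
                      Si = c(2, 40))
  sys <- normalize_system(em)
  # population sd of {5, 25} is 10, so scaled T coefficients are 0.5 and 2.5
  expect_equal(unname(sys$A["T", ]), c(0.5, 2.5))
  expect_equal(diff(sys$A["T", ]), 2, ignore_attr = TRUE)
  # doubling the weight doubles the separation
  em_w <- endmember_set(c("a", "b"), T = c(5, 25), S = c(33, 35),
                        O = c(200, 300), P = c(0.1, 2), N = c(1, 20),
                        Si = c(2, 40), property_weights = c(2, 1, 1, 1, 1, 1))
  expect_equal(diff(normalize_system(em_w)$A["T", ]), 4, ignore_attr = TRUE)
  expect_equal(unname(sys$A["mass", ]), c(100, 100))
})

test_that("a property constant across endmembers is excluded with a warning", {
  em <- endmember_set(c("a", "b"), T = c(5, 25), S = c(34, 34),
                      O = c(200, 300), P = c(0.1, 2), N = c(1, 20),
                      Si = c(2, 40))
  expect_warning(sys <- normalize_system(em), "constant across endmembers")
  expect_false(sys$used[["S"]])
  expect_false("S" %in% rownames(sys$A))
})

test_that("pure endmembers and exact mixtures are recovered exactly", {
  em <- em3()
  # pure endmember 2
  pure <- as.data.frame(as.list(em$properties[2, ]))
  sol <- solve_omp(pure, em)
  expect_equal(unname(sol$x), c(0, 1, 0), tolerance = 1e-9)
  expect_lt(max(abs(sol$residuals)), 1e-8)
  # 50/50 of endmembers 1 and 2
  mix <- as.data.frame(as.list(0.5 * em$properties[1, ] +
                                 0.5 * em$properties[2, ]))
  sol <- solve_omp(mix, em)
  expect_equal(unname(sol$x), c(0.5, 0.5, 0), tolerance = 1e-9)
  expect_lt(sol$objective, 1e-18)
  expect_lt(abs(sol$R_M), 1e-9)
})

test_that("NaN or missing observations are rejected with the sample named", {
  em <- em2()
  bad <- as.data.frame(as.list(em$properties[1, ]))
  bad$T <- NA_real_
  bad$station <- "P07"
  expect_error(solve_omp(bad, em), "NA in observed")
  expect_error(solve_omp(bad, em), "P07")
  expect_error(solve_omp(data.frame(T = 10, S = 34), em), "lacks propert")
})

test_that("solver matches the dense simplex grid-search oracle", {
  em <- em3()
  sys <- normalize_system(em)
  grid <- simplex_grid(3, step = 0.01)
  mix <- random_mixture(em, 25, noise_sd = 0.5, seed = 42)
  step_slack <- 1e-6  # numerical slack only; dominance is the real check
  for (i in seq_len(nrow(mix$samples))) {
    obs <- as.numeric(mix$samples[i, ])
    b <- scaled_obs(sys, obs)
    best_grid <- min(grid_search_objective(sys$A, b, grid))
    sol <- solve_omp(mix$samples[i, ], em)
    # oracle dominance: the NNLS objective is never worse than any grid point
    expect_lte(sol$objective, best_grid + step_slack)
  }
})

test_that("every solution is non-negative with fractions summing to ~1", {
  em <- em3()
  mix <- random_mixture(em, 50, noise_sd = 1, seed = 7)
  mix$samples$station <- "X"
  mix$samples$depth <- 1
  out <- omp_section(cbind(mix$samples), em)
  frac <- as.matrix(out[, paste0("frac_", em$names)])
  expect_true(all(frac >= 0))
  expect_true(all(abs(rowSums(frac) - 1) < 0.01))
})

test_that("raising the mass weight never increases |R_M|", {
  obs <- as.data.frame(as.list(0.3 * em2()$properties[1, ] +
                                 0.7 * em2()$properties[2, ]))
  obs$T <- obs$T + 1  # perturb so residuals are non-zero
  rm_abs <- vapply(c(1, 10, 100, 1000), function(mw) {
    em <- default_endmembers(2, mass_weight = mw)
    abs(solve_omp(obs, em)$R_M)
  }, numeric(1))
  expect_true(all(diff(rm_abs) <= 1e-12))
})

test_that("omp_section round-trips a noiseless synthetic section exactly", {
  cfg <- scenario_config(seed = 5, n_stations = 5, depths = c(5, 50, 200),
                         noise_sd = c(T = 0, S = 0, O = 0, P = 0, N = 0,
                                      Si = 0, ch4 = 0))
  sec <- generate_section(cfg)
  out <- omp_section(sec$samples, cfg$endmembers)
  for (nm in cfg$endmembers$names) {
    expect_equal(out[[paste0("frac_", nm)]],
                 sec$true_fractions[[paste0("frac_", nm)]],
                 tolerance = 1e-9)
  }
  summ <- attr(out, "station_summary")
  expect_equal(nrow(summ), 5)
})

test_that("empty sections and per-sample failures are handled gracefully", {
  em <- em2()
  out <- omp_section(data.frame(), em)
  expect_equal(nrow(out), 0)
  # one bad row does not abort the section
  sec <- generate_section(scenario_config(seed = 2, n_stations = 2,
                                          depths = c(5, 50)))
  sec$samples$T[2] <- NA
  out <- omp_section(sec$samples, em)
  expect_equal(sum(out$failed), 1)
  expect_match(out$message[out$failed], "NA in observed")
  expect_equal(sum(!out$failed), 3)
})

test_that("dominant-mass classification uses argmax with ordered tie-break", {
  x <- c(A = 0.7, B = 0.2, C = 0.1)
  expect_equal(classify_dominant_mass(x)$label, "A")
  expect_equal(classify_dominant_mass(c(A = 0, B = 1))$label, "B")
  expect_message(tie <- classify_dominant_mass(c(A = 0.5, B = 0.5)), "tie")
  expect_equal(tie$label, "A")
  expect_true(tie$tie)
})

test_that("low-confidence flagging follows the residual threshold", {
  em <- em2()
  obs <- as.data.frame(as.list(0.5 * em$properties[1, ] +
                                 0.5 * em$properties[2, ]))
  obs$T <- obs$T + 0.5
  thr_loose <- c(T = 2, S = 2, O = 10, P = 1, N = 5, Si = 5)
  thr_tight <- c(T = 0.01, S = 2, O = 10, P = 1, N = 5, Si = 5)
  expect_false(solve_omp(obs, em, residual_threshold = thr_loose)$low_confidence)
  expect_true(solve_omp(obs, em, residual_threshold = thr_tight)$low_confidence)
})
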