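#' Scenario configuration for the synthetic pipeline
#'
#' Bundles everything needed to simulate a two- (or three-) endmember
#' mixing section with superimposed methane production/consumption,
#' triplicate tracer incubations with killed controls, an underway surface
#' transect with meridional gradients, and amendment incubation time
#' series. A single global seed fans out to per-stage substreams so each
#' generator is independently reproducible.
#'
#' Defaults emulate a Kuroshio-Oyashio-type frontal transect: salinity
#' 33.2-35.1 and SST 16.8-30.2 C between 40 N and 35 N, surface pCO2 rising
#' southwards from 338 to 360 uatm, dissolved CH4 falling from 6.11 to
#' 5.15 nmol l-1, wind 7.31 +/- 1.38 m s-1, and first-order oxidation rate
#' constants within 0.001-0.05 d-1.
#'
#' @param seed integer master seed.
#' @param n_stations number of stations along the section.
#' @param depths sample depths (m), strictly increasing.
#' @param endmembers an [endmember_set()].
#' @param mixing_profile optional array `[station, depth, endmember]` of
#'   true fractions; each fraction vector must be non-negative and sum
#'   to 1. NULL = default meridional/vertical gradient.
#' @param noise_sd named vector of measurement noise sds in property units
#'   for `T, S, O, P, N, Si, ch4`; zeros allowed.
#' @param ch4_endmember dissolved CH4 of each endmember, nmol l-1.
#' @param production_anomaly scalar or `[station, depth]` matrix of CH4
#'   added to (positive) or removed from (negative) the conservative
#'   mixture, nmol l-1.
#' @param true_k scalar or `[station, depth]` matrix of true first-order
#'   oxidation rate constants, d-1.
#' @param wind_mean,wind_sd wind speed distribution, m s-1.
#' @param lat_range section/underway latitude range, degrees N
#'   (north, south).
#' @param n_underway number of underway records.
#' @param sst_range,pco2_range,ch4_water_range underway gradients, given as
#'   (northern, southern) values.
#' @param ch4_atm_ppb,pco2_atm_uatm atmospheric endpoints for flux
#'   calculations.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(seed = 1L,
                            n_stations = 20,
                            depths = c(5, 25, 50, 75, 100, 150, 200, 300),
                            endmembers = default_endmembers(2),
                            mixing_profile = NULL,
                            noise_sd = c(T = 0.005, S = 0.003, O = 1,
                                         P = 0.02, N = 0.1, Si = 0.5,
                                         ch4 = 0.05),
                            ch4_endmember = NULL,
                            production_anomaly = 0,
                            true_k = 0.02,
                            wind_mean = 7.31, wind_sd = 1.38,
                            lat_range = c(40, 35),
                            n_underway = 200,
                            sst_range = c(16.8, 30.2),
                            pco2_range = c(338, 360),
                            ch4_water_range = c(6.11, 5.15),
                            ch4_atm_ppb = 1900,
                            pco2_atm_uatm = 420) {
  stopifnot(inherits(endmembers, "endmember_set"))
  n_em <- length(endmembers$names)
  if (is.null(ch4_endmember)) {
    # north (fresh) endmember richer in CH4, per the observed dilution
    ch4_endmember <- stats::setNames(
      c(5.15, 6.11, 4.5)[seq_len(n_em)], endmembers$names)
  }
  if (length(ch4_endmember) != n_em) {
    stop("scenario_config: ch4_endmember needs one value per endmember")
  }
  if (any(noise_sd < 0)) stop("scenario_config: noise_sd must be >= 0")
  req_noise <- c("T", "S", "O", "P", "N", "Si", "ch4")
  if (!all(req_noise %in% names(noise_sd))) {
    stop("scenario_config: noise_sd needs named entries ",
         paste(req_noise, collapse = ", "))
  }
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("scenario_config: depths must be strictly increasing")
  }
  if (is.null(mixing_profile)) {
    mixing_profile <- .default_mixing_profile(n_stations, length(depths), n_em)
  }
  dm <- dim(mixing_profile)
  if (length(dm) != 3 || dm[1] != n_stations || dm[2] != length(depths) ||
      dm[3] != n_em) {
    stop("scenario_config: mixing_profile must be [n_stations x n_depths x ",
         "n_endmembers]")
  }
  for (s in seq_len(n_stations)) {
    for (d in seq_along(depths)) {
      fr <- mixing_profile[s, d, ]
      if (any(fr < 0) || abs(sum(fr) - 1) > 1e-8) {
        stop("scenario_config: fraction vector at station ", s, " depth ",
             depths[d], " m is not on the simplex (values ",
             paste(signif(fr, 4), collapse = ", "), ")")
      }
    }
  }
  expand_field <- function(x, what) {
    if (length(x) == 1) {
      matrix(x, n_stations, length(depths))
    } else if (is.matrix(x) && all(dim(x) == c(n_stations, length(depths)))) {
      x
    } else {
      stop("scenario_config: ", what,
           " must be a scalar or an [n_stations x n_depths] matrix")
    }
  }
  structure(
    list(seed = as.integer(seed), n_stations = n_stations, depths = depths,
         endmembers = endmembers, mixing_profile = mixing_profile,
         noise_sd = noise_sd, ch4_endmember = ch4_endmember,
         production_anomaly = expand_field(production_anomaly,
                                           "production_anomaly"),
         true_k = expand_field(true_k, "true_k"),
         wind_mean = wind_mean, wind_sd = wind_sd,
         lat_range = lat_range, n_underway = n_underway,
         sst_range = sst_range, pco2_range = pco2_range,
         ch4_water_range = ch4_water_range,
         ch4_atm_ppb = ch4_atm_ppb, pco2_atm_uatm = pco2_atm_uatm),
    class = "scenario_config"
  )
}

# warm endmember dominant in the south, cold in the north; third endmember
# (intermediate water), when present, grows with depth
.default_mixing_profile <- function(n_stations, n_depths, n_em) {
  arr <- array(0, dim = c(n_stations, n_depths, n_em))
  s_frac <- if (n_stations > 1) {
    (seq_len(n_stations) - 1) / (n_stations - 1)
  } else 0.5
  d_frac <- if (n_depths > 1) (seq_len(n_depths) - 1) / (n_depths - 1) else 0
  for (s in seq_len(n_stations)) {
    for (d in seq_len(n_depths)) {
      f_deep <- if (n_em == 3) 0.7 * d_frac[d] else 0
      f_warm <- s_frac[s] * (1 - f_deep)  # warm mass grows southward
      arr[s, d, ] <- c(f_warm, 1 - f_deep - f_warm, f_deep)[seq_len(n_em)]
    }
  }
  arr
}

# per-stage substreams derived from one master seed
.substream <- function(seed, stage) {
  offsets <- c(section = 101, tracer = 211, underway = 307,
               amendment = 401)
  set.seed(as.integer((as.numeric(seed) * 1009 + offsets[[stage]]) %%
                        2147483587))
}

#' Generate a synthetic hydrographic section with known mixing fractions
#'
#' Each sample's six properties are the fraction-weighted endmember
#' properties plus independent Gaussian measurement noise; dissolved CH4 is
#' the conservative mixture of per-endmember CH4 plus the configured
#' production/consumption anomaly plus noise. The true fractions are
#' returned alongside for recovery tests.
#'
#' @param config a [scenario_config()].
#' @return list with `samples` (data.frame: `station`, `lat`, `depth_m`,
#'   `T`, `S`, `O`, `P`, `N`, `Si`, `ch4_nmol_l`) and `true_fractions`
#'   (data.frame: `station`, `depth_m`, one `frac_<name>` column per
#'   endmember, `ch4_conservative`, `production_anomaly`).
#' @export
generate_section <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  .substream(config$seed, "section")
  em <- config$endmembers
  props <- em$properties
  n_s <- config$n_stations
  n_d <- length(config$depths)
  lat <- seq(config$lat_range[1], config$lat_range[2], length.out = n_s)
  rows <- vector("list", n_s * n_d)
  frows <- vector("list", n_s * n_d)
  i <- 0
  for (s in seq_len(n_s)) {
    for (d in seq_len(n_d)) {
      i <- i + 1
      fr <- config$mixing_profile[s, d, ]
      true_prop <- drop(t(props) %*% fr)
      noise <- stats::rnorm(6, 0, config$noise_sd[colnames(props)])
      ch4_cons <- sum(fr * config$ch4_endmember)
      ch4 <- ch4_cons + config$production_anomaly[s, d] +
        stats::rnorm(1, 0, config$noise_sd[["ch4"]])
      st <- sprintf("P%02d", s)
      rows[[i]] <- data.frame(
        station = st, lat = lat[s], depth_m = config$depths[d],
        T = true_prop[["T"]] + noise[1], S = true_prop[["S"]] + noise[2],
        O = true_prop[["O"]] + noise[3], P = true_prop[["P"]] + noise[4],
        N = true_prop[["N"]] + noise[5], Si = true_prop[["Si"]] + noise[6],
        ch4_nmol_l = ch4
      )
      f <- data.frame(station = st, depth_m = config$depths[d])
      f[paste0("frac_", em$names)] <- as.list(fr)
      f$ch4_conservative <- ch4_cons
      f$production_anomaly <- config$production_anomaly[s, d]
      frows[[i]] <- f
    }
  }
  samples <- do.call(rbind, rows)
  true_fractions <- do.call(rbind, frows)
  rownames(samples) <- rownames(true_fractions) <- NULL
  list(samples = samples, true_fractions = true_fractions)
}

#' Simulate a triplicate tracer incubation set with a killed control
#'
#' Live replicates receive product DPM equal to `true_k * t * dpm_total`
#' plus a counting background plus Gaussian counting noise with
#' SD = sqrt(expected DPM) (the Poisson approximation for scintillation
#' counting); the killed control carries background only.
#'
#' @param true_k true first-order rate constant, d-1; `true_k * t` must lie
#'   in \[0, 1\] (the fraction oxidized cannot exceed the pool).
#' @param ch4 in situ CH4, nmol l-1.
#' @param t incubation time, days.
#' @param dpm_total total activity added, DPM.
#' @param n_reps number of live replicates.
#' @param seed integer seed.
#' @param background_dpm mean background product DPM (killed control level).
#' @param noise simulate counting noise (TRUE) or return exact expected
#'   counts (FALSE).
#' @param station,depth_m identifiers carried through to the output.
#' @return data.frame in the tracer-table schema: `station`, `depth_m`,
#'   `replicate`, `is_control`, `dpm_product`, `dpm_total`, `t_days`,
#'   `ch4_nmol_l`.
#' @export
generate_tracer_incubations <- function(true_k, ch4, t = 2, dpm_total = 1e5,
                                        n_reps = 3, seed = 1L,
                                        background_dpm = 50, noise = TRUE,
                                        station = "S1", depth_m = 5) {
  if (true_k < 0 || true_k * t > 1) {
    stop("generate_tracer_incubations: true_k * t = ", true_k * t,
         " outside [0, 1]; the oxidized fraction cannot exceed the pool")
  }
  if (dpm_total <= 0) {
    stop("generate_tracer_incubations: dpm_total must be positive")
  }
  set.seed(as.integer(seed))
  expected_live <- true_k * t * dpm_total + background_dpm
  jitter <- function(mu) {
    if (noise && mu > 0) stats::rnorm(1, mu, sqrt(mu)) else mu
  }
  live <- vapply(seq_len(n_reps),
                 function(r) max(0, jitter(expected_live)), numeric(1))
  ctrl <- max(0, jitter(background_dpm))
  data.frame(
    station = station, depth_m = depth_m,
    replicate = c(seq_len(n_reps), 0L),
    is_control = c(rep(FALSE, n_reps), TRUE),
    dpm_product = c(live, ctrl),
    dpm_total = dpm_total,
    t_days = t,
    ch4_nmol_l = ch4
  )
}

#' Generate a synthetic underway surface transect
#'
#' Builds a monotone latitude grid with linear meridional gradients in SST,
#' salinity, in situ pCO2 and dissolved CH4 matching the configured
#' endpoints, an equilibrator warmed by a fixed offset above SST, and wind
#' speeds drawn from the configured distribution (truncated at 0). The dry
#' xCO2 is back-computed so that the gas-exchange chain recovers the
#' intended in situ pCO2 exactly; the true fluxes implied by the noiseless
#' fields are returned in `true_*` columns for round-trip tests.
#'
#' @param config a [scenario_config()].
#' @param eq_warming equilibrator warming above SST, deg C.
#' @param xh2o headspace water-vapor mole fraction.
#' @param p_eq_atm equilibrator pressure, atm.
#' @return data.frame in the underway schema plus `true_f_ch4_mmol_m2_y`,
#'   `true_f_co2_mol_m2_y`, `true_saturation_pct`.
#' @export
generate_underway <- function(config, eq_warming = 0.5, xh2o = 0.02,
                              p_eq_atm = 1) {
  stopifnot(inherits(config, "scenario_config"))
  .substream(config$seed, "underway")
  n <- config$n_underway
  lat <- seq(config$lat_range[1], config$lat_range[2], length.out = n)
  grad <- function(rng) seq(rng[1], rng[2], length.out = n)
  SST <- grad(config$sst_range)
  S <- grad(c(33.2, 35.1))
  pco2_water <- grad(config$pco2_range)
  ch4_water <- grad(config$ch4_water_range)
  t_eq_c <- SST + eq_warming
  t_eq_k <- t_eq_c + 273.15
  f <- water_vapor_pressure(t_eq_k, S)
  pco2_eq <- pco2_water / exp(0.0423 * (SST - t_eq_c))
  xco2 <- pco2_eq * (1 - xh2o) / (p_eq_atm - f)
  wind <- pmax(0, stats::rnorm(n, config$wind_mean, config$wind_sd))
  out <- data.frame(
    time = seq_len(n), lat = lat, lon = 147,
    SST = SST, S = S,
    xco2_umol_mol = xco2, xh2o_mol_frac = xh2o,
    p_eq_atm = p_eq_atm, t_eq_k = t_eq_k,
    wind_m_s = wind,
    ch4_water_nmol_l = ch4_water,
    ch4_atm_ppb = config$ch4_atm_ppb,
    pco2_atm_uatm = config$pco2_atm_uatm
  )
  ch4_eq <- ch4_equilibrium_concentration(SST, S, config$ch4_atm_ppb)
  k_ch4 <- gas_transfer_velocity(wind, schmidt_number(SST, "CH4"))
  k_co2 <- gas_transfer_velocity(wind, schmidt_number(SST, "CO2"))
  out$true_f_ch4_mmol_m2_y <- ch4_flux(k_ch4, ch4_water, ch4_eq)$mmol_m2_y
  out$true_f_co2_mol_m2_y <-
    co2_flux(k_co2, co2_solubility(SST, S),
             pco2_water - config$pco2_atm_uatm)$mol_m2_y
  out$true_saturation_pct <- saturation_pct(ch4_water, ch4_eq)
  out
}

#' Generate an amendment incubation time series with a control
#'
#' The control is flat at `baseline` plus noise; the treatment is flat
#' until `lag` days and then increases linearly at `rate`. Concentrations
#' that fall below zero after noise are clipped to 0 and flagged.
#'
#' @param baseline starting CH4, nmol l-1.
#' @param rate production rate after the lag, nmol l-1 d-1.
#' @param lag lag before production starts, days (>= 0).
#' @param t_points sampling times, days, increasing.
#' @param noise_sd replicate noise sd, nmol l-1.
#' @param seed integer seed.
#' @param n_reps replicates per treatment.
#' @param treatment_label label for the amended series (e.g. "DMSP",
#'   "MPn", "MPn+Pi").
#' @return data.frame: `treatment`, `replicate`, `t_days`, `ch4_nmol_l`,
#'   `clipped`.
#' @export
generate_amendment_timeseries <- function(baseline, rate, lag, t_points,
                                          noise_sd = 1, seed = 1L,
                                          n_reps = 3,
                                          treatment_label = "amended") {
  if (lag < 0) stop("generate_amendment_timeseries: lag must be >= 0")
  if (is.unsorted(t_points, strictly = TRUE)) {
    stop("generate_amendment_timeseries: t_points must be increasing")
  }
  set.seed(as.integer(seed))
  mean_trt <- baseline + rate * pmax(0, t_points - lag)
  build <- function(label, means) {
    do.call(rbind, lapply(seq_len(n_reps), function(r) {
      vals <- means + stats::rnorm(length(means), 0, noise_sd)
      clipped <- vals < 0
      vals[clipped] <- 0
      data.frame(treatment = label, replicate = r, t_days = t_points,
                 ch4_nmol_l = vals, clipped = clipped)
    }))
  }
  out <- rbind(build(treatment_label, mean_trt),
               build("control", rep(baseline, length(t_points))))
  rownames(out) <- NULL
  if (any(out$clipped)) {
    warning("generate_amendment_timeseries: ", sum(out$clipped),
            " concentration(s) clipped at 0 after noise")
  }
  out
}
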