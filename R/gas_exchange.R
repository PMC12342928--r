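#' Saturated water vapor pressure over seawater
#'
#' Vapor pressure at 100% humidity as a function of equilibrator temperature
#' and salinity,
#' \deqn{\ln f = 24.4543 - 6745.09/T_{eq} - 4.8489 \ln(T_{eq}/100)
#'       - 0.000544\, S,}
#' used to convert dry-headspace xCO2 to partial pressure.
#'
#' @param T_eq equilibrator temperature, kelvin (valid 270-320 K).
#' @param S practical salinity (valid 0-42).
#' @return f in atm. Vectorized.
#' @examples
#' water_vapor_pressure(298.15, 35)  # ~0.0307 atm
#' @export
water_vapor_pressure <- function(T_eq, S) {
  if (any(T_eq <= 270 | T_eq >= 320)) {
    stop("water_vapor_pressure: T_eq outside (270, 320) K; ",
         "refusing to extrapolate (is the temperature in kelvin?)")
  }
  if (any(S < 0 | S > 42)) {
    stop("water_vapor_pressure: salinity outside [0, 42]")
  }
  exp(24.4543 - 6745.09 / T_eq - 4.8489 * log(T_eq / 100) - 0.000544 * S)
}

#' Equilibrator-headspace pCO2 from dry mole fraction
#'
#' \deqn{pCO_2(eq) = \frac{xCO_2}{1 - xH_2O} (P_{eq} - f)}
#' With xCO2 in umol mol-1 and pressures in atm the result is in uatm.
#'
#' @param xCO2 dry mole fraction of CO2, umol mol-1.
#' @param xH2O mole fraction of water vapor in the headspace (0 <= xH2O < 1).
#' @param P_eq in situ atmospheric pressure, atm.
#' @param f saturated water vapor pressure, atm (see
#'   [water_vapor_pressure()]).
#' @return pCO2 in the equilibrator headspace, uatm. Vectorized.
#' @export
pco2_equilibrator <- function(xCO2, xH2O, P_eq, f) {
  if (any(xH2O < 0 | xH2O >= 1)) {
    stop("pco2_equilibrator: xH2O must be in [0, 1)")
  }
  (xCO2 / (1 - xH2O)) * (P_eq - f)
}

#' Temperature correction of equilibrator pCO2 to in situ SST
#'
#' Corrects for warming between the seawater intake and the equilibrator,
#' \deqn{pCO_2(water) = pCO_2(eq)\, e^{0.0423 (SST - T_{eq})},}
#' with both temperatures in degrees C.
#'
#' @param pco2_eq equilibrator pCO2, uatm.
#' @param SST sea-surface (intake) temperature, deg C.
#' @param T_eq_C equilibrator temperature, deg C.
#' @param max_dT sanity bound on |SST - T_eq_C| (deg C); larger differences
#'   indicate a unit error and raise an error.
#' @return in situ pCO2, uatm. Vectorized.
#' @export
pco2_temperature_correction <- function(pco2_eq, SST, T_eq_C, max_dT = 10) {
  if (any(abs(SST - T_eq_C) >= max_dT)) {
    stop("pco2_temperature_correction: |SST - T_eq| >= ", max_dT,
         " deg C; check units (T_eq must be in deg C here)")
  }
  pco2_eq * exp(0.0423 * (SST - T_eq_C))
}

#' Schmidt number of CH4 or CO2 in seawater
#'
#' Quartic fit in temperature; coefficients in [gas_coefs]. The Schmidt
#' number (kinematic viscosity over gas diffusivity) normalizes transfer
#' velocities between gases; Sc(CO2) = 668 at 20 C in seawater.
#'
#' @param SST temperature, deg C (valid -2 to 40).
#' @param gas "CH4" or "CO2".
#' @return dimensionless Schmidt number. Vectorized over SST.
#' @export
schmidt_number <- function(SST, gas = c("CH4", "CO2")) {
  gas <- match.arg(gas)
  if (any(SST < -2 | SST > 40)) {
    stop("schmidt_number: SST outside the fit range [-2, 40] deg C")
  }
  cf <- gas_coefs$schmidt[gas, ]
  unname(cf["a"] + cf["b"] * SST + cf["c"] * SST^2 + cf["d"] * SST^3 +
           cf["e"] * SST^4)
}

#' Gas transfer velocity from wind speed
#'
#' Quadratic wind-speed parameterization
#' \deqn{k = 0.251\, u^2 (Sc/660)^{-1/2}}
#' with u the 10-m wind speed (m s-1); the coefficient's convention puts k in
#' cm h-1.
#'
#' @param u wind speed at 10 m, m s-1 (>= 0).
#' @param Sc Schmidt number of the gas at in situ temperature.
#' @return k in cm h-1. Vectorized.
#' @examples
#' gas_transfer_velocity(7.31, 660)  # 0.251 * 7.31^2 = 13.41 cm h-1
#' @export
gas_transfer_velocity <- function(u, Sc) {
  if (any(u < 0)) stop("gas_transfer_velocity: wind speed must be >= 0")
  if (any(Sc <= 0)) stop("gas_transfer_velocity: Sc must be positive")
  tv <- gas_coefs$transfer_velocity
  unname(tv["coef"] * u^2 * (Sc / tv["sc_ref"])^-0.5)
}

#' Atmospheric-equilibrium dissolved CH4 concentration
#'
#' Equilibrium concentration of methane in seawater in contact with air of a
#' given dry CH4 mole fraction, from the seawater solubility fit in
#' [gas_coefs].
#'
#' @param SST temperature, deg C.
#' @param S practical salinity.
#' @param ch4_atm_ppb atmospheric dry mole fraction of CH4, nmol mol-1 (ppb).
#' @return equilibrium concentration, nmol l-1. Vectorized.
#' @export
ch4_equilibrium_concentration <- function(SST, S, ch4_atm_ppb) {
  if (any(SST < -2 | SST > 40)) {
    stop("ch4_equilibrium_concentration: SST outside [-2, 40] deg C")
  }
  if (any(S < 0 | S > 42)) {
    stop("ch4_equilibrium_concentration: salinity outside [0, 42]")
  }
  if (any(ch4_atm_ppb < 0)) {
    stop("ch4_equilibrium_concentration: mole fraction must be >= 0")
  }
  TK <- SST + 273.15
  cf <- gas_coefs$ch4_solubility
  fG <- ch4_atm_ppb * 1e-9  # ppb -> mole fraction
  lnC <- log(fG) + cf["A1"] + cf["A2"] * (100 / TK) +
    cf["A3"] * log(TK / 100) + cf["A4"] * (TK / 100) +
    S * (cf["B1"] + cf["B2"] * (TK / 100) + cf["B3"] * (TK / 100)^2)
  out <- exp(lnC)
  out[ch4_atm_ppb == 0] <- 0
  unname(out)
}

#' CO2 solubility K_H in seawater
#'
#' Henry's-law solubility of CO2 (K0) as a function of temperature and
#' salinity, from the seawater solubility fit in [gas_coefs].
#'
#' @param SST temperature, deg C.
#' @param S practical salinity.
#' @return K_H in mol l-1 atm-1. Vectorized.
#' @export
co2_solubility <- function(SST, S) {
  TK <- SST + 273.15
  cf <- gas_coefs$co2_solubility
  unname(exp(cf["A1"] + cf["A2"] * (100 / TK) + cf["A3"] * log(TK / 100) +
               S * (cf["B1"] + cf["B2"] * (TK / 100) +
                      cf["B3"] * (TK / 100)^2)))
}

#' Air-sea CH4 flux
#'
#' \deqn{F_{CH_4} = k_{CH_4} ([CH_4]_{water} - [CH_4]_{atm-eq})}
#' Computed natively in umol m-2 h-1 (k in cm h-1 x concentration in
#' nmol l-1 = umol m-3 gives 0.01 umol m-2 h-1 per unit product) and
#' converted for reporting. Positive flux = sea to air.
#'
#' @param k_gas transfer velocity, cm h-1.
#' @param ch4_water dissolved CH4, nmol l-1.
#' @param ch4_equilibrium atmospheric-equilibrium CH4, nmol l-1 (see
#'   [ch4_equilibrium_concentration()]).
#' @return data.frame with `umol_m2_h`, `mmol_m2_d`, `mmol_m2_y`.
#' @examples
#' ch4_flux(10, 2, 1)  # 0.1 umol m-2 h-1 = 0.8766 mmol m-2 y-1
#' @export
ch4_flux <- function(k_gas, ch4_water, ch4_equilibrium) {
  if (any(k_gas < 0)) stop("ch4_flux: k_gas must be >= 0")
  # cm h-1 -> m h-1 (/100); nmol l-1 -> umol m-3 (x1); product in umol m-2 h-1
  umol_m2_h <- (k_gas / 100) * (ch4_water - ch4_equilibrium)
  data.frame(
    umol_m2_h = umol_m2_h,
    mmol_m2_d = umol_m2_h * 24 / 1000,
    mmol_m2_y = umol_m2_h * .UMOL_H_TO_MMOL_Y
  )
}

#' Air-sea CO2 flux
#'
#' \deqn{F_{CO_2} = k_{CO_2}\, K_H\, \Delta pCO_2}
#' with the same native unit pipeline as [ch4_flux()]: k in cm h-1, K_H in
#' mol l-1 atm-1, dpCO2 in uatm. Negative flux = ocean uptake (sink).
#'
#' @param k_gas transfer velocity, cm h-1.
#' @param KH CO2 solubility, mol l-1 atm-1 (see [co2_solubility()]).
#' @param dpco2 pCO2(water) - pCO2(air), uatm.
#' @return data.frame with `umol_m2_h`, `mmol_m2_d`, `mmol_m2_y`,
#'   `mol_m2_y`.
#' @export
co2_flux <- function(k_gas, KH, dpco2) {
  if (any(k_gas < 0)) stop("co2_flux: k_gas must be >= 0")
  if (any(KH <= 0)) stop("co2_flux: KH must be positive")
  # (cm h-1 /100 -> m h-1) x (mol l-1 atm-1 x 1000 -> mol m-3 atm-1)
  #   x (uatm x 1e-6 -> atm) = mol m-2 h-1; x 1e6 -> umol m-2 h-1
  umol_m2_h <- (k_gas / 100) * (KH * 1000) * dpco2 * 1e-6 * 1e6
  data.frame(
    umol_m2_h = umol_m2_h,
    mmol_m2_d = umol_m2_h * 24 / 1000,
    mmol_m2_y = umol_m2_h * .UMOL_H_TO_MMOL_Y,
    mol_m2_y = umol_m2_h * .UMOL_H_TO_MMOL_Y / 1000
  )
}

#' Methane saturation relative to atmospheric equilibrium
#'
#' @param ch4_water dissolved CH4, nmol l-1.
#' @param ch4_equilibrium atmospheric-equilibrium CH4, nmol l-1 (> 0).
#' @return saturation in percent (100 = equilibrium, > 100 = sea is a
#'   source). Vectorized.
#' @export
saturation_pct <- function(ch4_water, ch4_equilibrium) {
  if (any(ch4_equilibrium <= 0)) {
    stop("saturation_pct: equilibrium concentration must be positive")
  }
  100 * ch4_water / ch4_equilibrium
}

#' Process an underway surface transect into air-sea fluxes
#'
#' Runs the full surface gas-exchange chain on an underway record table:
#' water-vapor correction of xCO2 to equilibrator pCO2, temperature
#' correction to in situ pCO2, Schmidt numbers and transfer velocities for
#' CH4 and CO2, atmospheric-equilibrium CH4, both air-sea fluxes, and the
#' CH4 saturation. All intermediates are returned for auditability.
#'
#' @param underway data.frame with columns `lat`, `lon`, `SST` (deg C), `S`,
#'   `xco2_umol_mol`, `xh2o_mol_frac`, `p_eq_atm`, `t_eq_k`, `wind_m_s`,
#'   `ch4_water_nmol_l`, `ch4_atm_ppb`, `pco2_atm_uatm`. Optional `time`.
#' @return the input with appended columns `f_vapor_atm`, `pco2_eq_uatm`,
#'   `pco2_water_uatm`, `dpco2_uatm`, `sc_ch4`, `sc_co2`, `k_ch4_cm_h`,
#'   `k_co2_cm_h`, `kh_co2`, `ch4_eq_nmol_l`, `saturation_pct`,
#'   `f_ch4_mmol_m2_y`, `f_ch4_mmol_m2_d`, `f_co2_mol_m2_y`,
#'   `f_co2_mmol_m2_d`.
#' @export
process_underway <- function(underway) {
  req <- c("lat", "SST", "S", "xco2_umol_mol", "xh2o_mol_frac", "p_eq_atm",
           "t_eq_k", "wind_m_s", "ch4_water_nmol_l", "ch4_atm_ppb",
           "pco2_atm_uatm")
  missing_cols <- setdiff(req, names(underway))
  if (length(missing_cols)) {
    stop("process_underway: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  u <- underway
  u$f_vapor_atm <- water_vapor_pressure(u$t_eq_k, u$S)
  u$pco2_eq_uatm <- pco2_equilibrator(u$xco2_umol_mol, u$xh2o_mol_frac,
                                      u$p_eq_atm, u$f_vapor_atm)
  u$pco2_water_uatm <- pco2_temperature_correction(u$pco2_eq_uatm, u$SST,
                                                   u$t_eq_k - 273.15)
  u$dpco2_uatm <- u$pco2_water_uatm - u$pco2_atm_uatm
  u$sc_ch4 <- schmidt_number(u$SST, "CH4")
  u$sc_co2 <- schmidt_number(u$SST, "CO2")
  u$k_ch4_cm_h <- gas_transfer_velocity(u$wind_m_s, u$sc_ch4)
  u$k_co2_cm_h <- gas_transfer_velocity(u$wind_m_s, u$sc_co2)
  u$kh_co2 <- co2_solubility(u$SST, u$S)
  u$ch4_eq_nmol_l <- ch4_equilibrium_concentration(u$SST, u$S, u$ch4_atm_ppb)
  u$saturation_pct <- saturation_pct(u$ch4_water_nmol_l, u$ch4_eq_nmol_l)
  fch4 <- ch4_flux(u$k_ch4_cm_h, u$ch4_water_nmol_l, u$ch4_eq_nmol_l)
  fco2 <- co2_flux(u$k_co2_cm_h, u$kh_co2, u$dpco2_uatm)
  u$f_ch4_mmol_m2_y <- fch4$mmol_m2_y
  u$f_ch4_mmol_m2_d <- fch4$mmol_m2_d
  u$f_co2_mol_m2_y <- fco2$mol_m2_y
  u$f_co2_mmol_m2_d <- fco2$mmol_m2_d
  u
}
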