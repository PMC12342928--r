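#' Gas-exchange coefficient tables
#'
#' All empirical coefficients used by the gas-exchange module, isolated in
#' one place so they can be inspected or swapped without code changes.
#'
#' * `schmidt`: quartic fits Sc = a + b t + c t^2 + d t^3 + e t^4 of the
#'   Schmidt number in seawater against temperature t (deg C), valid -2 to
#'   40 C, from the Wanninkhof (2014) transfer-velocity update (the source
#'   of the k = 0.251 u^2 (Sc/660)^-0.5 relationship). Sc(CO2, 20 C) = 668.
#' * `ch4_solubility`: Wiesenburg & Guinasso (1979) fit of the
#'   atmospheric-equilibrium CH4 concentration in seawater,
#'   ln C = ln f_G + A1 + A2 (100/T) + A3 ln(T/100) + A4 (T/100)
#'   + S \[B1 + B2 (T/100) + B3 (T/100)^2\],
#'   with T in kelvin, S practical salinity, f_G the dry atmospheric mole
#'   fraction (dimensionless) and C in nmol l-1.
#' * `co2_solubility`: Weiss (1974) fit of K_H (here K0, mol l-1 atm-1),
#'   ln K0 = A1 + A2 (100/T) + A3 ln(T/100)
#'   + S \[B1 + B2 (T/100) + B3 (T/100)^2\].
#' * `transfer_velocity`: the coefficient 0.251 (cm h-1 per (m s-1)^2) and
#'   the reference Schmidt number 660 (CO2 in 20 C seawater).
#'
#' @format A named list of numeric vectors/matrices.
#' @export
gas_coefs <- list(
  schmidt = rbind(
    CO2 = c(a = 2116.8, b = -136.25, c = 4.7353, d = -0.092307, e = 0.0007555),
    CH4 = c(a = 2101.2, b = -131.54, c = 4.4931, d = -0.08676, e = 0.00070663)
  ),
  ch4_solubility = c(A1 = -415.2807, A2 = 596.8104, A3 = 379.2599,
                     A4 = -62.0757, B1 = -0.059160, B2 = 0.032174,
                     B3 = -0.0048198),
  co2_solubility = c(A1 = -58.0931, A2 = 90.5069, A3 = 22.2940,
                     B1 = 0.027766, B2 = -0.025888, B3 = 0.0050578),
  transfer_velocity = c(coef = 0.251, sc_ref = 660)
)

# unit conversion constants (documented with the flux functions)
# 1 umol m-2 h-1 = 8.766 mmol m-2 y-1 (8766 h per mean year / 1000)
.HOURS_PER_YEAR <- 8766
.UMOL_H_TO_MMOL_Y <- .HOURS_PER_YEAR / 1000
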