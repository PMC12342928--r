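#' Depth-integrate a volumetric rate profile
#'
#' Trapezoidal integration of a bottle-profile rate (nmol l-1 d-1 =
#' umol m-3 d-1) from the surface to `z_max`. The profile is extended to the
#' surface with the shallowest value (flagged) and truncated/interpolated at
#' `z_max` when it lies between sample depths.
#'
#' @param depths sample depths, m, strictly increasing, >= 2 values.
#' @param rates volumetric rates at those depths, nmol l-1 d-1, >= 0.
#' @param z_max integration depth, m (default 300, the upper water column);
#'   must lie within (shallowest, deepest] sample depth.
#' @return list with `umol_m2_d`, `mmol_m2_d`, `mmol_m2_y`,
#'   `surface_extended` (TRUE when the shallowest sample was deeper than
#'   0 m), `z_max`.
#' @examples
#' depth_integrate(c(0, 300), c(0.044, 0.044))  # 13.2 umol m-2 d-1
#' @export
depth_integrate <- function(depths, rates, z_max = 300) {
  stopifnot(length(depths) == length(rates), length(depths) >= 2)
  if (is.unsorted(depths, strictly = TRUE)) {
    stop("depth_integrate: depths must be strictly increasing")
  }
  if (any(rates < 0)) stop("depth_integrate: rates must be non-negative")
  if (z_max > max(depths)) {
    stop("depth_integrate: z_max = ", z_max, " m is below the deepest sample (",
         max(depths), " m); refusing to extrapolate downward")
  }
  if (z_max <= min(depths) && min(depths) > 0) {
    stop("depth_integrate: z_max = ", z_max,
         " m is above the shallowest sample (", min(depths), " m)")
  }
  surface_extended <- depths[1] > 0
  if (surface_extended) {
    depths <- c(0, depths)
    rates <- c(rates[1], rates)
  }
  keep <- depths <= z_max
  d <- depths[keep]; r <- rates[keep]
  if (max(d) < z_max) {  # interpolate the profile at z_max
    r_at <- stats::approx(depths, rates, xout = z_max)$y
    d <- c(d, z_max); r <- c(r, r_at)
  }
  umol_m2_d <- pracma::trapz(d, r)  # umol m-3 d-1 x m = umol m-2 d-1
  list(umol_m2_d = umol_m2_d,
       mmol_m2_d = umol_m2_d / 1000,
       mmol_m2_y = umol_m2_d / 1000 * 365.25,
       surface_extended = surface_extended,
       z_max = z_max)
}

#' Fraction of total methane removal due to microbial oxidation
#'
#' Total methane removal is the sum of two loss terms: the depth-integrated
#' oxidation (MOx) and the sea-air flux. The MOx contribution is
#' \deqn{100 \cdot \frac{\int MOx\,dz}{\int MOx\,dz + F_{CH_4}}.}
#' When the air-sea flux is negative (the sea is a CH4 sink) it is not a
#' loss from the water column, so it is floored at 0 for the ratio and the
#' result is flagged.
#'
#' @param integrated_mox depth-integrated MOx, any areal-rate unit.
#' @param flux_ch4 sea-air CH4 flux, same unit.
#' @return list with `fraction_pct`, `flux_floored` (flag).
#' @examples
#' mox_fraction(0.7, 0.9)  # 43.75%
#' @export
mox_fraction <- function(integrated_mox, flux_ch4) {
  stopifnot(length(integrated_mox) == 1, length(flux_ch4) == 1)
  if (integrated_mox < 0) stop("mox_fraction: integrated_mox must be >= 0")
  floored <- flux_ch4 < 0
  flux <- max(flux_ch4, 0)
  if (integrated_mox == 0 && flux == 0) {
    stop("mox_fraction: both loss terms are zero; the fraction is undefined")
  }
  list(fraction_pct = 100 * integrated_mox / (integrated_mox + flux),
       flux_floored = floored)
}

#' Per-station methane loss budgets
#'
#' Combines MOx rate profiles with sea-air CH4 fluxes into per-station
#' budgets: depth-integrated MOx, flux, and the MOx share of total removal.
#'
#' @param mox_profiles data.frame with columns `station`, `depth_m`, `mox`
#'   (nmol l-1 d-1), e.g. from [mox_estimate()].
#' @param fluxes data.frame with columns `station`, `f_ch4_mmol_m2_d`.
#' @param z_max integration depth, m.
#' @return data.frame with one row per station: `station`,
#'   `integrated_mox_mmol_m2_d`, `integrated_mox_mmol_m2_y`,
#'   `flux_mmol_m2_d`, `flux_mmol_m2_y`, `mox_fraction_pct`,
#'   `flux_floored`, `surface_extended`, `integration_depth_m`.
#' @export
station_budget <- function(mox_profiles, fluxes, z_max = 300) {
  req1 <- c("station", "depth_m", "mox")
  req2 <- c("station", "f_ch4_mmol_m2_d")
  if (!all(req1 %in% names(mox_profiles))) {
    stop("station_budget: mox_profiles needs columns ",
         paste(req1, collapse = ", "))
  }
  if (!all(req2 %in% names(fluxes))) {
    stop("station_budget: fluxes needs columns ", paste(req2, collapse = ", "))
  }
  stations <- intersect(unique(mox_profiles$station), unique(fluxes$station))
  if (length(stations) == 0) {
    stop("station_budget: no stations shared between profiles and fluxes")
  }
  rows <- lapply(stations, function(st) {
    prof <- mox_profiles[mox_profiles$station == st, , drop = FALSE]
    prof <- prof[order(prof$depth_m), , drop = FALSE]
    integ <- depth_integrate(prof$depth_m, prof$mox, z_max = z_max)
    fl <- mean(fluxes$f_ch4_mmol_m2_d[fluxes$station == st])
    frac <- mox_fraction(integ$mmol_m2_d, fl)
    data.frame(
      station = as.character(st),
      integrated_mox_mmol_m2_d = integ$mmol_m2_d,
      integrated_mox_mmol_m2_y = integ$mmol_m2_y,
      flux_mmol_m2_d = fl,
      flux_mmol_m2_y = fl * 365.25,
      mox_fraction_pct = frac$fraction_pct,
      flux_floored = frac$flux_floored,
      surface_extended = integ$surface_extended,
      integration_depth_m = integ$z_max
    )
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}

#' Regional summary of station budgets
#'
#' Group means and sample standard deviations of all numeric budget fields,
#' grouped by a water-mass label or latitude band.
#'
#' @param budgets data.frame from [station_budget()] (any extra numeric
#'   columns are summarized too).
#' @param grouping vector, one group label per budget row.
#' @return data.frame with one row per group: `group`, `n`, then
#'   `<field>_mean` and `<field>_sd` for every numeric field (sd is NA for
#'   singleton groups).
#' @export
regional_summary <- function(budgets, grouping) {
  stopifnot(nrow(budgets) == length(grouping))
  num <- names(budgets)[vapply(budgets, is.numeric, logical(1))]
  rows <- lapply(split(seq_len(nrow(budgets)), grouping), function(idx) {
    g <- budgets[idx, , drop = FALSE]
    out <- data.frame(group = as.character(grouping[idx[1]]), n = nrow(g))
    for (cc in num) {
      out[[paste0(cc, "_mean")]] <- mean(g[[cc]])
      out[[paste0(cc, "_sd")]] <- if (nrow(g) >= 2) stats::sd(g[[cc]]) else NA_real_
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
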