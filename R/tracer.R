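#' First-order methane oxidation rate constant from tracer counts
#'
#' In the 3H-CH4 radiotracer assay, the fraction of tracer turned over during
#' the incubation is the ratio of product activity (3H-H2O, after purging the
#' unreacted 3H-CH4) to total activity (3H-H2O + 3H-CH4). Dividing by the
#' incubation time gives the first-order rate constant
#' \deqn{k = \frac{DPM_{^3H\mbox{-}H_2O}}{DPM_{^3H\mbox{-}H_2O + ^3H\mbox{-}CH_4}}
#'       \cdot \frac{1}{t}.}
#'
#' @param dpm_product DPM of 3H-H2O after purging (product of oxidation).
#' @param dpm_total DPM of 3H-H2O + 3H-CH4 (total activity added).
#' @param t incubation time in days (48 h incubations give t = 2).
#' @return k in d-1. Vectorized over all arguments.
#' @examples
#' rate_constant(120, 2400, 2)  # 0.025 d-1
#' @export
rate_constant <- function(dpm_product, dpm_total, t) {
  if (any(dpm_total <= 0)) stop("rate_constant: dpm_total must be positive")
  if (any(t <= 0)) stop("rate_constant: incubation time must be positive")
  if (any(dpm_product < 0)) stop("rate_constant: dpm_product must be non-negative")
  if (any(dpm_product > dpm_total)) {
    stop("rate_constant: dpm_product exceeds dpm_total ",
         "(contamination or purge failure)")
  }
  (dpm_product / dpm_total) / t
}

#' Killed-control correction of tracer turnover fractions
#'
#' Abiotic tracer turnover (and counting background) is estimated from a
#' formalin-killed control and subtracted from each live replicate on the
#' turnover-fraction scale, i.e. before division by the incubation time.
#' Corrected fractions that would be negative are clipped to zero and
#' flagged, since a first-order rate constant is physically non-negative.
#'
#' @param sample_fractions numeric vector of live-sample turnover fractions
#'   (dpm_product / dpm_total).
#' @param control_fraction single turnover fraction of the killed control.
#' @return list with `fraction` (corrected, clipped), `clipped` (logical
#'   flag per sample).
#' @examples
#' control_correct(c(0.05, 0.01), 0.02)
#' @export
control_correct <- function(sample_fractions, control_fraction) {
  stopifnot(length(control_fraction) == 1L, control_fraction >= 0)
  corrected <- sample_fractions - control_fraction
  clipped <- corrected < 0
  corrected[clipped] <- 0
  if (all(clipped) && length(clipped) > 0 && control_fraction > 0) {
    warning("control_correct: control turnover exceeds every sample; ",
            "all corrected fractions are zero")
  }
  list(fraction = corrected, clipped = clipped)
}

#' Methane oxidation rate from rate constant and in situ concentration
#'
#' \deqn{MOx = k \cdot [CH_4]_{in\,situ}}
#'
#' @param k first-order rate constant, d-1.
#' @param ch4_in_situ methane concentration measured in separate vials,
#'   nmol l-1.
#' @return MOx rate in nmol l-1 d-1. Vectorized.
#' @examples
#' mox_rate(0.025, 3.77)  # 0.094 nmol l-1 d-1
#' @export
mox_rate <- function(k, ch4_in_situ) {
  if (any(k < 0)) stop("mox_rate: k must be non-negative")
  if (any(ch4_in_situ < 0)) stop("mox_rate: ch4_in_situ must be non-negative")
  k * ch4_in_situ
}

#' Estimate MOx rates from a table of tracer incubations
#'
#' Groups replicate incubations by station and depth, applies the
#' killed-control correction (one control per group; switchable), converts
#' turnover fractions to rate constants and MOx rates, and returns per-group
#' means and sample standard deviations.
#'
#' @param incubations data.frame with columns `station`, `depth_m`,
#'   `replicate`, `is_control` (logical or 0/1), `dpm_product`, `dpm_total`,
#'   `t_days`, `ch4_nmol_l`.
#' @param correct_control apply the killed-control subtraction (default TRUE;
#'   the assay includes the control either way).
#' @return data.frame, one row per station/depth: `station`, `depth_m`,
#'   `n_reps`, `k`, `k_sd`, `mox`, `mox_sd`, `ch4_nmol_l`,
#'   `control_fraction`, `any_clipped`.
#' @export
mox_estimate <- function(incubations, correct_control = TRUE) {
  req <- c("station", "depth_m", "replicate", "is_control",
           "dpm_product", "dpm_total", "t_days", "ch4_nmol_l")
  missing_cols <- setdiff(req, names(incubations))
  if (length(missing_cols)) {
    stop("mox_estimate: missing columns: ", paste(missing_cols, collapse = ", "))
  }
  inc <- incubations
  inc$is_control <- as.logical(inc$is_control)
  key <- interaction(inc$station, inc$depth_m, drop = TRUE)
  out <- lapply(split(inc, key), function(g) {
    live <- g[!g$is_control, , drop = FALSE]
    ctrl <- g[g$is_control, , drop = FALSE]
    if (nrow(live) == 0) {
      stop("mox_estimate: no live replicates for station ", g$station[1],
           " depth ", g$depth_m[1])
    }
    if (nrow(ctrl) > 1) {
      stop("mox_estimate: more than one killed control for station ",
           g$station[1], " depth ", g$depth_m[1])
    }
    frac <- live$dpm_product / live$dpm_total
    if (any(frac > 1)) {
      stop("mox_estimate: dpm_product exceeds dpm_total at station ",
           g$station[1], " depth ", g$depth_m[1])
    }
    ctrl_frac <- if (nrow(ctrl) == 1) ctrl$dpm_product / ctrl$dpm_total else 0
    clipped <- rep(FALSE, length(frac))
    if (correct_control && nrow(ctrl) == 1) {
      cc <- control_correct(frac, ctrl_frac)
      frac <- cc$fraction
      clipped <- cc$clipped
    }
    k <- frac / live$t_days
    ch4 <- mean(live$ch4_nmol_l)
    mox <- mox_rate(k, live$ch4_nmol_l)
    data.frame(
      station = as.character(g$station[1]), depth_m = g$depth_m[1],
      n_reps = length(k),
      k = mean(k), k_sd = if (length(k) >= 2) stats::sd(k) else NA_real_,
      mox = mean(mox),
      mox_sd = if (length(mox) >= 2) stats::sd(mox) else NA_real_,
      ch4_nmol_l = ch4,
      control_fraction = ctrl_frac,
      any_clipped = any(clipped)
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$station, res$depth_m), , drop = FALSE]
}

#' Replicate statistics of rate-constant / MOx estimates
#'
#' Per-group mean and sample standard deviation of `k` and `mox` for a table
#' of per-replicate estimates. Singleton groups pass through with sd absent
#' (NA).
#'
#' @param estimates data.frame with columns `station`, `depth_m`, `k`, `mox`.
#' @return data.frame with `station`, `depth_m`, `n_reps`, `k`, `k_sd`,
#'   `mox`, `mox_sd`.
#' @export
replicate_stats <- function(estimates) {
  req <- c("station", "depth_m", "k", "mox")
  missing_cols <- setdiff(req, names(estimates))
  if (length(missing_cols)) {
    stop("replicate_stats: missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  key <- interaction(estimates$station, estimates$depth_m, drop = TRUE)
  out <- lapply(split(estimates, key), function(g) {
    data.frame(
      station = as.character(g$station[1]), depth_m = g$depth_m[1],
      n_reps = nrow(g),
      k = mean(g$k),
      k_sd = if (nrow(g) >= 2) stats::sd(g$k) else NA_real_,
      mox = mean(g$mox),
      mox_sd = if (nrow(g) >= 2) stats::sd(g$mox) else NA_real_
    )
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$station, res$depth_m), , drop = FALSE]
}
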