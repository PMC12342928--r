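#' Build the scaled OMP design system
#'
#' OMP analysis solves, for each water sample, the property-conservation
#' system
#' \deqn{\sum_i x_i P_i = P_{obs} + R_P \quad (P \in \{T,S,O,P,N,Si\}),
#'       \qquad \sum_i x_i = 1 + R_M}
#' for the non-negative mixing fractions \eqn{x_i}. The six properties are in
#' incommensurate units, so each property row is standardized before the
#' least-squares solve: divided by the across-endmember standard deviation of
#' that property (population convention, divisor n) and multiplied by its
#' property weight. The mass-conservation row of ones is scaled by
#' `mass_weight`. Properties with zero spread across endmembers carry no
#' mixing information and are excluded with a warning.
#'
#' @param endmembers an [endmember_set()].
#' @param samples optional data.frame with columns `T, S, O, P, N, Si`
#'   (observed sample properties); when supplied, the scaled observation
#'   vectors are returned alongside the design matrix.
#' @return A list with elements `A` (scaled design matrix, rows = used
#'   property rows + mass row, columns = endmembers), `scale` (per-property
#'   divisor), `weights`, `used` (logical, which of the six properties are in
#'   the system), `mass_weight`, and, if `samples` was given, `B` (matrix of
#'   scaled observation vectors, one column per sample).
#' @export
normalize_system <- function(endmembers, samples = NULL) {
  stopifnot(inherits(endmembers, "endmember_set"))
  props <- endmembers$properties
  w <- endmembers$property_weights
  # population sd (divisor n) across endmember values, per property
  n_em <- nrow(props)
  sds <- apply(props, 2, function(v) sqrt(mean((v - mean(v))^2)))
  used <- sds > 0 & w > 0
  if (any(sds == 0)) {
    warning("normalize_system: propert",
            if (sum(sds == 0) == 1) "y " else "ies ",
            paste(colnames(props)[sds == 0], collapse = ", "),
            " constant across endmembers; excluded from the system")
  }
  if (!any(used)) stop("normalize_system: all properties excluded; system unsolvable")
  scale <- ifelse(used, sds, NA_real_)
  A_prop <- t(props[, used, drop = FALSE]) / sds[used] * w[used]
  A <- rbind(A_prop, mass = rep(endmembers$mass_weight, n_em))
  out <- list(A = A, scale = scale, weights = w, used = used,
              mass_weight = endmembers$mass_weight,
              properties = colnames(props))
  if (!is.null(samples)) {
    obs <- as.matrix(samples[, colnames(props), drop = FALSE])
    B <- t(obs[, used, drop = FALSE]) / sds[used] * w[used]
    out$B <- rbind(B, mass = rep(endmembers$mass_weight, nrow(obs)))
  }
  out
}

#' Solve the OMP mixing system for one sample
#'
#' Finds the non-negative fraction vector minimizing the weighted sum of
#' squared residuals of the scaled property equations plus the (heavily
#' weighted) mass-conservation row, via Lawson-Hanson non-negative least
#' squares. Residuals are reported both in native property units and in
#' scaled (dimensionless) form.
#'
#' @param sample a one-row data.frame (or named list/vector) with fields
#'   `T, S, O, P, N, Si`, optionally `station` and `depth`.
#' @param endmembers an [endmember_set()].
#' @param residual_threshold optional named numeric vector (native units per
#'   property): solutions whose absolute native residual exceeds the
#'   threshold in any property are flagged `low_confidence`. A sensible
#'   choice is twice the measurement noise sd.
#' @param system optional precomputed [normalize_system()] result (without
#'   samples), to avoid rebuilding the design per sample.
#' @return An object of class `omp_solution`: list with `x` (named fractions),
#'   `residuals` (native units, named by property; NA for excluded
#'   properties), `residuals_scaled`, `R_M` (mass residual, sum(x) - 1),
#'   `objective` (weighted SSR in the scaled system), `low_confidence`,
#'   `sample` (station/depth if present).
#' @examples
#' em <- default_endmembers(2)
#' mix <- as.data.frame(t(0.5 * em$properties[1, ] + 0.5 * em$properties[2, ]))
#' sol <- solve_omp(mix, em)
#' sol$x  # 0.5, 0.5
#' @export
solve_omp <- function(sample, endmembers, residual_threshold = NULL,
                      system = NULL) {
  stopifnot(inherits(endmembers, "endmember_set"))
  sample <- as.data.frame(as.list(sample))
  if (!"depth" %in% names(sample) && "depth_m" %in% names(sample)) {
    sample$depth <- sample$depth_m
  }
  props <- colnames(endmembers$properties)
  missing_cols <- setdiff(props, names(sample))
  if (length(missing_cols)) {
    stop("solve_omp: sample lacks propert",
         if (length(missing_cols) == 1) "y " else "ies ",
         paste(missing_cols, collapse = ", "))
  }
  obs <- as.numeric(sample[1, props])
  id <- paste0(
    if (!is.null(sample$station)) paste0("station ", sample$station, " ") else "",
    if (!is.null(sample$depth)) paste0("depth ", sample$depth, " m") else ""
  )
  if (anyNA(obs)) {
    stop("solve_omp: NA in observed properties (",
         paste(props[is.na(obs)], collapse = ", "), ") for sample ", id)
  }
  sys <- if (is.null(system)) normalize_system(endmembers) else system
  b <- c(obs[sys$used] / sys$scale[sys$used] * sys$weights[sys$used],
         sys$mass_weight)
  fit <- pracma::lsqnonneg(sys$A, b)
  x <- stats::setNames(as.numeric(fit$x), endmembers$names)
  pred <- drop(t(endmembers$properties) %*% x)  # per property, native units
  res_native <- stats::setNames(rep(NA_real_, length(props)), props)
  res_native[sys$used] <- pred[sys$used] - obs[sys$used]
  res_scaled <- res_native
  res_scaled[sys$used] <- res_native[sys$used] / sys$scale[sys$used] *
    sys$weights[sys$used]
  low_conf <- FALSE
  if (!is.null(residual_threshold)) {
    thr <- residual_threshold[props]
    chk <- !is.na(res_native) & !is.na(thr) & abs(res_native) > thr
    low_conf <- any(chk)
  }
  structure(
    list(
      x = x,
      residuals = res_native,
      residuals_scaled = res_scaled,
      R_M = sum(x) - 1,
      objective = sum((sys$A %*% x - b)^2),
      low_confidence = low_conf,
      station = sample$station, depth = sample$depth
    ),
    class = "omp_solution"
  )
}

#' @export
print.omp_solution <- function(x, ...) {
  cat("OMP solution", if (!is.null(x$station)) paste0("(station ", x$station,
      if (!is.null(x$depth)) paste0(", ", x$depth, " m"), ")"), "\n")
  print(round(x$x, 4))
  cat("sum(x) =", format(sum(x$x), digits = 6),
      " objective =", format(x$objective, digits = 4),
      if (x$low_confidence) " [low confidence]", "\n")
  invisible(x)
}

#' Solve OMP for a whole section of samples
#'
#' Applies [solve_omp()] to every row of a sample table and assembles a tidy
#' result table. Per-sample failures (missing values, unsolvable rows) are
#' captured as flagged rows rather than aborting the section.
#'
#' @param samples data.frame with columns `station`, `depth`, `T, S, O, P, N,
#'   Si`.
#' @param endmembers an [endmember_set()].
#' @param residual_threshold see [solve_omp()].
#' @return A data.frame with one row per sample: `station`, `depth`, one
#'   fraction column per water mass (`frac_<name>`), native residual columns
#'   (`R_T` ... `R_Si`), `R_M`, `objective`, `dominant_mass`,
#'   `dominant_fraction`, `tie`, `low_confidence`, `failed`, `message`.
#'   The per-station mean fraction of each water mass is attached as
#'   attribute `"station_summary"`.
#' @export
omp_section <- function(samples, endmembers, residual_threshold = NULL) {
  stopifnot(inherits(endmembers, "endmember_set"))
  nm <- endmembers$names
  frac_cols <- paste0("frac_", nm)
  res_cols <- paste0("R_", colnames(endmembers$properties))
  empty <- data.frame(station = character(), depth = numeric())
  for (cc in c(frac_cols, res_cols, "R_M", "objective")) empty[[cc]] <- numeric()
  empty$dominant_mass <- character()
  empty$dominant_fraction <- numeric()
  empty$tie <- logical()
  empty$low_confidence <- logical()
  empty$failed <- logical()
  empty$message <- character()
  if (is.null(samples) || nrow(samples) == 0) {
    attr(empty, "station_summary") <- empty[0, c("station", frac_cols)]
    return(empty)
  }
  if (!"depth" %in% names(samples) && "depth_m" %in% names(samples)) {
    samples$depth <- samples$depth_m
  }
  sys <- normalize_system(endmembers)
  rows <- lapply(seq_len(nrow(samples)), function(i) {
    smp <- samples[i, , drop = FALSE]
    out <- data.frame(
      station = if (!is.null(smp$station)) as.character(smp$station) else NA_character_,
      depth = if (!is.null(smp$depth)) as.numeric(smp$depth) else NA_real_
    )
    sol <- tryCatch(
      solve_omp(smp, endmembers, residual_threshold = residual_threshold,
                system = sys),
      error = function(e) e
    )
    if (inherits(sol, "error")) {
      for (cc in c(frac_cols, res_cols, "R_M", "objective",
                   "dominant_fraction")) out[[cc]] <- NA_real_
      out$dominant_mass <- NA_character_
      out$tie <- NA
      out$low_confidence <- NA
      out$failed <- TRUE
      out$message <- conditionMessage(sol)
      return(out[, c("station", "depth", frac_cols, res_cols, "R_M",
                     "objective", "dominant_mass", "dominant_fraction",
                     "tie", "low_confidence", "failed", "message")])
    }
    out[frac_cols] <- as.list(sol$x)
    out[res_cols] <- as.list(sol$residuals)
    out$R_M <- sol$R_M
    out$objective <- sol$objective
    dom <- classify_dominant_mass(sol)
    out$dominant_mass <- dom$label
    out$dominant_fraction <- dom$fraction
    out$tie <- dom$tie
    out$low_confidence <- sol$low_confidence
    out$failed <- FALSE
    out$message <- ""
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  ok <- !res$failed
  summ <- stats::aggregate(res[ok, frac_cols, drop = FALSE],
                           by = list(station = res$station[ok]), FUN = mean)
  attr(res, "station_summary") <- summ
  res
}

#' Dominant water mass of an OMP solution
#'
#' Returns the label of the endmember with the largest mixing fraction. Ties
#' (within a small numeric tolerance) are broken by endmember order and
#' flagged.
#'
#' @param solution an `omp_solution` (or bare named fraction vector).
#' @param tol tie tolerance on the fraction scale.
#' @return list with `label`, `fraction`, `tie`.
#' @export
classify_dominant_mass <- function(solution, tol = 1e-9) {
  x <- if (inherits(solution, "omp_solution")) solution$x else solution
  stopifnot(is.numeric(x), length(x) >= 2, !is.null(names(x)))
  i <- which.max(x)  # first maximum -> endmember-order tie-break
  tie <- sum(x >= x[i] - tol) > 1L
  if (tie) {
    message("classify_dominant_mass: tie between ",
            paste(names(x)[x >= x[i] - tol], collapse = ", "),
            "; broken by endmember order")
  }
  list(label = names(x)[i], fraction = as.numeric(x[i]), tie = tie)
}
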