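#' Conservative two-endmember dilution model for dissolved methane
#'
#' If methane behaved conservatively during the mixing of two water masses,
#' its concentration would fall on the straight line joining the two
#' endmember (salinity, CH4) pairs — the theoretical dilution line.
#' Departures from that line diagnose in situ production (above) or
#' consumption/oxidation (below).
#'
#' @param S_A,ch4_A salinity and CH4 (nmol l-1) of endmember A.
#' @param S_B,ch4_B salinity and CH4 (nmol l-1) of endmember B.
#' @return object of class `dilution_model`.
#' @examples
#' m <- dilution_model(33.2, 6.11, 35.1, 5.15)
#' dilution_predict(m, 34.15)  # 5.63 nmol l-1
#' @export
dilution_model <- function(S_A, ch4_A, S_B, ch4_B) {
  if (S_A == S_B) {
    stop("dilution_model: endmember salinities are equal; ",
         "the dilution line is undefined")
  }
  structure(list(S_A = S_A, ch4_A = ch4_A, S_B = S_B, ch4_B = ch4_B),
            class = "dilution_model")
}

#' Fit a dilution model from the salinity extremes of a table
#'
#' Default endmember choice: the observations at minimum and maximum
#' salinity of the input define the two (S, CH4) endpoints.
#'
#' @param S,ch4 paired observations.
#' @return a [dilution_model()].
#' @export
dilution_model_from_extremes <- function(S, ch4) {
  ok <- stats::complete.cases(S, ch4)
  S <- S[ok]; ch4 <- ch4[ok]
  if (length(S) < 2) stop("dilution_model_from_extremes: need >= 2 observations")
  i <- which.min(S); j <- which.max(S)
  dilution_model(S[i], ch4[i], S[j], ch4[j])
}

#' Predict conservative methane at a given salinity
#'
#' Linear interpolation along the dilution line. Salinities outside the
#' endmember range are extrapolated but flagged via the `"extrapolated"`
#' attribute.
#'
#' @param model a [dilution_model()].
#' @param S salinity (vectorized).
#' @return predicted CH4, nmol l-1, with attribute `extrapolated` (logical
#'   per value).
#' @export
dilution_predict <- function(model, S) {
  stopifnot(inherits(model, "dilution_model"))
  slope <- (model$ch4_B - model$ch4_A) / (model$S_B - model$S_A)
  pred <- model$ch4_A + slope * (S - model$S_A)
  lo <- min(model$S_A, model$S_B); hi <- max(model$S_A, model$S_B)
  extrap <- S < lo | S > hi
  if (any(extrap)) {
    warning("dilution_predict: ", sum(extrap),
            " salinity value(s) outside the endmember range; extrapolated")
  }
  attr(pred, "extrapolated") <- extrap
  pred
}

#' Residuals from the theoretical dilution line
#'
#' residual = observed - predicted; negative residuals indicate methane
#' below the conservative expectation (net consumption or oxidation),
#' positive residuals net production.
#'
#' @param model a [dilution_model()].
#' @param S,ch4 paired observations.
#' @param lat optional latitudes; when supplied, mean residuals are also
#'   summarized by latitude band.
#' @param band_width latitude band width in degrees (default 1).
#' @return list with `residuals` (data.frame S, ch4, predicted, residual,
#'   and lat if given) and `summary` (n, mean_residual, sd_residual,
#'   frac_negative, and a `by_band` data.frame when lat is given).
#' @export
dilution_residuals <- function(model, S, ch4, lat = NULL, band_width = 1) {
  stopifnot(length(S) == length(ch4), length(S) >= 1)
  pred <- suppressWarnings(dilution_predict(model, S))
  res <- as.numeric(ch4 - pred)
  df <- data.frame(S = S, ch4 = ch4, predicted = as.numeric(pred),
                   residual = res)
  summary <- list(
    n = length(res),
    mean_residual = mean(res),
    sd_residual = if (length(res) >= 2) stats::sd(res) else NA_real_,
    frac_negative = mean(res < 0)
  )
  if (!is.null(lat)) {
    stopifnot(length(lat) == length(S))
    df$lat <- lat
    band <- floor(lat / band_width) * band_width
    agg <- stats::aggregate(res, by = list(lat_band = band),
                            FUN = function(v) c(mean = mean(v), n = length(v)))
    summary$by_band <- data.frame(lat_band = agg$lat_band,
                                  mean_residual = agg$x[, "mean"],
                                  n = agg$x[, "n"])
  }
  list(residuals = df, summary = summary)
}

#' Driver attribution for methane variability by multiple regression
#'
#' Ordinary least squares of the response on the supplied predictors
#' (standardized internally), with per-predictor shares of explained
#' variability computed by averaging sequential sum-of-squares contributions
#' over all predictor orderings (the LMG decomposition). Shares are reported
#' as percent of total response variance, so they sum to R-squared x 100 —
#' i.e. to 100% of the explained part.
#'
#' @param data data.frame holding response and predictors.
#' @param response name of the response column (e.g. dissolved CH4).
#' @param predictors character vector of predictor column names (e.g. SST,
#'   salinity, oxygen saturation). At most 10 (orderings are enumerated via
#'   all subsets).
#' @param condition_threshold design-matrix condition number above which the
#'   shares are flagged as collinearity-affected (still computed).
#' @return object of class `driver_attribution`: list with `coefficients`
#'   (estimate, std.error, t, p on the standardized scale), `r_squared`,
#'   `adjusted_r2`, `shares_pct` (named, % of total variance),
#'   `shares_of_explained_pct`, `n`, `condition_number`,
#'   `collinearity_flag`, `fit` (the lm object).
#' @export
driver_regression <- function(data, response, predictors,
                              condition_threshold = 1e3) {
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  p <- length(predictors)
  if (p < 1 || p > 10) stop("driver_regression: need 1-10 predictors")
  d <- data[, c(response, predictors)]
  d <- d[stats::complete.cases(d), , drop = FALSE]
  n <- nrow(d)
  if (n <= p + 2) {
    stop("driver_regression: need more than p + 2 = ", p + 2,
         " complete observations, got ", n)
  }
  y <- d[[response]]
  X <- scale(as.matrix(d[predictors]))  # standardized predictors
  if (any(!is.finite(X))) {
    stop("driver_regression: a predictor is constant; cannot standardize")
  }
  dd <- data.frame(y = y, X)
  names(dd) <- c("y", predictors)
  fit <- stats::lm(stats::reformulate(predictors, "y"), data = dd)
  sm <- summary(fit)
  kappa_x <- kappa(cbind(1, X), exact = TRUE)
  # all-subsets R^2 for the LMG average over orderings
  r2_subset <- function(vars) {
    if (length(vars) == 0) return(0)
    summary(stats::lm(stats::reformulate(vars, "y"), data = dd))$r.squared
  }
  subsets <- lapply(0:(2^p - 1), function(m) predictors[bitwAnd(
    m, 2^(seq_len(p) - 1)) > 0])
  r2s <- vapply(subsets, r2_subset, numeric(1))
  names(r2s) <- vapply(subsets, paste, character(1), collapse = "|")
  lmg <- stats::setNames(numeric(p), predictors)
  for (j in seq_len(p)) {
    contrib <- 0
    for (s in seq_along(subsets)) {
      S <- subsets[[s]]
      if (predictors[j] %in% S) next
      k <- length(S)
      w <- factorial(k) * factorial(p - k - 1) / factorial(p)
      key_with <- paste(predictors[predictors %in% c(S, predictors[j])],
                        collapse = "|")
      contrib <- contrib + w * (r2s[[key_with]] - r2s[[s]])
    }
    lmg[j] <- contrib
  }
  structure(
    list(
      coefficients = data.frame(
        term = rownames(sm$coefficients),
        estimate = sm$coefficients[, 1],
        std.error = sm$coefficients[, 2],
        t = sm$coefficients[, 3],
        p = sm$coefficients[, 4],
        row.names = NULL
      ),
      r_squared = sm$r.squared,
      adjusted_r2 = sm$adj.r.squared,
      shares_pct = 100 * lmg,
      shares_of_explained_pct = if (sm$r.squared > 0) {
        100 * lmg / sum(lmg)
      } else stats::setNames(rep(NA_real_, p), predictors),
      n = n,
      condition_number = kappa_x,
      collinearity_flag = kappa_x > condition_threshold,
      fit = fit
    ),
    class = "driver_attribution"
  )
}

#' @export
print.driver_attribution <- function(x, ...) {
  cat("Driver attribution (n =", x$n, ")\n")
  cat("adjusted R^2 =", round(x$adjusted_r2, 4), "\n")
  cat("explained-variability shares (% of total variance):\n")
  print(round(x$shares_pct, 2))
  if (x$collinearity_flag) {
    cat("WARNING: condition number", format(x$condition_number, digits = 3),
        "- shares affected by collinearity\n")
  }
  invisible(x)
}

#' Pairwise Pearson correlations with p-values
#'
#' Pearson r and two-sided p for each requested pair of columns, using
#' pairwise-complete observations.
#'
#' @param table data.frame.
#' @param pairs list of length-2 character vectors, or a 2-column matrix of
#'   column names.
#' @return data.frame with `var1`, `var2`, `n`, `r`, `p`.
#' @export
correlations <- function(table, pairs) {
  if (is.matrix(pairs)) pairs <- split(pairs, seq_len(nrow(pairs)))
  rows <- lapply(pairs, function(pr) {
    stopifnot(length(pr) == 2, all(pr %in% names(table)))
    x <- table[[pr[1]]]; y <- table[[pr[2]]]
    ok <- stats::complete.cases(x, y)
    if (sum(ok) < 3) {
      stop("correlations: fewer than 3 complete pairs for ",
           pr[1], " vs ", pr[2])
    }
    ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
    data.frame(var1 = pr[1], var2 = pr[2], n = sum(ok),
               r = unname(ct$estimate), p = ct$p.value)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
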