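#' Define a set of water-mass endmembers
#'
#' An endmember is an idealized source water mass characterized by fixed
#' values of the six conservative/quasi-conservative hydrographic properties
#' used in optimum multiparameter (OMP) analysis: potential temperature (T,
#' degrees C), salinity (S, practical), dissolved oxygen (O, umol l-1),
#' phosphate (P, umol l-1), nitrate (N, umol l-1) and silicate (Si, umol l-1).
#'
#' Between 2 and 7 endmembers are accepted: with six properties plus the mass
#' conservation row the system has seven equations, so more than seven
#' unknowns would be underdetermined.
#'
#' @param names character vector of water-mass labels.
#' @param T,S,O,P,N,Si numeric vectors, one value per endmember, in the units
#'   above.
#' @param property_weights non-negative weights for the six property
#'   equations, in the order T, S, O, P, N, Si. Default: uniform.
#' @param mass_weight positive weight on the mass-conservation row. The
#'   default (100) treats mass conservation as a heavily weighted soft
#'   constraint, so mixing fractions sum very close to 1 while a mass
#'   residual R_M is still defined.
#' @return An object of class `endmember_set`: a list with a `properties`
#'   matrix (endmembers x 6), `names`, `property_weights`, `mass_weight`.
#' @examples
#' em <- endmember_set(
#'   names = c("Kuroshio", "Oyashio"),
#'   T = c(20, 4), S = c(35.1, 33.2), O = c(210, 320),
#'   P = c(0.2, 1.9), N = c(1, 22), Si = c(3, 45)
#' )
#' @export
endmember_set <- function(names, T, S, O, P, N, Si,
                          property_weights = rep(1, 6),
                          mass_weight = 100) {
  props <- cbind(T = T, S = S, O = O, P = P, N = N, Si = Si)
  n <- length(names)
  if (n < 2L || n > 7L) {
    stop("endmember_set: need between 2 and 7 endmembers, got ", n)
  }
  if (nrow(props) != n) {
    stop("endmember_set: property vectors must have one value per endmember")
  }
  if (anyNA(props)) stop("endmember_set: endmember properties must not be NA")
  if (anyDuplicated(names)) stop("endmember_set: endmember names must be unique")
  # no two endmembers identical in all six properties
  if (anyDuplicated(props) > 0L) {
    stop("endmember_set: two endmembers share all six property values")
  }
  if (length(property_weights) != 6L || any(property_weights < 0)) {
    stop("endmember_set: property_weights must be 6 non-negative values")
  }
  if (length(mass_weight) != 1L || mass_weight <= 0) {
    stop("endmember_set: mass_weight must be a single positive value")
  }
  rownames(props) <- names
  structure(
    list(
      names = as.character(names),
      properties = props,
      property_weights = stats::setNames(as.numeric(property_weights),
                                         colnames(props)),
      mass_weight = as.numeric(mass_weight)
    ),
    class = "endmember_set"
  )
}

#' @export
print.endmember_set <- function(x, ...) {
  cat("Endmember set (", length(x$names), " water masses)\n", sep = "")
  print(x$properties)
  cat("property weights:", paste(signif(x$property_weights, 3), collapse = " "),
      " mass weight:", x$mass_weight, "\n")
  invisible(x)
}

#' Placeholder endmember definitions for the Kuroshio-Oyashio mixing region
#'
#' Default property sextuples for the warm, saline, oligotrophic Kuroshio,
#' the cold, fresh, nutrient-rich Oyashio, and (optionally) North Pacific
#' Intermediate Water (NPIW). The salinity extremes (35.1 and 33.2) follow
#' the observed transect range in the region; the oxygen and nutrient
#' contrasts are field-plausible placeholders. Real analyses should supply
#' endmembers derived from their own T-S diagrams via [endmember_set()] or an
#' endmember table file; these defaults exist so that the synthetic pipeline
#' has a concrete, realistic scenario.
#'
#' @param n_endmembers 2 (Kuroshio + Oyashio) or 3 (adds NPIW).
#' @param ... passed on to [endmember_set()] (e.g. `property_weights`,
#'   `mass_weight`).
#' @return An `endmember_set`.
#' @export
default_endmembers <- function(n_endmembers = 2, ...) {
  stopifnot(n_endmembers %in% c(2L, 3L))
  tab <- data.frame(
    name = c("Kuroshio", "Oyashio", "NPIW"),
    T = c(20.0, 4.0, 6.5),
    S = c(35.1, 33.2, 33.9),
    O = c(210, 320, 80),
    P = c(0.2, 1.9, 2.6),
    N = c(1.0, 22.0, 38.0),
    Si = c(3.0, 45.0, 90.0)
  )
  tab <- tab[seq_len(n_endmembers), ]
  endmember_set(names = tab$name, T = tab$T, S = tab$S, O = tab$O,
                P = tab$P, N = tab$N, Si = tab$Si, ...)
}
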