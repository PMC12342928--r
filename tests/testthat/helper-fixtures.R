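# shared fixtures and independent oracles

# small endmember sets used across tests
em2 <- function(...) default_endmembers(2, ...)
em3 <- function(...) default_endmembers(3, ...)

# Independent brute-force oracle for the OMP objective: dense grid over the
# probability simplex (step `step`), evaluating the same weighted stacked
# objective ||A x - b||^2 by direct enumeration. Only the design system is
# shared with the implementation; the optimization is exhaustive search.
simplex_grid <- function(n_em, step = 0.01) {
  stopifnot(n_em %in% 2:3)
  if (n_em == 2) {
    x1 <- seq(0, 1, by = step)
    rbind(x1, 1 - x1)
  } else {
    pts <- list()
    for (x1 in seq(0, 1, by = step)) {
      x2 <- seq(0, 1 - x1 + 1e-12, by = step)
      pts[[length(pts) + 1]] <- rbind(x1, x2, pmax(0, 1 - x1 - x2))
    }
    do.call(cbind, pts)
  }
}

grid_search_objective <- function(A, b, grid) {
  M <- A %*% grid                       # columns: candidate predictions
  colSums((M - as.numeric(b))^2)
}

# scaled observation vector for one sample, matching normalize_system scaling
scaled_obs <- function(sys, obs) {
  c(obs[sys$used] / sys$scale[sys$used] * sys$weights[sys$used],
    sys$mass_weight)
}

# random mixture samples from an endmember set (true fractions known)
random_mixture <- function(em, n, noise_sd = 0, seed = 1) {
  set.seed(seed)
  n_em <- length(em$names)
  fr <- matrix(stats::rexp(n * n_em), n, n_em)
  fr <- fr / rowSums(fr)
  props <- fr %*% em$properties
  noisy <- props + matrix(stats::rnorm(length(props), 0, noise_sd),
                          nrow(props), ncol(props))
  colnames(noisy) <- colnames(em$properties)
  list(samples = as.data.frame(noisy), fractions = fr)
}
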