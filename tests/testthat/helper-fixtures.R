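# Fixtures and independent oracles shared across the suite.

gaussian_spectrum <- function(centers, grid = seq(400, 1800, by = 1),
                              sigma = 10, amplitudes = 1, id = "gauss") {
  y <- numeric(length(grid))
  amplitudes <- rep_len(amplitudes, length(centers))
  for (k in seq_along(centers)) {
    y <- y + amplitudes[k] * exp(-(grid - centers[k])^2 / (2 * sigma^2))
  }
  spectrum(grid, y, id = id)
}

# adapter that always returns the same probability row
constant_model <- function(probs = c(0.3, 0.7)) {
  model_adapter(function(X) matrix(rep(probs, each = nrow(X)), nrow = nrow(X)),
                paste0("c", seq_along(probs)))
}

# an equally spaced k-zone partition of a grid
even_zones <- function(grid, k) {
  cuts <- floor(seq(0, length(grid), length.out = k + 1))
  zone_set(head(cuts, -1) + 1L, cuts[-1], grid)
}

# small reference set of smooth random spectra on a grid (deterministic)
random_reference <- function(grid, n = 12, seed = 42) {
  set.seed(seed)
  M <- t(vapply(seq_len(n), function(i) {
    centers <- sort(runif(3, min(grid) + 50, max(grid) - 50))
    amps <- runif(3, 0.2, 1)
    rowSums(vapply(1:3, function(k) {
      amps[k] * exp(-(grid - centers[k])^2 / (2 * 30^2))
    }, numeric(length(grid))))
  }, numeric(length(grid))))
  spectra_set(grid, M)
}

# Independent brute-force Shapley oracle: direct subset enumeration with the
# factorial weights, building each coalition spectrum by plain indexing. Kept
# free of the package's coalition machinery on purpose.
oracle_shap <- function(model, x, zs, background, class_index) {
  nz <- n_zones(zs)
  f_of <- function(keep) { # keep: integer set of retained zones
    v <- background
    for (i in keep) {
      idx <- seq(zs$zones$start[i], zs$zones$end[i])
      v[idx] <- x$intensities[idx]
    }
    predict_proba(model, v)[1, class_index]
  }
  phi <- numeric(nz)
  for (i in seq_len(nz)) {
    others <- setdiff(seq_len(nz), i)
    for (size in 0:length(others)) {
      subsets <- if (size == 0) list(integer(0))
                 else asplit(combn(others, size), 2)
      w <- factorial(size) * factorial(nz - size - 1) / factorial(nz)
      for (S in subsets) {
        phi[i] <- phi[i] + w * (f_of(c(S, i)) - f_of(S))
      }
    }
  }
  phi
}

# Closed-form weighted least squares oracle via the normal equations.
oracle_wls <- function(X, y, w) {
  D <- cbind(1, X)
  A <- t(D) %*% (w * D)
  drop(solve(A, t(D) %*% (w * y)))
}
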