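# Small synthetic fixtures shared across tests.

# A narrow grid around one absorption band, fine enough for exactness checks.
toy_grid <- function(center = 760.5, half = 12, step = 0.1) {
  wavelength_grid(center - half, center + half, step)
}

# Downwelling with a flat continuum and a single Gaussian absorption dip:
# equal shoulder values, which is what the interpolated-shoulder 3FLD
# formula assumes in addition to linear reflectance.
toy_downwelling <- function(grid, band = o2a_band(), e0 = 1000) {
  sif_spectrum(grid, e0 * band_transmittance(band, grid), "irradiance")
}

# Upwelling radiance for polynomial reflectance/fluorescence truths given as
# coefficient vectors in powers of (lambda - center).
toy_upwelling <- function(E, r_coef, f_coef, center) {
  x <- E$wavelength_nm - center
  r <- drop(outer(x, seq_along(r_coef) - 1, `^`) %*% r_coef)
  f <- drop(outer(x, seq_along(f_coef) - 1, `^`) %*% f_coef)
  sif_spectrum(E$wavelength_nm, E$value * r / pi + f, "radiance")
}

# Reduced-size study configuration for Monte-Carlo tests.
test_config <- function(n = 100, seed = 42) {
  experiment_config(n_realizations = n, seed = seed)
}

# Independent normal-equations least-squares solve, kept deliberately
# separate from the package's QR-based SFM fit.
normal_equations_sfm <- function(e, l, x, degree_r, degree_f) {
  p <- degree_r + degree_f + 2
  X <- matrix(0, length(x), p)
  for (j in 0:degree_r) X[, j + 1] <- e * x^j / pi
  for (j in 0:degree_f) X[, degree_r + 2 + j] <- x^j
  G <- matrix(0, p, p)
  b <- numeric(p)
  for (a in 1:p) {
    b[a] <- sum(X[, a] * l)
    for (c in 1:p) G[a, c] <- sum(X[, a] * X[, c])
  }
  solve(G, b)
}
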