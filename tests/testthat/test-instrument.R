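test_that("the Gaussian filter kernel has the documented shape", {
  k <- smoothing_kernel(fwhm_d = 0.9, ssi_o = 0.01, step = 0.01, half_range = 0.45)
  expect_equal(nrow(k), 91L)
  expect_equal(k$weight, rev(k$weight))          # even function
  expect_equal(which.max(k$weight), 46L)         # unimodal, peak at 0
  expect_true(all(diff(k$weight[1:46]) > 0))
  # value at the half-range offset is half the peak (0.45 = FWHM/2)
  expect_equal(k$weight[1] / k$weight[46], 0.5, tolerance = 1e-3)
  # truncated-Gaussian mass, frozen from numerical integration of the kernel
  # formula over +/-0.45 nm
  expect_equal(sum(k$weight) * 0.01, 0.7662, tolerance = 0.005)
  expect_error(smoothing_kernel(fwhm_d = 0.4, ssi_o = 0.5), "Degenerate")
})

test_that("smoothing preserves constants exactly and degrades a line to 0.9 nm FWHM", {
  spec <- instrument_spec()
  g <- wavelength_grid(470, 870, 0.01)
  const <- sif_spectrum(g, rep(3.7, length(g)), "radiance")
  out <- smooth_and_resample(const, spec)
  expect_equal(out$value, rep(3.7, nrow(out)), tolerance = 1e-12)
  expect_equal(out$wavelength_nm, instrument_grid(spec))

  # a delta-like emission line smooths to the instrument resolution
  line <- sif_spectrum(g, as.numeric(abs(g - 700.121) < 0.005), "radiance")
  sm <- stats::filter(line$value,
                      smoothing_kernel()$weight / sum(smoothing_kernel()$weight),
                      sides = 2)
  sm[is.na(sm)] <- 0
  sm <- as.numeric(sm)
  half <- max(sm) / 2
  cross <- function(i1, i2) { # linear interpolation of the half-max crossing
    stats::approx(sm[c(i1, i2)], g[c(i1, i2)], xout = half)$y
  }
  above <- range(which(sm >= half))
  fwhm <- cross(above[2], above[2] + 1) - cross(above[1] - 1, above[1])
  expect_lt(abs(fwhm - 0.9), 0.02)

  # monotone input stays monotone under a positive kernel
  mono <- sif_spectrum(g, seq_along(g) ^ 1.3, "radiance")
  expect_true(all(diff(smooth_and_resample(mono, spec)$value) > 0))

  # mean of a slowly varying input is preserved to 0.1%
  slow <- sif_spectrum(g, 2 + sin(g / 40), "radiance")
  sm2 <- smooth_and_resample(slow, spec)
  expect_equal(mean(sm2$value),
               mean(slow$value[g >= spec$grid_start & g <= spec$grid_end]),
               tolerance = 1e-3)

  short <- sif_spectrum(wavelength_grid(480, 870, 0.01), rep(1, 39001), "radiance")
  expect_error(smooth_and_resample(short, spec), "over-cover")
})

test_that("adjacent averaging is a centred mean with shrunken edges", {
  g <- wavelength_grid(700, 700.4, 0.1)
  s <- sif_spectrum(g, c(0, 3, 0, 3, 0), "radiance")
  expect_equal(adjacent_average(s, 3)$value, c(1.5, 1, 2, 1, 1.5))
  expect_equal(adjacent_average(s, 1)$value, s$value)
  const <- sif_spectrum(g, rep(2.2, 5), "radiance")
  expect_equal(adjacent_average(const, 5)$value, rep(2.2, 5))
  expect_error(adjacent_average(s, 2), "odd")
})

test_that("instrument spec validates its physical limits", {
  expect_error(instrument_spec(dark_counts = 5000), "3000")
  expect_error(instrument_spec(counts_ref = 0), "counts_ref")
  expect_error(instrument_spec(grid_start = 900, grid_end = 800), "grid_start")
  g <- instrument_grid(instrument_spec())
  expect_equal(g[1], 475.921)
  expect_equal(stats::median(diff(g)), 0.4)
})
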