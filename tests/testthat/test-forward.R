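test_that("downwelling irradiance follows the cosine law and band transmittance", {
  g <- wavelength_grid(700, 800, 0.05)
  plain <- simulate_downwelling(0, bands = list(), grid = g)
  expect_true(all(plain$value > 0))
  oblique <- simulate_downwelling(60, bands = list(), grid = g)
  expect_equal(oblique$value / plain$value, rep(0.5, length(g)), tolerance = 1e-12)

  band <- absorption_band(760.5, 0.7, 1.5)
  dipped <- simulate_downwelling(0, bands = list(band), grid = g)
  i <- snap_index(g, band$center)
  expect_equal(dipped$value[i] / plain$value[i], 0.3, tolerance = 1e-6)
  # strict local minimum at the band centre
  expect_lt(dipped$value[i], min(dipped$value[i - 1], dipped$value[i + 1]))
  expect_error(simulate_downwelling(30, bands = list(o2b_band()),
                                    grid = wavelength_grid(700, 800, 0.05)),
               "cover")
})

test_that("reflectance trends follow the configured canopy drivers", {
  g <- wavelength_grid(640, 820, 0.05)
  for (cab in c(10, 30, 50, 70)) {
    for (lai in 0:4) {
      r <- simulate_reflectance(canopy_scene(cab = cab, lai = lai), g)
      expect_true(all(r$value > 0 & r$value < 1))
    }
  }
  slope_in <- function(r, lo, hi) {
    sel <- r$wavelength_nm >= lo & r$wavelength_nm <= hi
    unname(stats::coef(stats::lm(r$value[sel] ~ r$wavelength_nm[sel]))[2])
  }
  curv_in <- function(r, lo, hi) {
    sel <- r$wavelength_nm >= lo & r$wavelength_nm <= hi
    x <- r$wavelength_nm[sel] - (lo + hi) / 2
    unname(stats::coef(stats::lm(r$value[sel] ~ x + I(x^2)))[3])
  }
  rs <- lapply(c(10, 30, 50, 70), function(cab)
    simulate_reflectance(canopy_scene(cab = cab), g))
  # O2-A trend-line slope rises with chlorophyll content
  s_a <- vapply(rs, slope_in, numeric(1), lo = 755, hi = 765)
  expect_true(all(diff(s_a) > 0))
  # O2-B trend-line slope falls with chlorophyll content
  s_b <- vapply(rs, slope_in, numeric(1), lo = 682, hi = 692)
  expect_true(all(diff(s_b) < 0))
  # O2-B curvature rises with leaf area index
  c_b <- vapply(1:4, function(lai)
    curv_in(simulate_reflectance(canopy_scene(lai = lai), g), 682, 692),
    numeric(1))
  expect_true(all(diff(c_b) > 0))
  # bare soil is much flatter near O2-B than a vegetated scene
  soil <- simulate_reflectance(canopy_scene(lai = 0), g)
  veg <- simulate_reflectance(canopy_scene(lai = 4), g)
  near <- abs(g - 687) < 5
  expect_lt(max(abs(diff(diff(soil$value[near])))),
            max(abs(diff(diff(veg$value[near])))))
})

test_that("fluorescence emission scales with illumination and canopy closure", {
  g <- wavelength_grid(640, 820, 0.05)
  zero <- simulate_fluorescence(canopy_scene(f_red_peak = 0, f_farred_peak = 0), g)
  expect_true(all(zero$value == 0))
  expect_true(all(simulate_fluorescence(canopy_scene(lai = 0), g)$value == 0))

  i760 <- snap_index(g, 760.519)
  at760 <- vapply(seq(10, 70, 5), function(sza)
    simulate_fluorescence(canopy_scene(sza = sza), g)$value[i760], numeric(1))
  expect_true(all(diff(at760) < 0))

  # total emission matches the closed-form two-Gaussian integral within 1%
  gw <- wavelength_grid(620, 900, 0.05)
  sc <- canopy_scene(sza = 0)
  f <- simulate_fluorescence(sc, gw)
  got <- sum(f$value) * 0.05
  want <- sqrt(2 * pi) * (sc$f_red_peak * 10 + sc$f_farred_peak * 35)
  expect_equal(got, want, tolerance = 0.01)
})

test_that("upwelling composition is E*R/pi + F", {
  g <- wavelength_grid(700, 800, 0.1)
  E <- simulate_downwelling(30, bands = list(o2a_band()), grid = g)
  half <- sif_spectrum(g, rep(0.5, length(g)), "reflectance")
  zero <- sif_spectrum(g, rep(0, length(g)), "radiance")
  L <- compose_upwelling(E, half, zero)
  expect_equal(L$value, E$value / (2 * pi), tolerance = 1e-12)

  E0 <- sif_spectrum(g, rep(0, length(g)), "irradiance")
  F <- simulate_fluorescence(canopy_scene(), g)
  expect_equal(compose_upwelling(E0, half, F)$value, F$value, tolerance = 1e-12)
  expect_error(compose_upwelling(E, half, simulate_fluorescence(canopy_scene(),
               wavelength_grid(700, 800, 0.2))), "grid")
})

test_that("the in-band fluorescence fraction exceeds the out-of-band fraction", {
  cfg <- test_config()
  obs <- simulate_observation(canopy_scene(), cfg)
  i_in <- snap_index(obs$l_up$wavelength_nm, 760.519)
  i_out <- snap_index(obs$l_up$wavelength_nm, 770)
  frac <- obs$fluorescence$value / obs$l_up$value
  expect_gt(frac[i_in], frac[i_out])
})

test_that("bare land yields zero fluorescence and zero noiseless retrievals", {
  bl <- bare_land_scene(wavelength_grid(640, 820, 0.05))
  expect_equal(sum(bl$fluorescence$value), 0)
  expect_true(all(bl$reflectance$value > 0 & bl$reflectance$value < 1))

  cfg <- test_config()
  obs <- simulate_observation(NULL, cfg, sza = 30)
  w <- default_windows("selected")
  for (i in seq_len(nrow(w))) {
    r <- retrieve_sif(obs$e_down, obs$l_up, w$window[[i]])
    expect_lt(abs(r$f_value), 1e-9)
  }
})
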