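test_that("FLD is exact when reflectance and fluorescence are constant", {
  g <- toy_grid()
  E <- toy_downwelling(g)
  w <- retrieval_window("FLD", "O2A", 760.5, 757.1)
  L <- toy_upwelling(E, 0.5, 0.8, 760.5)
  expect_equal(fld(E, L, w)$f_value, 0.8, tolerance = 1e-9)
  L0 <- toy_upwelling(E, 0.5, 0, 760.5)
  expect_equal(fld(E, L0, w)$f_value, 0, tolerance = 1e-9)
  flat <- sif_spectrum(g, rep(1000, length(g)), "irradiance")
  expect_error(fld(flat, L, w), "Degenerate")
})

test_that("3FLD interpolation weights sum to one for every bundled window", {
  w <- load_windows()
  w <- w[w$algorithm == "3FLD", ]
  for (i in seq_len(nrow(w))) {
    v <- w$window[[i]]
    wt <- canopysif:::three_fld_weights(v$lambda_left[1], v$lambda_in,
                                        v$lambda_right[1])
    expect_equal(sum(wt), 1)
    expect_true(all(wt > 0))
  }
})

test_that("3FLD is exact for linear reflectance and constant fluorescence", {
  g <- toy_grid()
  E <- toy_downwelling(g, absorption_band(760.5, 0.7, 1.5))
  w <- retrieval_window("3FLD", "O2A", 760.5, 756.0, 765.0)
  L <- toy_upwelling(E, c(0.4, 0.002), 0.5, 760.5)
  expect_equal(three_fld(E, L, w)$f_value, 0.5, tolerance = 1e-9)
})

test_that("SFM recovers polynomial truths exactly and matches the brute-force oracle", {
  g <- toy_grid(687.3, 6, 0.4)
  E <- toy_downwelling(g, o2b_band())
  w <- retrieval_window("SFM", "O2B", 687.3, 683.5, 691.5, 2L, 1L)
  r_coef <- c(0.08, 0.003, 2e-4)
  f_coef <- c(0.9, -0.01)
  L <- toy_upwelling(E, r_coef, f_coef, 687.3)
  got <- sfm(E, L, w)
  expect_equal(got$f_value, f_coef[1], tolerance = 1e-8)
  L0 <- toy_upwelling(E, r_coef, 0, 687.3)
  expect_lt(abs(sfm(E, L0, w)$f_value), 1e-8)

  # independent normal-equations solve on a <= 20-sample window
  sel <- canopysif:::sfm_sample_index(g, w)
  expect_lte(length(sel), 20)
  x <- g[sel] - w$lambda_in
  oracle <- normal_equations_sfm(E$value[sel], L$value[sel], x, 2L, 1L)
  X <- canopysif:::sfm_design(E$value[sel], x, 2L, 1L)
  beta <- qr.coef(qr(X), L$value[sel])
  expect_equal(unname(beta), oracle, tolerance = 1e-8)
  expect_equal(got$f_value, oracle[4], tolerance = 1e-8)

  narrow <- retrieval_window("SFM", "O2B", 687.3, 686.9, 687.3 + 0.5, 2L, 1L)
  expect_error(sfm(E, L, narrow), "Underdetermined")
})

test_that("each algorithm recovers random truths satisfying its own assumptions", {
  set.seed(202)
  g <- toy_grid(760.5, 14, 0.2)
  for (rep in 1:10) {
    E <- toy_downwelling(g, absorption_band(760.5, stats::runif(1, 0.3, 0.8), 1.5))
    f0 <- stats::runif(1, 0.2, 3)
    r0 <- stats::runif(1, 0.2, 0.6)

    w1 <- retrieval_window("FLD", "O2A", 760.5, 757.1)
    expect_equal(fld(E, toy_upwelling(E, r0, f0, 760.5), w1)$f_value,
                 f0, tolerance = 1e-8 * f0)

    w2 <- retrieval_window("3FLD", "O2A", 760.5, 755.1, 765.9)
    r_lin <- c(r0, stats::runif(1, -3e-3, 3e-3))
    expect_equal(three_fld(E, toy_upwelling(E, r_lin, f0, 760.5), w2)$f_value,
                 f0, tolerance = 1e-8 * f0)

    w3 <- retrieval_window("SFM", "O2A", 760.5, 754.0, 768.0, 2L, 1L)
    r_quad <- c(r0, stats::runif(1, -3e-3, 3e-3), stats::runif(1, -1e-4, 1e-4))
    f_lin <- c(f0, stats::runif(1, -0.01, 0.01))
    expect_equal(sfm(E, toy_upwelling(E, r_quad, f_lin, 760.5), w3)$f_value,
                 f0, tolerance = 1e-8 * f0)
  }
})

test_that("FLD overestimates on the vegetated scene and 3FLD/SFM bias less", {
  cfg <- test_config()
  obs <- simulate_observation(canopy_scene(cab = 40, lai = 4, sza = 30), cfg)
  sel <- default_windows("selected", "O2A")
  f <- purrr::map_dbl(sel$window, function(w) {
    retrieve_sif(obs$e_down, obs$l_up, w)$f_value
  })
  names(f) <- sel$algorithm
  truth <- canopysif:::observation_truth(obs, sel$window[[1]])
  expect_gt(f[["FLD"]], truth)
  expect_gt(abs(f[["FLD"]] - truth), abs(f[["3FLD"]] - truth))
  expect_gt(abs(f[["FLD"]] - truth), abs(f[["SFM"]] - truth))
})

test_that("ensemble statistics pair realizations and audit the truth", {
  g <- toy_grid()
  E <- toy_downwelling(g)
  w <- retrieval_window("FLD", "O2A", 760.5, 757.1)
  L <- toy_upwelling(E, 0.5, 0.8, 760.5)
  one_e <- tibble::tibble(wavelength_nm = g, r1 = E$value)
  one_l <- tibble::tibble(wavelength_nm = g, r1 = L$value)
  st <- retrieve_ensemble(one_e, one_l, w, truth = 0.7)
  expect_equal(st$stats$sd, 0)
  expect_equal(st$stats$bias, st$stats$mean - 0.7)
  expect_equal(st$stats$truth, 0.7)
  expect_equal(nrow(tidy(st)), 1)
  expect_equal(glance(st)$n, 1)
  bad <- tibble::tibble(wavelength_nm = g, r1 = L$value, r2 = L$value)
  expect_error(retrieve_ensemble(one_e, bad, w, 0.7), "equal")
})

test_that("noise ensembles at lower sun elevations retrieve with less spread", {
  cfg <- test_config(n = 150)
  inst <- cfg$instrument
  w <- default_windows("selected", "O2A")
  w3 <- w$window[[which(w$algorithm == "3FLD")]]
  sd_at <- function(sza, off) {
    obs <- simulate_observation(canopy_scene(sza = sza), cfg)
    me <- noise_model(inst$snr_ref, inst$counts_ref, seed = cfg$seed + off)
    ml <- noise_model(inst$snr_ref, inst$counts_ref, seed = cfg$seed + off + 1000)
    E <- noisy_ensemble(obs$e_down, cfg$n_realizations, me, inst$calibration)
    L <- noisy_ensemble(obs$l_up, cfg$n_realizations, ml, inst$calibration)
    glance(retrieve_ensemble(E, L, w3, canopysif:::observation_truth(obs, w3)))$sd
  }
  expect_lt(sd_at(60, 20), sd_at(30, 40))
})
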