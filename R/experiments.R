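#' Evaluation experiment configuration
#'
#' Default study conditions for the Monte-Carlo evaluation: chlorophyll
#' contents 10/30/50/70 ug/cm2, leaf area indices 0--4 and solar zenith
#' angles 10--70 degrees in 5-degree steps, with the off-sweep drivers fixed
#' at cab = 40 ug/cm2, lai = 4 and sza = 30 degrees; 1000 noise realizations
#' per cell. Reduced replicate counts (e.g. `n_realizations = 100`) preserve
#' the ordering and monotonicity structure with wider noise on the
#' statistics.
#'
#' @param n_realizations Ensemble size per cell.
#' @param cab_values,lai_values,sza_values Sweep grids.
#' @param fixed_cab,fixed_lai,fixed_sza Drivers held fixed off-sweep.
#' @param seed Base seed; every ensemble derives a deterministic substream.
#' @param instrument An [instrument_spec()].
#' @param bands Absorption bands of the downwelling simulator.
#' @param grid High-resolution working grid, nm.
#' @param stretch_target Counts assigned to each spectrum maximum before
#'   noise injection.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(n_realizations = 1000,
                              cab_values = c(10, 30, 50, 70),
                              lai_values = 0:4,
                              sza_values = seq(10, 70, by = 5),
                              fixed_cab = 40, fixed_lai = 4, fixed_sza = 30,
                              seed = 1,
                              instrument = instrument_spec(),
                              bands = list(o2a_band(), o2b_band()),
                              grid = wavelength_grid(),
                              stretch_target = 50000) {
  stopifnot(n_realizations >= 1, length(cab_values) > 0,
            length(lai_values) > 0, length(sza_values) > 0)
  structure(list(
    n_realizations = n_realizations, cab_values = cab_values,
    lai_values = lai_values, sza_values = sza_values,
    fixed_cab = fixed_cab, fixed_lai = fixed_lai, fixed_sza = fixed_sza,
    seed = seed, instrument = instrument, bands = bands, grid = grid,
    stretch_target = stretch_target
  ), class = "experiment_config")
}

#' Simulate one observation at instrument resolution
#'
#' Runs the forward chain for a scene (or bare land): high-resolution
#' downwelling irradiance, reflectance and fluorescence; upwelling radiance
#' `E * R / pi + F`; then Gaussian smoothing and resampling of every
#' component onto the instrument grid. The resampled fluorescence provides
#' the injected truth that retrievals are judged against.
#'
#' @param scene A [canopy_scene()], or `NULL` for bare land.
#' @param config An [experiment_config()] supplying instrument, bands and grid.
#' @param sza Solar zenith angle override in degrees (required for bare land).
#' @return A list of class `sif_observation` with instrument-grid spectra
#'   `e_down` (irradiance), `l_up` (radiance), `fluorescence` (radiance) and
#'   `reflectance`, plus the scene and sza used.
#' @export
simulate_observation <- function(scene, config = experiment_config(), sza = NULL) {
  grid <- config$grid
  inst <- config$instrument
  if (is.null(scene)) {
    if (is.null(sza)) rlang::abort("Bare land needs an explicit `sza`.")
    bl <- bare_land_scene(grid)
    R <- bl$reflectance
    F <- bl$fluorescence
  } else {
    if (is.null(sza)) sza <- scene$sza else scene$sza <- sza
    R <- simulate_reflectance(scene, grid)
    F <- simulate_fluorescence(scene, grid)
  }
  E <- simulate_downwelling(sza, config$bands, grid)
  L <- compose_upwelling(E, R, F)
  kern <- smoothing_kernel(fwhm_d = inst$fwhm_d)
  structure(list(
    e_down = smooth_and_resample(E, inst, kern),
    l_up = smooth_and_resample(L, inst, kern),
    fluorescence = smooth_and_resample(F, inst, kern),
    reflectance = smooth_and_resample(R, inst, kern),
    scene = scene, sza = sza
  ), class = "sif_observation")
}

# Injected truth for a window: resampled fluorescence at the snapped
# in-band wavelength.
observation_truth <- function(obs, window) {
  i <- snap_index(obs$fluorescence$wavelength_nm, window$lambda_in)
  obs$fluorescence$value[i]
}

clean_ensemble <- function(spectrum) {
  out <- tibble::tibble(wavelength_nm = spectrum$wavelength_nm, r1 = spectrum$value)
  attr(out, "unit") <- sif_unit(spectrum)
  out
}

# Retrieve every window of a window table against one observation,
# noiselessly or over a paired noise ensemble with substream seeds.
run_retrieval_set <- function(obs, windows, config, noiseless = FALSE,
                              seed_offset = 0) {
  inst <- config$instrument
  if (noiseless) {
    E_ens <- clean_ensemble(obs$e_down)
    L_ens <- clean_ensemble(obs$l_up)
  } else {
    model_e <- noise_model(inst$snr_ref, inst$counts_ref,
                           seed = config$seed + seed_offset)
    model_l <- noise_model(inst$snr_ref, inst$counts_ref,
                           seed = config$seed + seed_offset + 500000L)
    E_ens <- noisy_ensemble(obs$e_down, config$n_realizations, model_e,
                            inst$calibration, config$stretch_target)
    L_ens <- noisy_ensemble(obs$l_up, config$n_realizations, model_l,
                            inst$calibration, config$stretch_target)
  }
  purrr::pmap_dfr(windows, function(set, candidate, window, ...) {
    st <- glance(retrieve_ensemble(E_ens, L_ens, window,
                                   observation_truth(obs, window)))
    dplyr::bind_cols(tibble::tibble(set = set, candidate = candidate), st)
  })
}

#' Compare candidate retrieval parameter sets on the reference scene
#'
#' Runs every bundled candidate window and the selected window, for all three
#' algorithms and both bands, on the reference scene (cab = 40, lai = 4,
#' sza = 30 degrees). Noiseless by default so the reported bias isolates the
#' systematic error of each parameter choice; with `noiseless = FALSE` the
#' full noise ensemble is used. Each selected row is flagged with whether it
#' attains the smallest absolute bias among its algorithm's candidates.
#'
#' @param config An [experiment_config()].
#' @param noiseless Retrieve without noise injection (default) or over the
#'   configured ensemble.
#' @return A tibble of per-window retrieval statistics with a
#'   `selected_is_best` flag on selected rows.
#' @export
run_parameter_comparison <- function(config = experiment_config(),
                                     noiseless = TRUE) {
  scene <- canopy_scene(cab = config$fixed_cab, lai = config$fixed_lai,
                        sza = config$fixed_sza)
  obs <- simulate_observation(scene, config)
  windows <- load_windows()
  out <- run_retrieval_set(obs, windows, config, noiseless = noiseless,
                           seed_offset = 10000L)
  out <- dplyr::group_by(out, .data$algorithm, .data$band)
  out <- dplyr::mutate(out,
    selected_is_best = .data$set == "selected" &
      abs(.data$bias) <= min(abs(.data$bias[.data$set == "candidate"]))
  )
  dplyr::ungroup(out)
}

sweep_core <- function(config, scenes, label, values, windows,
                       seed_base, noiseless = FALSE) {
  purrr::map2_dfr(scenes, seq_along(scenes), function(sc, k) {
    obs <- simulate_observation(sc$scene, config, sza = sc$sza)
    st <- run_retrieval_set(obs, windows, config, noiseless = noiseless,
                            seed_offset = seed_base + k * 1000L)
    st[[label]] <- values[[k]]
    if (!is.null(sc$target)) st$target <- sc$target
    st
  })
}

#' Chlorophyll-content sweep
#'
#' Monte-Carlo retrieval statistics for the selected windows over the
#' configured chlorophyll contents (lai and sza fixed).
#'
#' @param config An [experiment_config()].
#' @param noiseless Skip noise injection (single noiseless retrieval per cell).
#' @return A tibble keyed by `cab`, `algorithm`, `band`.
#' @export
sweep_cab <- function(config = experiment_config(), noiseless = FALSE) {
  scenes <- lapply(config$cab_values, function(cab) {
    list(scene = canopy_scene(cab = cab, lai = config$fixed_lai,
                              sza = config$fixed_sza), sza = NULL)
  })
  sweep_core(config, scenes, "cab", config$cab_values,
             default_windows("selected"), 100000L, noiseless)
}

#' Leaf-area-index sweep
#'
#' As [sweep_cab()], over the configured leaf area indices, with the selected
#' windows plus an additional SFM(1,1) variant at O2-B (linear reflectance
#' and fluorescence fits, which favour sparse canopies whose red-edge
#' reflectance is nearly straight). `lai = 0` is the bare-soil, zero-truth
#' case.
#'
#' @inheritParams sweep_cab
#' @return A tibble keyed by `lai`, `algorithm`, `band` (the SFM(1,1) variant
#'   carries `set = "SFM11"`).
#' @export
sweep_lai <- function(config = experiment_config(), noiseless = FALSE) {
  windows <- default_windows("selected")
  sel_b <- windows[windows$algorithm == "SFM" & windows$band == "O2B", ]
  v <- sel_b$window[[1]]
  sfm11 <- retrieval_window("SFM", "O2B", v$lambda_in, v$lambda_left,
                            v$lambda_right, 1L, 1L)
  extra <- sel_b
  extra$set <- "SFM11"
  extra$degree_r <- 1L
  extra$window <- list(sfm11)
  windows <- dplyr::bind_rows(windows, extra)
  scenes <- lapply(config$lai_values, function(lai) {
    list(scene = canopy_scene(cab = config$fixed_cab, lai = lai,
                              sza = config$fixed_sza), sza = NULL)
  })
  sweep_core(config, scenes, "lai", config$lai_values, windows, 200000L, noiseless)
}

#' Solar-zenith-angle sweep over vegetation and bare land
#'
#' As [sweep_cab()], over the configured solar zenith angles, run for both the
#' reference vegetation scene and the bare-land (zero fluorescence) target.
#'
#' @inheritParams sweep_cab
#' @return A tibble keyed by `sza_deg`, `target`, `algorithm`, `band`.
#' @export
sweep_sza <- function(config = experiment_config(), noiseless = FALSE) {
  windows <- default_windows("selected")
  mk <- function(sza, target) {
    if (target == "vegetation") {
      list(scene = canopy_scene(cab = config$fixed_cab, lai = config$fixed_lai,
                                sza = sza), sza = NULL, target = target)
    } else {
      list(scene = NULL, sza = sza, target = target)
    }
  }
  scenes <- c(lapply(config$sza_values, mk, target = "vegetation"),
              lapply(config$sza_values, mk, target = "bare_land"))
  sweep_core(config, scenes, "sza_deg",
             rep(config$sza_values, 2), windows, 300000L, noiseless)
}

#' Solar zenith angle of a diurnal trajectory
#'
#' Standard solar geometry: `cos(sza) = sin(lat) sin(decl) +
#' cos(lat) cos(decl) cos(h)` with hour angle `h = 15 deg * (t - solar_noon)`.
#'
#' @param hour Local time in decimal hours.
#' @param lat_deg Site latitude, degrees.
#' @param decl_deg Solar declination, degrees.
#' @param solar_noon Local time of solar noon, decimal hours.
#' @return Solar zenith angle in degrees.
#' @export
solar_zenith <- function(hour, lat_deg = 39.14, decl_deg = -7.3,
                         solar_noon = 12.1) {
  to_r <- pi / 180
  h <- 15 * (hour - solar_noon) * to_r
  cz <- sin(lat_deg * to_r) * sin(decl_deg * to_r) +
    cos(lat_deg * to_r) * cos(decl_deg * to_r) * cos(h)
  acos(pmin(pmax(cz, -1), 1)) / to_r
}

#' Diurnal observation analogue
#'
#' Simulates a day of alternating vegetation / bare-land observations driven
#' by a diurnal solar-zenith trajectory. Vegetation SIF at both bands is
#' retrieved noiselessly with the selected 3FLD and SFM windows (so the
#' series isolates the illumination-driven diurnal shape); bare land is
#' retrieved from one noisy realization per time step, emulating the
#' single-shot field measurements of the zero-fluorescence control.
#' Photosynthetically active radiation is modelled as `par_max * cos(sza)`.
#'
#' @param config An [experiment_config()].
#' @param hours Sampling times in decimal hours.
#' @param lat_deg,decl_deg,solar_noon Solar-geometry parameters.
#' @param par_max PAR for an overhead sun, umol m-2 s-1.
#' @return A tibble with one row per time step, algorithm, band and target:
#'   `hour`, `sza_deg`, `par`, `target`, `algorithm`, `band`, `f_value`,
#'   `truth`.
#' @export
diurnal_simulation <- function(config = experiment_config(),
                               hours = seq(10.5, 16.5, by = 0.25),
                               lat_deg = 39.14, decl_deg = -7.3,
                               solar_noon = 12.1, par_max = 2000) {
  windows <- default_windows("selected")
  windows <- windows[windows$algorithm %in% c("3FLD", "SFM"), ]
  inst <- config$instrument
  purrr::map2_dfr(hours, seq_along(hours), function(hr, k) {
    sza <- solar_zenith(hr, lat_deg, decl_deg, solar_noon)
    if (sza >= 90) return(NULL)
    par <- par_max * cos(sza * pi / 180)
    veg <- simulate_observation(
      canopy_scene(cab = config$fixed_cab, lai = config$fixed_lai, sza = sza),
      config)
    bare <- simulate_observation(NULL, config, sza = sza)
    model_e <- noise_model(inst$snr_ref, inst$counts_ref,
                           seed = config$seed + 400000L + k)
    model_l <- noise_model(inst$snr_ref, inst$counts_ref,
                           seed = config$seed + 450000L + k)
    bare_e <- add_noise(bare$e_down, model_e, inst$calibration,
                        config$stretch_target)
    bare_l <- add_noise(bare$l_up, model_l, inst$calibration,
                        config$stretch_target)
    purrr::pmap_dfr(windows, function(window, ...) {
      rv <- retrieve_sif(veg$e_down, veg$l_up, window)
      rb <- retrieve_sif(bare_e, bare_l, window)
      tibble::tibble(
        hour = hr, sza_deg = sza, par = par,
        target = c("vegetation", "bare_land"),
        algorithm = window$algorithm, band = window$band,
        f_value = c(rv$f_value, rb$f_value),
        truth = c(observation_truth(veg, window), 0)
      )
    })
  })
}

#' Diurnal vegetation indices
#'
#' PRI and red-edge chlorophyll index of the vegetation scene along a diurnal
#' solar trajectory, computed from the instrument-resolution reflectance.
#'
#' @inheritParams diurnal_simulation
#' @return A tibble: `hour`, `sza_deg`, `par`, `name`, `value`.
#' @export
diurnal_indices <- function(config = experiment_config(),
                            hours = seq(10.5, 16.5, by = 0.25),
                            lat_deg = 39.14, decl_deg = -7.3,
                            solar_noon = 12.1, par_max = 2000) {
  purrr::map_dfr(hours, function(hr) {
    sza <- solar_zenith(hr, lat_deg, decl_deg, solar_noon)
    if (sza >= 90) return(NULL)
    obs <- simulate_observation(
      canopy_scene(cab = config$fixed_cab, lai = config$fixed_lai, sza = sza),
      config)
    dplyr::bind_cols(
      tibble::tibble(hour = hr, sza_deg = sza,
                     par = par_max * cos(sza * pi / 180)),
      dplyr::bind_rows(pri(obs$reflectance), ci_rededge(obs$reflectance))
    )
  })
}
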