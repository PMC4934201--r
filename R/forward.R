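#' Telluric absorption band
#'
#' A Gaussian transmittance feature `T(lambda) = 1 - depth *
#' exp(-(lambda - center)^2 / (2 width^2))`. The O2-A feature near 760.5 nm is
#' configured deeper than the O2-B feature near 687.3 nm, as observed in
#' ground-level solar spectra.
#'
#' @param center Band centre in nm.
#' @param depth Fractional depth at the centre, in \[0, 1).
#' @param width Gaussian sigma in nm.
#' @return A list of class `absorption_band`.
#' @export
absorption_band <- function(center, depth, width) {
  stopifnot(is.numeric(center), is.numeric(depth), is.numeric(width))
  if (depth < 0 || depth >= 1) rlang::abort("Band depth must lie in [0, 1).")
  if (width <= 0) rlang::abort("Band width must be positive.")
  structure(list(center = center, depth = depth, width = width),
            class = "absorption_band")
}

#' @rdname absorption_band
#' @export
o2a_band <- function(center = 760.519, depth = 0.7, width = 1.5) {
  absorption_band(center, depth, width)
}

#' @rdname absorption_band
#' @export
o2b_band <- function(center = 687.276, depth = 0.4, width = 1.0) {
  absorption_band(center, depth, width)
}

#' @rdname absorption_band
#' @param bands List of `absorption_band` objects.
#' @param wavelength_nm Wavelengths at which to evaluate transmittance.
#' @export
band_transmittance <- function(bands, wavelength_nm) {
  if (inherits(bands, "absorption_band")) bands <- list(bands)
  tr <- rep(1, length(wavelength_nm))
  for (b in bands) {
    tr <- tr * (1 - b$depth * exp(-(wavelength_nm - b$center)^2 / (2 * b$width^2)))
  }
  tr
}

#' Canopy scene description
#'
#' Biophysical drivers of the forward simulator: chlorophyll a+b content,
#' leaf area index, solar zenith angle, the two fluorescence emission peak
#' amplitudes, and the reflectance shape coefficients. Fluorescence amplitudes
#' are the emitted radiances of the red (~687 nm) and far-red (~740 nm) peaks
#' for an overhead sun and a closed canopy; `simulate_fluorescence()` scales
#' them by `cos(sza)` and by canopy closure, so `lai = 0` implies zero
#' emission.
#'
#' @param cab Chlorophyll a+b content in ug/cm2 (>= 0).
#' @param lai Leaf area index (>= 0); 0 means bare soil.
#' @param sza Solar zenith angle in degrees, in \[0, 90).
#' @param f_red_peak,f_farred_peak Fluorescence peak radiances
#'   (mW m-2 sr-1 nm-1) at 687 and 740 nm for sza = 0, closed canopy.
#' @param red_edge_nm Red-edge inflection wavelength of the canopy logistic.
#' @param red_edge_scale_nm Logistic slope scale of the red edge, nm.
#' @param slope_o2a_per_cab Local reflectance slope added near the O2-A band,
#'   per nm per unit cab. Positive: slope grows with chlorophyll content.
#' @param slope_o2b_per_cab Local slope added near the O2-B band, per nm per
#'   unit cab. Negative by default: the red-edge slope flattens as chlorophyll
#'   deepens red absorption.
#' @param curv_o2b_per_lai Local curvature added near the O2-B band, per nm2
#'   per unit lai.
#' @param soil_level Soil reflectance level used for the bare fraction.
#' @return A list of class `canopy_scene`.
#' @export
canopy_scene <- function(cab = 40, lai = 4, sza = 30,
                         f_red_peak = 1.0, f_farred_peak = 2.0,
                         red_edge_nm = 708, red_edge_scale_nm = 7,
                         slope_o2a_per_cab = 4e-5,
                         slope_o2b_per_cab = -3e-5,
                         curv_o2b_per_lai = 3e-5,
                         soil_level = 0.25) {
  if (cab < 0) rlang::abort("`cab` must be >= 0.")
  if (lai < 0) rlang::abort("`lai` must be >= 0.")
  if (sza < 0 || sza >= 90) rlang::abort("`sza` must lie in [0, 90).")
  if (f_red_peak < 0 || f_farred_peak < 0) {
    rlang::abort("Fluorescence amplitudes must be >= 0.")
  }
  structure(list(
    cab = cab, lai = lai, sza = sza,
    f_red_peak = f_red_peak, f_farred_peak = f_farred_peak,
    red_edge_nm = red_edge_nm, red_edge_scale_nm = red_edge_scale_nm,
    slope_o2a_per_cab = slope_o2a_per_cab,
    slope_o2b_per_cab = slope_o2b_per_cab,
    curv_o2b_per_lai = curv_o2b_per_lai,
    soil_level = soil_level
  ), class = "canopy_scene")
}

# Canopy closure weight: fraction of the field of view filled by foliage.
canopy_closure <- function(lai) 1 - exp(-0.7 * lai)

# Planck-shaped solar continuum, normalised so its maximum over the grid
# equals e_max (mW m-2 nm-1) for an overhead sun.
solar_continuum <- function(wavelength_nm, e_max = 1200, t_sun = 5800) {
  h <- 6.62607015e-34; c0 <- 2.99792458e8; kb <- 1.380649e-23
  lm <- wavelength_nm * 1e-9
  b <- 1 / (lm^5 * (exp(h * c0 / (lm * kb * t_sun)) - 1))
  b / max(b) * e_max
}

#' Simulate downwelling irradiance
#'
#' A smooth Planck-shaped solar continuum multiplied by the product of the
#' configured band transmittances and by `cos(sza)`.
#'
#' @param sza Solar zenith angle in degrees, \[0, 90).
#' @param bands List of [absorption_band()] objects (may be empty).
#' @param grid Wavelength grid (nm), covering every band centre.
#' @param e_max Continuum maximum for an overhead sun, mW m-2 nm-1.
#' @return An irradiance [sif_spectrum()].
#' @export
simulate_downwelling <- function(sza, bands = list(o2a_band(), o2b_band()),
                                 grid = wavelength_grid(), e_max = 1200) {
  if (sza < 0 || sza >= 90) rlang::abort("`sza` must lie in [0, 90).")
  if (inherits(bands, "absorption_band")) bands <- list(bands)
  for (b in bands) {
    if (b$center < min(grid) || b$center > max(grid)) {
      rlang::abort(sprintf("Grid does not cover band centre %.3f nm.", b$center))
    }
  }
  e <- solar_continuum(grid, e_max) * cos(sza * pi / 180) *
    band_transmittance(bands, grid)
  sif_spectrum(grid, e, "irradiance")
}

# Smooth bare-soil reflectance; flat by default so that noiseless retrievals
# over soil are exact for every algorithm's reflectance assumption.
soil_reflectance_values <- function(wavelength_nm, level = 0.25, slope_per_nm = 0) {
  pmin(pmax(level + slope_per_nm * (wavelength_nm - 700), 1e-3), 0.999)
}

#' Simulate canopy reflectance
#'
#' A logistic red edge for the foliage, mixed with a smooth soil background by
#' canopy closure, plus local slope/curvature terms near the two oxygen bands:
#' the trend-line slope near O2-A grows with `cab`, while near O2-B the slope
#' shrinks with `cab` and the curvature grows with `lai`. `lai = 0` returns
#' the bare-soil spectrum.
#'
#' @param scene A [canopy_scene()].
#' @param grid Wavelength grid in nm.
#' @return A reflectance [sif_spectrum()].
#' @export
simulate_reflectance <- function(scene, grid = wavelength_grid()) {
  stopifnot(inherits(scene, "canopy_scene"))
  soil <- soil_reflectance_values(grid, scene$soil_level)
  if (scene$lai == 0) {
    return(sif_spectrum(grid, soil, "reflectance"))
  }
  r_red <- 0.02 + 0.10 * exp(-scene$cab / 50)
  r_nir <- 0.55
  z <- (grid - scene$red_edge_nm) / scene$red_edge_scale_nm
  leaf <- r_red + (r_nir - r_red) * stats::plogis(z)
  # green reflectance peak, fading with chlorophyll content
  leaf <- leaf + 0.04 * exp(-scene$cab / 40) * exp(-(grid - 550)^2 / (2 * 20^2))
  # local trend-line slope near O2-A, proportional to cab; the wide window
  # keeps the curve close to a straight line within +/-15 nm of the band
  da <- grid - 760.5
  leaf <- leaf + scene$slope_o2a_per_cab * scene$cab * da * exp(-da^2 / (2 * 45^2))
  # local slope (cab) and curvature (lai) near O2-B
  db <- grid - 687.3
  wb <- exp(-db^2 / (2 * 12^2))
  leaf <- leaf + wb * (scene$slope_o2b_per_cab * scene$cab * db +
                         scene$curv_o2b_per_lai * scene$lai * (db^2 - 144))
  w <- canopy_closure(scene$lai)
  r <- pmin(pmax(w * leaf + (1 - w) * soil, 1e-3), 0.999)
  sif_spectrum(grid, r, "reflectance")
}

#' Simulate canopy fluorescence emission
#'
#' Two Gaussian peaks (red ~687 nm, sigma 10 nm; far-red ~740 nm, sigma
#' 35 nm), scaled by `cos(sza)` (emission follows absorbed light) and by
#' canopy closure so a bare scene emits nothing.
#'
#' @inheritParams simulate_reflectance
#' @return A radiance [sif_spectrum()].
#' @export
simulate_fluorescence <- function(scene, grid = wavelength_grid()) {
  stopifnot(inherits(scene, "canopy_scene"))
  closure <- canopy_closure(scene$lai) / canopy_closure(4)
  s <- cos(scene$sza * pi / 180) * closure
  f <- s * (scene$f_red_peak * exp(-(grid - 687)^2 / (2 * 10^2)) +
              scene$f_farred_peak * exp(-(grid - 740)^2 / (2 * 35^2)))
  sif_spectrum(grid, f, "radiance")
}

#' Compose upwelling radiance
#'
#' `L = E * R / pi + F`: reflected sunlight from a Lambertian target plus the
#' additive fluorescence emission.
#'
#' @param E Downwelling irradiance spectrum.
#' @param R Reflectance spectrum on the same grid.
#' @param F Fluorescence radiance spectrum on the same grid.
#' @return A radiance [sif_spectrum()].
#' @export
compose_upwelling <- function(E, R, F) {
  stopifnot_same_grid(E, R, F)
  if (sif_unit(E) != "irradiance") rlang::abort("`E` must be an irradiance spectrum.")
  if (sif_unit(R) != "reflectance") rlang::abort("`R` must be a reflectance spectrum.")
  l <- E$value * R$value / pi + F$value
  sif_spectrum(E$wavelength_nm, l, "radiance")
}

#' Bare-land scene spectra
#'
#' Bare soil emits no fluorescence, which makes it a natural zero-SIF control
#' target: any retrieval run on noiseless bare-land spectra should return 0.
#'
#' @param grid Wavelength grid in nm.
#' @param soil_level Soil reflectance level.
#' @return A list with elements `reflectance` and `fluorescence` (both
#'   [sif_spectrum()]; the fluorescence is identically zero).
#' @export
bare_land_scene <- function(grid = wavelength_grid(), soil_level = 0.25) {
  list(
    reflectance = sif_spectrum(grid, soil_reflectance_values(grid, soil_level),
                               "reflectance"),
    fluorescence = sif_spectrum(grid, rep(0, length(grid)), "radiance")
  )
}
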