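#' Spectral data as a tibble
#'
#' A spectrum is a tibble with columns `wavelength_nm` and `value` plus a
#' `unit` attribute. Wavelengths must be finite, strictly increasing and lie
#' within the 400--1000 nm working range of the simulator. Reflectance values
#' must lie in \[0, 1\] and counts must be non-negative.
#'
#' @param wavelength_nm Numeric vector of wavelengths in nanometres.
#' @param value Numeric vector of the same length as `wavelength_nm`.
#' @param unit One of `"radiance"` (mW m-2 sr-1 nm-1), `"irradiance"`
#'   (mW m-2 nm-1), `"reflectance"` (unitless) or `"counts"`.
#' @return A tibble of class `sif_spectrum`.
#' @examples
#' sif_spectrum(seq(750, 770, 0.5), rep(0.45, 41), "reflectance")
#' @export
sif_spectrum <- function(wavelength_nm, value, unit = c("radiance", "irradiance", "reflectance", "counts")) {
  unit <- match.arg(unit)
  wavelength_nm <- as.numeric(wavelength_nm)
  value <- as.numeric(value)
  validate_grid(wavelength_nm)
  if (length(value) != length(wavelength_nm)) {
    rlang::abort("`value` and `wavelength_nm` must have the same length.")
  }
  if (anyNA(value) || any(!is.finite(value))) {
    rlang::abort("Spectrum values must all be finite.")
  }
  if (unit == "reflectance" && (any(value < 0) || any(value > 1))) {
    rlang::abort("Reflectance values must lie in [0, 1].")
  }
  if (unit == "counts" && any(value < 0)) {
    rlang::abort("Counts must be non-negative.")
  }
  out <- tibble::tibble(wavelength_nm = wavelength_nm, value = value)
  attr(out, "unit") <- unit
  class(out) <- c("sif_spectrum", class(out))
  out
}

validate_grid <- function(wavelength_nm) {
  if (length(wavelength_nm) < 1L) {
    rlang::abort("A wavelength grid needs at least one sample.")
  }
  if (anyNA(wavelength_nm) || any(!is.finite(wavelength_nm))) {
    rlang::abort("Wavelengths must all be finite.")
  }
  if (length(wavelength_nm) > 1L && any(diff(wavelength_nm) <= 0)) {
    rlang::abort("Wavelengths must be strictly increasing.")
  }
  if (any(wavelength_nm < 400) || any(wavelength_nm > 1000)) {
    rlang::abort("Wavelengths must lie within [400, 1000] nm.")
  }
  invisible(wavelength_nm)
}

#' Uniform wavelength grid
#'
#' @param from,to Range in nm (inclusive of `from`; `to` is reached when
#'   `(to - from)` is a multiple of `step`).
#' @param step Sampling interval in nm; the working default of 0.01 nm matches
#'   the high-resolution grid the instrument smoothing operates on.
#' @return Numeric vector of wavelengths.
#' @export
wavelength_grid <- function(from = 400, to = 1000, step = 0.01) {
  g <- seq(from, to, by = step)
  validate_grid(g)
  g
}

#' @export
print.sif_spectrum <- function(x, ...) {
  cat("<sif_spectrum> unit:", sif_unit(x), "\n")
  NextMethod()
}

#' Unit tag of a spectrum
#' @param x A `sif_spectrum`.
#' @return Character scalar.
#' @export
sif_unit <- function(x) {
  u <- attr(x, "unit")
  if (is.null(u)) "radiance" else u
}

as_spectrum <- function(x, unit) {
  if (inherits(x, "sif_spectrum")) return(x)
  sif_spectrum(x$wavelength_nm, x$value, unit)
}

stopifnot_same_grid <- function(...) {
  sp <- list(...)
  w <- sp[[1]]$wavelength_nm
  for (s in sp[-1]) {
    if (length(s$wavelength_nm) != length(w) || any(abs(s$wavelength_nm - w) > 1e-9)) {
      rlang::abort("Spectra must share an identical wavelength grid.")
    }
  }
  invisible(w)
}

#' Nearest-sample lookup on a spectrum grid
#'
#' Snaps a target wavelength to the nearest grid sample, breaking ties toward
#' the shorter wavelength. The snap distance must be smaller than half the
#' local sampling interval; larger distances indicate the anchor is not
#' resolvable on this grid and raise an error.
#'
#' @param grid Numeric wavelength vector (strictly increasing).
#' @param target Target wavelength in nm.
#' @param ssi Optional sampling interval; inferred from the grid by default.
#' @return Integer index into `grid`, with attribute `snap_nm` (the distance).
#' @export
snap_index <- function(grid, target, ssi = NULL) {
  if (is.null(ssi)) ssi <- stats::median(diff(grid))
  d <- abs(grid - target)
  i <- which(d <= min(d) + 1e-9)[1] # ties resolve to the shorter wavelength
  if (d[i] > ssi / 2 + 1e-9) {
    rlang::abort(sprintf(
      "No grid sample within half a sampling interval of %.3f nm (nearest: %.3f nm).",
      target, grid[i]
    ))
  }
  structure(i, snap_nm = d[i])
}
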