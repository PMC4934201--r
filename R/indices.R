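band_mean <- function(R, lo, hi, what) {
  sel <- R$wavelength_nm >= lo & R$wavelength_nm <= hi
  if (!any(sel)) {
    rlang::abort(sprintf("Grid does not cover the %s window %.1f-%.1f nm.", what, lo, hi))
  }
  mean(R$value[sel])
}

#' Photochemical reflectance index
#'
#' `PRI = (R531 - R570) / (R531 + R570)`, with each band reflectance taken as
#' the mean over a window (default +/- 1.5 nm) around the nominal centre.
#' Tracks xanthophyll-cycle activity; bounded in \[-1, 1\].
#'
#' @param R A reflectance [sif_spectrum()].
#' @param centers Band centres in nm.
#' @param halfwidth Band half-width in nm.
#' @return One-row tibble: `name`, `value`.
#' @export
pri <- function(R, centers = c(531, 570), halfwidth = 1.5) {
  r1 <- band_mean(R, centers[1] - halfwidth, centers[1] + halfwidth, "PRI")
  r2 <- band_mean(R, centers[2] - halfwidth, centers[2] + halfwidth, "PRI")
  tibble::tibble(name = "PRI", value = (r1 - r2) / (r1 + r2))
}

#' Red-edge chlorophyll index
#'
#' `CI = R_NIR / R_rededge - 1`, with the NIR reflectance averaged over
#' 760--800 nm and the red-edge reflectance over 690--710 nm by default.
#' Increases roughly linearly with canopy chlorophyll content.
#'
#' @param R A reflectance [sif_spectrum()].
#' @param nir,rededge Two-element wavelength windows in nm.
#' @return One-row tibble: `name`, `value`.
#' @export
ci_rededge <- function(R, nir = c(760, 800), rededge = c(690, 710)) {
  r_nir <- band_mean(R, nir[1], nir[2], "NIR")
  r_re <- band_mean(R, rededge[1], rededge[2], "red-edge")
  if (r_re == 0) rlang::abort("Red-edge reflectance is zero; index undefined.")
  tibble::tibble(name = "CI_rededge", value = r_nir / r_re - 1)
}
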