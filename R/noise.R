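#' Count-scaled shot-noise model
#'
#' SNR scales with the square root of detector counts:
#' `SNR(counts) = snr_ref * sqrt(counts / counts_ref)`, anchored at the
#' reference SNR of 1000:1 at saturation.
#'
#' @param snr_ref Reference SNR.
#' @param counts_ref Counts at which `snr_ref` applies.
#' @param seed Optional integer seed; realization `i` of an ensemble draws
#'   from the deterministic substream `seed + i`, so ensembles are
#'   order-independent and reproducible.
#' @return A list of class `noise_model`.
#' @export
noise_model <- function(snr_ref = 1000, counts_ref = 65000, seed = NULL) {
  stopifnot(snr_ref > 0, counts_ref > 0)
  structure(list(snr_ref = snr_ref, counts_ref = counts_ref, seed = seed),
            class = "noise_model")
}

#' @rdname noise_model
#' @param counts Non-negative count values.
#' @param model A `noise_model`.
#' @export
snr_at <- function(counts, model = noise_model()) {
  if (any(counts < 0)) rlang::abort("Counts must be non-negative.")
  model$snr_ref * sqrt(counts / model$counts_ref)
}

# Counts implied by a radiance spectrum: divide by the calibration
# coefficient, then stretch the maximum to the target (the emulated effect of
# integration-time optimization). All-zero spectra stay at zero counts.
stretched_counts <- function(value, calibration = 1, stretch_target = 50000) {
  counts <- value / calibration
  m <- max(counts)
  if (m > 0) counts <- counts * (stretch_target / m)
  counts
}

#' Add one realization of spectrometer noise
#'
#' Perturbs each wavelength with a Gaussian of mean 0 and standard deviation
#' `L(lambda) / SNR(lambda)`, where the per-wavelength SNR follows the count
#' level after stretching the spectrum's maximum counts to `stretch_target`
#' (the working point reached by integration-time optimization). Dark noise
#' (about 4 counts on the emulated detector) is ignored. An all-zero spectrum
#' is returned unchanged.
#'
#' @param spectrum A radiance or irradiance [sif_spectrum()] (non-negative).
#' @param model A [noise_model()].
#' @param calibration Radiance per count.
#' @param stretch_target Counts assigned to the spectrum maximum.
#' @param realization Index of the realization; with a seeded model,
#'   realization `i` always reproduces the same draw.
#' @return A [sif_spectrum()] of the same unit with noise added.
#' @export
add_noise <- function(spectrum, model = noise_model(), calibration = 1,
                      stretch_target = 50000, realization = 1) {
  v <- spectrum$value
  if (any(v < 0)) rlang::abort("Noise injection requires a non-negative spectrum.")
  if (max(v) == 0) return(spectrum)
  counts <- stretched_counts(v, calibration, stretch_target)
  snr <- snr_at(counts, model)
  sd <- ifelse(snr > 0, v / snr, 0)
  if (!is.null(model$seed)) {
    old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed((model$seed + realization) %% .Machine$integer.max)
  }
  noisy <- v + stats::rnorm(length(v)) * sd
  out <- spectrum
  out$value <- noisy
  out
}

#' Noisy ensemble of a spectrum
#'
#' Generates `n` independent noisy realizations of one spectrum as a wide
#' tibble (first column the wavelengths, one column per realization).
#'
#' @inheritParams add_noise
#' @param n Number of realizations.
#' @return A tibble with columns `wavelength_nm`, `r1` ... `rn`, carrying the
#'   unit in attribute `unit`.
#' @export
noisy_ensemble <- function(spectrum, n, model = noise_model(), calibration = 1,
                           stretch_target = 50000) {
  cols <- lapply(seq_len(n), function(i) {
    add_noise(spectrum, model, calibration, stretch_target, realization = i)$value
  })
  names(cols) <- paste0("r", seq_len(n))
  out <- tibble::tibble(wavelength_nm = spectrum$wavelength_nm, !!!cols)
  attr(out, "unit") <- sif_unit(spectrum)
  out
}

ensemble_matrix <- function(ens) {
  as.matrix(ens[, -1, drop = FALSE])
}

#' Single-step integration-time optimization
#'
#' `it_opt = it_init * counts_opt / counts_init`: assuming a linear detector
#' response, one probe exposure is enough to land the peak signal at the
#' target count level, with no iteration.
#'
#' @param it_init Probe integration time in seconds (> 0).
#' @param counts_init Maximum dark-subtracted count of the probe exposure.
#' @param counts_opt Target count level (typically 80--85% of saturation).
#' @return Optimized integration time in seconds.
#' @export
optimize_integration_time <- function(it_init, counts_init, counts_opt) {
  if (it_init <= 0) rlang::abort("`it_init` must be positive.")
  if (counts_init <= 0) {
    rlang::abort("Unmeasurable target: probe exposure produced no signal.")
  }
  it_init * counts_opt / counts_init
}

#' Simulated linear detector exposure
#'
#' Counts respond linearly to radiance and integration time on top of the
#' dark-current offset, clipped at saturation:
#' `counts = min(dark + L / calibration * it, saturation)`.
#'
#' @param radiance A radiance [sif_spectrum()].
#' @param it Integration time in seconds (> 0).
#' @param spec An [instrument_spec()].
#' @return A counts [sif_spectrum()].
#' @export
detector_counts <- function(radiance, it, spec = instrument_spec()) {
  if (it <= 0) rlang::abort("`it` must be positive.")
  counts <- spec$dark_counts + radiance$value / spec$calibration * it
  counts <- pmin(counts, spec$saturation_counts)
  sif_spectrum(radiance$wavelength_nm, counts, "counts")
}

#' Simulated acquisition sequence
#'
#' Runs the measurement sequence of the observation system against the
#' simulated detector: probe exposure, single-step integration-time
#' optimization toward `counts_opt_fraction * saturation`, then the measured
#' exposure at the optimized time.
#'
#' @param radiance Target radiance [sif_spectrum()].
#' @param spec An [instrument_spec()].
#' @param it_probe Probe integration time in seconds.
#' @return A list: `it_opt`, `counts` (the optimized exposure), and
#'   `max_counts` (its dark-subtracted maximum).
#' @export
acquire_simulation <- function(radiance, spec = instrument_spec(), it_probe = 0.1) {
  probe <- detector_counts(radiance, it_probe, spec)
  while (max(probe$value) >= spec$saturation_counts && it_probe > 1e-6) {
    it_probe <- it_probe / 4 # saturated probe carries no usable maximum
    probe <- detector_counts(radiance, it_probe, spec)
  }
  counts_init <- max(probe$value) - spec$dark_counts
  target <- spec$counts_opt_fraction * spec$saturation_counts
  it_opt <- optimize_integration_time(it_probe, counts_init, target)
  meas <- detector_counts(radiance, it_opt, spec)
  list(it_opt = it_opt, counts = meas,
       max_counts = max(meas$value) - spec$dark_counts)
}
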