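---
title: "Simulating and evaluating canopy SIF retrieval"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Simulating and evaluating canopy SIF retrieval}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(canopysif)
```

## The problem

Chlorophyll in sunlit vegetation re-emits a small fraction of the light it
absorbs as fluorescence (SIF). At the top of a canopy this emission is three
orders of magnitude weaker than reflected sunlight, but inside the telluric
oxygen absorption bands — O2-A near 760.5 nm and the shallower O2-B near
687.3 nm — the reflected term is strongly suppressed while the additive
fluorescence is not, so the radiance "filling in" the band bottom can be
solved for. Ground-based observation systems measure pairs of spectra
(downwelling irradiance off a Lambertian reference panel, then upwelling
canopy radiance) with an array spectrometer and retrieve SIF at both band
bottoms, alongside reflectance-based vegetation indices.

The retrieval accuracy depends on the spectrometer (resolution, sampling,
signal-to-noise), on the retrieval algorithm and its wavelength anchors, and
on the canopy itself (chlorophyll content shapes the local reflectance slope,
leaf area index its curvature). `canopysif` packages the full evaluation
chain: a parametric forward simulator, a spectrometer emulator, the FLD,
3FLD and SFM retrieval algorithms with bundled anchor tables, the PRI and
red-edge chlorophyll indices, and a Monte-Carlo harness that quantifies the
bias and precision of each algorithm/parameter choice.

## The forward simulator

The simulator is deliberately parametric rather than physical: radiative
transfer through the atmosphere and canopy is out of scope, and only the
*local* spectral structure near the two oxygen bands matters for the
retrievals being evaluated.

* **Downwelling irradiance** is a Planck-shaped continuum (5800 K,
  normalised to a configurable maximum of 1200 mW m⁻² nm⁻¹ for an overhead
  sun) scaled by `cos(sza)` and multiplied by one Gaussian transmittance
  feature per band: `T(λ) = 1 − depth · exp(−(λ−center)²/(2 width²))`.
  Defaults: O2-A at 760.519 nm, depth 0.7, σ 1.5 nm; O2-B at 687.276 nm,
  depth 0.4, σ 1.0 nm. Real telluric bands have line-by-line structure; a
  single Gaussian reproduces only the two facts the evaluation depends on —
  the feature's depth and its width relative to the instrument response —
  with O2-A configured strictly deeper than O2-B.
* **Canopy reflectance** is a logistic red edge (inflection 708 nm, scale
  7 nm, red level falling with chlorophyll content `cab`, NIR plateau 0.55)
  mixed with a flat soil background by canopy closure `1 − exp(−0.7·lai)`,
  plus a small green peak and local terms that encode the documented
  trends: the trend-line slope near O2-A grows with `cab` (coefficient
  4e-5 nm⁻¹ per unit cab, applied in a wide window so the curve stays
  nearly straight within ±15 nm of the band), while near O2-B the slope
  falls with `cab` (−3e-5) and the curvature grows with `lai` (3e-5 nm⁻²
  per unit lai). All coefficients are `canopy_scene()` arguments, not
  constants; the signs of the O2-B terms are configuration because the
  empirical evidence for them is a single published reflectance figure.
* **Fluorescence emission** is the standard two-peak shape: Gaussians at
  687 nm (σ 10 nm) and 740 nm (σ 35 nm), with default peak radiances 1.0
  and 2.0 mW m⁻² sr⁻¹ nm⁻¹ for an overhead sun and closed canopy, scaled
  by `cos(sza)` (emission follows absorbed light) and by canopy closure so
  `lai = 0` emits nothing.
* **Upwelling radiance** is `L = E·R/π + F` for a Lambertian target.
  The reference panel is treated as ideal and of unit reflectance, so
  `E = π · L_panel`; because every retrieval formula is invariant to that
  π factor, the package carries `E` in irradiance units throughout.
* **Bare soil** (the zero-fluorescence control target) is spectrally flat
  at 0.25 by default, with an optional slope. Flatness is a deliberate
  idealisation: it makes noiseless retrievals over soil exact for *every*
  algorithm's reflectance assumption, which turns bare land into a clean
  zero-point check of the whole chain.

## The instrument emulator

The emulated spectrometer is a TE-cooled array instrument: range
475.921–862.227 nm, sampling interval 0.4 nm, resolution 0.9 nm FWHM,
saturation 65,000 counts, best-case SNR 1000:1 at saturation. The real
detector grid is slightly non-uniform but unpublished, so a uniform grid is
used as the only reproducible choice.

**Spectral response.** High-resolution spectra (0.01 nm grid) are convolved
with a Gaussian kernel tabulated at 0.01 nm over ±0.45 nm — 91 points —
whose FWHM is `sqrt(FWHM_d² − SSI_o²)` so that data already sampled at
`SSI_o` end up at resolution `FWHM_d`. Truncation at ± half the FWHM keeps
only ≈ 76.6% of the Gaussian mass, so the convolution renormalises the
weights to sum to one; this makes a constant spectrum map to exactly the
same constant and preserves the mean of slowly varying spectra to better
than 0.1%. The raw tabulation is available from `smoothing_kernel()`. The
smoothed result is linearly interpolated onto the instrument grid. Inputs
must over-cover the output grid by the kernel half-range; the package fails
loudly rather than pad or extrapolate.

**Noise.** Detector noise is shot-noise-like: `SNR(λ) = SNR_ref ·
sqrt(counts(λ)/counts_ref)`, anchored at 1000:1 for 65,000 counts. To noise
a spectrum, its values are converted to counts through a (constant,
configurable) calibration coefficient, the maximum is stretched to 50,000
counts — the working point that integration-time optimization reaches — and
each wavelength is perturbed by a zero-mean Gaussian with standard
deviation `L(λ)/SNR(λ)`. The stretch is applied per spectrum. Dark noise
(≈ 4 counts on this class of detector) is ignored. Each ensemble
realization `i` draws from the deterministic substream `seed + i`, so
ensembles are reproducible and order-independent.

**Integration time.** Because the detector response is linear in exposure
over its working range, one probe exposure suffices:
`IT_opt = IT_init · Counts_opt / Counts_init`, with `Counts_init` the
dark-subtracted maximum of the probe. The target is a configurable fraction
of saturation, default 0.80 (52,000 counts); measured systems report peak
counts near 50,000, i.e. ≈ 0.77 — the two statements differ slightly and
the fraction is therefore configuration. On the simulated detector one step
lands the peak within one count of the target, which the tests check for
100 random probe exposures.

**Adjacent averaging.** Measured spectra can be smoothed by a centred
moving mean (`adjacent_average()`, default 3 samples, edges shrink). The
phrase "averaged with three adjacent wavelengths" admits a 3- or 4-point
reading; the package implements the centred 3-point window and leaves the
width configurable rather than asserting intent.

## The retrieval algorithms

All three algorithms take the downwelling spectrum `E` and upwelling
radiance `L` on a common grid, with wavelength anchors snapped to the
nearest grid sample (ties toward the shorter wavelength; the snap distance
must be below half a sampling interval and is recorded on the index).

* **FLD** (two channels): `F = (E_out·L_in − E_in·L_out)/(E_out − E_in)`,
  with the out channel at the left shoulder. Exact when reflectance and
  fluorescence are both constant across the two channels. The bundled
  anchor tables list only left shoulders for FLD, so the package implements
  left-shoulder FLD; the underlying method admits either side.
* **3FLD** (three channels): the shoulders are interpolated to the in-band
  wavelength with weights `w_left = (λ_right − λ_in)/(λ_right − λ_left)`,
  `w_right = 1 − w_left`, applied to both `E` and `L`, then the FLD formula
  is applied. Exact when reflectance is linear across the window, the
  fluorescence constant, and the continuum equal at the two shoulders (the
  interpolated-shoulder formula carries an error term proportional to
  `E_right − E_left`; the exactness tests therefore use symmetric
  shoulders).
* **SFM**: linear least squares of `L(λ) = E(λ)·r(λ)/π + F(λ)` over every
  sample between the outermost anchors (the anchor pairs are read as
  inclusive window bounds), with `r` and `F` polynomials of configurable
  degrees in `(λ − λ_in)`. Centring on `λ_in` conditions the design
  matrix; the system is solved by QR, and an independent normal-equations
  solve is kept in the test suite as a cross-check, not as the
  implementation. The retrieved SIF is the fitted `F` constant term.
  Under-determined windows raise an error; rank-deficient designs warn.

The three formulas are the standard forms from the SIF-retrieval
literature; the source system names the algorithms and tabulates their
wavelength anchors without printing the formulas, so adopting the standard
definitions is the largest inference in the package. Negative retrievals
under noise are returned as-is, since ensemble statistics need them.

Anchor tables ship in `inst/extdata/retrieval_windows.csv`: for each band,
three candidate parameter sets per algorithm and one selected set
(`default_windows("selected")`), e.g. 3FLD at O2-A uses λ_in 760.519,
shoulders 754.040/767.342, and SFM fits degrees (1,1) at O2-A and (2,1) at
O2-B. Users may supply their own file in the same format.

## The Monte-Carlo evaluation

`experiment_config()` fixes the study conditions: chlorophyll contents
{10, 30, 50, 70} µg/cm², leaf area indices 0–4, solar zenith angles 10°–70°
in 5° steps, off-sweep drivers fixed at cab 40 / lai 4 / sza 30°, and 1000
noise realizations per cell (downwelling and upwelling ensembles are
generated independently and paired realization-by-realization). Reports
carry the injected truth — the instrument-resolution fluorescence at the
snapped in-band wavelength — beside every estimate so bias is auditable,
and rerunning any experiment with the same config reproduces it exactly.

* `run_parameter_comparison()` retrieves with every candidate and selected
  window on the reference scene, noiselessly by default so the bias
  isolates each parameter choice's systematic error.
* `sweep_cab()`, `sweep_lai()`, `sweep_sza()` produce per-cell mean/sd/bias
  tables; the lai sweep adds an SFM(1,1) variant at O2-B and the sza sweep
  runs both vegetation and bare land.
* `diurnal_simulation()` drives a day of observations from standard solar
  geometry (default: latitude 39.14°, declination −7.3°, solar noon 12.1 h,
  matching a mid-autumn day at a mid-latitude site) with
  PAR modelled as `par_max · cos(sza)`; vegetation is retrieved
  noiselessly, bare land from one noisy realization per time step,
  emulating single-shot field measurements of a zero-SIF control.

Monotonicity assertions on noisy quantities allow one inversion between
adjacent sweep points at n = 1000; the test suite runs a reduced-replicate
mode (n = 100) in which trend assertions widen to rank correlations with
end-to-end checks. The suite and the acceptance script use n = 100 and
n = 1000 respectively; both sizes are package choices balancing Monte-Carlo
error against runtime.

## What passing tests do and do not show

The generator reproduces the qualitative structure that the evaluation
logic depends on: band-bottom suppression of the reflected term; reflectance
slope/curvature trends with cab and lai; fluorescence and noise falling with
solar zenith angle; a deeper O2-A than O2-B. Passing tests therefore
demonstrate that the retrieval chain behaves correctly *given* spectra with
that structure. They do not validate the generator against real canopies:
there is no line-by-line atmospheric structure, no BRDF or canopy-structure
effects, no path radiance, no wavelength-dependent response or stray light,
and the fluorescence truth is the generator's, not a physiological
model's. One known mismatch with field experience follows from this: with
the default shape coefficients the red edge keeps noticeable curvature even
at low leaf area index, so the linear-reflectance SFM(1,1) variant never
beats SFM(2,1) at O2-B the way sparse-canopy measurements suggest it
should; the sweep reports both so users can examine the trade-off under
their own scene configurations.

## Numerical choices

* Wavelengths are nm in air, treated as point samples; grids must be
  strictly increasing within 400–1000 nm.
* Anchor snapping: nearest sample with a 1e-9 nm tie tolerance, ties to the
  shorter wavelength.
* SFM: QR factorisation on a design centred at `λ_in`; coefficients that QR
  marks as aliased are set to zero after a collinearity warning.
* Noise: an all-zero spectrum is returned unchanged (zero signal, zero
  noise); negative input radiance is refused.
* Degenerate FLD bands (`E_out == E_in`) and under-determined SFM windows
  raise errors rather than returning unstable values.
* The smoothing kernel requires `FWHM_d > SSI_o` and a tabulation step that
  divides the half-range exactly.
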