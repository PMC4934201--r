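Package: canopysif
Title: Simulation and Retrieval of Canopy Sun-Induced Chlorophyll Fluorescence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing and evaluating ground-based spectroscopic
    observation of canopy sun-induced chlorophyll fluorescence (SIF) in the
    O2-A and O2-B atmospheric absorption bands. Provides a parametric forward
    simulator of downwelling irradiance, canopy reflectance, fluorescence
    emission and upwelling radiance; an array-spectrometer emulator with
    Gaussian spectral-response smoothing, count-proportional shot noise and
    single-step integration-time optimization; the FLD, 3FLD and spectral
    fitting (SFM) retrieval algorithms with bundled wavelength parameter sets;
    the photochemical reflectance index and red-edge chlorophyll index; and a
    Monte-Carlo harness for quantifying retrieval bias and precision across
    chlorophyll content, leaf area index and solar zenith angle.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    ggplot2,
    generics
Suggests: testthat (>= 3.0.0), withr, jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
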