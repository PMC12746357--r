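Package: pcdmi
Title: Phase-Cycled Balanced SSFP Deuterium Metabolic Imaging
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Signal modeling, simulation and processing for deuterium
    metabolic imaging (DMI) with phase-cycled balanced SSFP spectral-spatial
    acquisitions at ultra-high field. Provides analytical FISP and bSSFP
    steady-state signal models with readout and duty-cycle effects for
    protocol SNR optimization, SNR-unit image reconstruction (noise
    prewhitening, zero-padded FFT, adaptive coil combination), three
    spectral-separation algorithms (standard IDEAL, IDEAL on SSFP
    configuration modes with data-driven mode combination, and a linear
    bSSFP-model fit), conditioning and number-of-signal-averages
    diagnostics, combined spectral-temporal relaxometry (T1, T2, T2*),
    acquisition-weighting and point-spread-function resolution analysis,
    absolute metabolite quantification against a water reference, and a
    digital multi-vial phantom simulator that generates multi-channel raw
    data for all protocols.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml,
    jsonlite,
    RNifti,
    minpack.lm
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
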