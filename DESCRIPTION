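Package: lowfieldsim
Title: Simulation of Low-Field MRI Acquisitions from High-Field k-Space Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Transforms proton-density-weighted multi-channel k-space data
    acquired at one main field strength (B0) into a statistically correct
    simulated acquisition at a lower B0. Signal is scaled by the B0^2
    prefactor and a steady-state relaxation-correction factor computed for
    common sequence families (spoiled gradient echo, spin echo, balanced
    SSFP, inversion recovery); thermal noise is augmented so that the
    simulated k-space noise covariance matches the B0^2 x bandwidth scaling
    law under body-noise dominance. Includes digital-phantom forward
    acquisition, channel noise-covariance estimation, Cartesian inverse-FFT
    and partial-Fourier homodyne reconstruction, sum-of-squares coil
    combination, magnitude-image SNR measurement with Rayleigh correction,
    region-growing segmentation with Dice overlap, and field-strength sweep
    utilities for minimum-field-strength decision curves.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    png,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
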