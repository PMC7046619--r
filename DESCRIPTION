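Package: cherenkovqa
Title: Cherenkov-Emission Imaging Quality Assurance for HDR Ir-192 Brachytherapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates and analyses Cherenkov-light camera images for quality
    assurance of high-dose-rate (HDR) Ir-192 brachytherapy. Provides a TG-43
    point-source dose engine for the mHDR-v2 source, closed-form Cherenkov
    physics (emission thresholds, Klein-Nishina Compton electron spectra,
    Frank-Tamm photon yield, CSDA electron ranges), a physics-based synthetic
    camera-image generator (dose-proportional emission projected through a
    100-mm water slab, catheter light, Poisson shot noise, 16-bit TIFF
    output), the image-analysis chain (background subtraction, radius-2 disc
    median filter, 1-pixel profiles, dose calibration at the 10-mm reference
    point), and the QA metrics: FWHM-midpoint source localization, dwell
    intervals, source-strength decay fitting, dose linearity, repeatability,
    dose-rate independence, and profile-versus-reference-dose agreement.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tiff,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
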