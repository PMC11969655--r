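Package: mtbarcode
Title: Photobleaching Barcodes on Gliding Microtubules
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Encode 4-bit binary numbers as superposed spatial frequencies
    photobleached into fluorescently labeled microtubules gliding across a
    kinesin-coated surface, and decode them from fluorescence time-lapse
    image stacks. Provides the encoding scheme (spatial periods, tolerance
    bins, pulse schedules), a synthetic-data generator (dye-speckled
    filament, velocity jitter, pulsed Gaussian-beam bleaching,
    diffraction-limited imaging, EMCCD readout), intensity-profile
    extraction along tracked filaments with cross-correlation alignment,
    smoothing-spline detection of the bleached region, and Fourier readout
    with a dynamic baseline, bootstrap confidence intervals and
    significance calls.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    tiff,
    MASS,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
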