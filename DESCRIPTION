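Package: venoxim
Title: Noninvasive Venous Oximetry from Cuff-Stimulated Photoplethysmography
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of dual-wavelength (660/940 nm)
    photoplethysmography for noninvasive venous oxygen saturation (SvO2)
    measurement. A ring cuff periodically compresses the venous bed of a
    finger at a frequency distinct from the heart rate, making the vein
    optically pulsatile; the pulse and stimulation components are separated
    with linear-phase FIR band-pass filters and each is converted to a
    saturation through Beer-Lambert ratio-of-ratios oximetry. The package
    provides the forward optics and its inversion, a three-compartment
    synthetic PPG generator with hypoxia-ramp protocols, spectral
    decomposition and per-cycle AC/DC extraction, the SpO2 / Mixed_SpO2 /
    SvO2 / oxygen-consumption pipeline, a software simulation of the
    stimulation feedback controller, and agreement statistics (RMSE,
    correlation, difference analysis) for method comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
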