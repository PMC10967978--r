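Package: planarmwi
Title: Planar Microwave Imaging for Abdominal Aortic Aneurysm Phantom
    Detection
Version: 0.1.0
Authors@R:
    person("Imaging", "Lab", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for monostatic ultra-wideband microwave imaging with a
    planar antenna array. Synthesizes frequency-domain reflection sweeps
    (S11) for phantom scenes under a linear echo-superposition model,
    reconstructs time-domain echoes with the inverse chirp-Z transform and
    Hilbert envelopes, forms delay-and-sum (DAS) and coherence-factor
    weighted (IDAS) images including plane-constrained variants driven by
    regenerated reference-plane pulses, and evaluates target detection and
    localization with thresholding, centroid extraction and positioning
    error tables. Reads and writes Touchstone .s1p sweep files and provides
    a command-line pipeline for simulation, calibration and imaging runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
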