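Package: fibrescope
Title: Simulation and Analysis for Holographic Multimode-Fibre Endo-Microscopy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale computational model of a laser-scanning endo-microscope
    built on holographic control of light transport through a multimode optical
    fibre. Provides a guided-mode (LP) model of step-index fibres, simulated
    transmission-matrix calibration by phase-shifting interferometry, focus
    synthesis by phase conjugation with binary off-axis (DMD-style) hologram
    encoding, angular-spectrum refocusing of the transmission matrix to
    arbitrary axial planes, raster and line-scan fluorescence imaging of
    synthetic three-dimensional scenes, stitching of records acquired along a
    moving probe into extended volumes, and red-blood-cell line-scan
    velocimetry with spectral analysis. Seeded phantom generators make every
    pipeline stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    grDevices,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown,
    withr
VignetteBuilder: knitr
Config/testthat/edition: 3
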