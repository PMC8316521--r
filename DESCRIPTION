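Package: cumulantscope
Title: Correlative Super-Resolution Optical Fluctuation and Scanning
    Ion-Conductance Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Toolkit for correlative SOFI/SICM image analysis. Computes
    2nd- to 4th-order auto- and cross-cumulant super-resolution images
    from movies of independently blinking fluorophores (2D and multiplane
    3D), estimates image resolution by decorrelation analysis, simulates
    and processes hopping-mode scanning ion-conductance topography maps,
    and co-registers fluorescence with topography via control-point
    affine transforms and cross-section Pearson correlation statistics.
    Ships a synthetic-data generator (telegraph-blinking emitters imaged
    through a Gaussian PSF, cell-like topographies scanned by a simulated
    nanopipette) so the full pipeline is testable end to end without any
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
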