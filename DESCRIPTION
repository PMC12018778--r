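Package: rhizograd
Title: Radial Rhizosphere Nutrient Transport and Micro-XRF Gradient Profiling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Simulates nutrient gradients around single plant roots with a
    radially symmetric 1D advection-diffusion-reaction model (linear sorption,
    Michaelis-Menten root uptake, a homogenized root-hair sink, irreversible
    CaSO4 precipitation and a diurnally varying water flux), computes
    threshold-based rhizosphere extents over a factorial scenario matrix
    (substrate x root segment x root-hair variant), and implements
    distance-transform radial profiling of 2D element-count maps with a
    weighted bulk + 2 SD extent rule, including a seeded generator of
    synthetic micro-XRF-like maps with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    deSolve,
    EBImage,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
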