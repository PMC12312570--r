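Package: mfstretch
Title: Mechanics of Cell Aggregates from Micropipette Force Sensor Stretching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for micropipette force sensor (MFS) stretching
    experiments on multicellular aggregates, such as the T-cell aggregates that
    form upon in vitro activation. Converts cantilever deflection traces and
    aggregate geometry into engineering stress-strain curves, fits the Young's
    modulus and ultimate tensile strength with propagated uncertainties, and
    applies the quality-control rules used in MFS practice. Includes the
    water-droplet cantilever calibration, a series-parallel spring-chain model
    linking aggregate elasticity to the effective single-cell spring constant,
    a synthetic-experiment generator (quasi-static spring-network simulator with
    bond yielding and rupture, plus a microscopy-style frame renderer), sub-pixel
    template tracking of the force-sensing pipette tip, and group-level
    statistics (Welch's t-test, box summaries, same-mouse paired ratios,
    covariate null checks).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    jsonlite,
    ggplot2,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
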