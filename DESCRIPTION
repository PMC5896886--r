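Package: tractorpull
Title: Convergence-Force and Viscoelastic Analysis of Embryonic Tissue Tensile Assays
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for analysing cantilever-probe ("tractor pull") measurements of
    convergence forces generated by amphibian marginal-zone explants, and uniaxial
    tensile stress-relaxation tests of embryonic tissue. Converts probe deflection to
    force with drift correction and hourly summaries, fits a standard-linear-solid
    (SLS) viscoelastic model to stress-relaxation traces, computes morphometric
    convergence, strain and shear rates and sagittal-sectional-area regressions,
    estimates force per cell and tensional stress, and simulates the whole experiment
    (an active motor-spring-dashpot tissue chain pulling on a calibrated probe, SLS
    relaxation traces, and marker tracks with prescribed regional strain rates) so
    that every analysis stage is testable against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
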