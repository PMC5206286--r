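Package: chromarch
Title: Multi-Phase-Field Simulation of Nuclear Chromatin Architecture
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Two-dimensional multi-phase-field model of interphase nuclear
    architecture. Chromosome-territory fields and a heterochromatin field
    evolve by gradient flow of an energy with territory-exclusion,
    volume-target, full-occupancy and envelope-affinity terms inside a
    prescribed (optionally shrinking and deforming) elliptical nucleus.
    Includes an explicit finite-difference solver with a stability guard,
    seeded angular-sector initial conditions, a preset library for the
    conventional and inverted architecture scenarios and their ablations,
    and quantitative readouts: intermingling (diffuse-interface) widths,
    heterochromatin cluster counts, envelope contact fractions, and
    architecture classification.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    graphics,
    grDevices,
    utils,
    tools,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
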