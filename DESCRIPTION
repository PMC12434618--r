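Package: menpsim
Title: Magnetoelectric Core-Shell Nanoparticle Simulation for Nano-Electroporation and Drug Release
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Finite-element simulation of a single core-shell magnetoelectric
    nanoparticle (magnetostrictive cobalt-ferrite core, piezoelectric
    barium-titanate shell) in biological surroundings. Implements an
    axisymmetric coupled magnetostatics / magnetostriction / piezoelectric
    elasticity / electrostatics solver, stationary DC field sweeps with
    magnetoelectric-coefficient curves, semi-corona electric-field statistics
    with nano-electroporation regime classification, and a Jiles-Atherton
    time-dependent study of AC-field-driven surface-potential oscillations and
    the ionic charge-displacement drug-release proxy. Includes closed-form
    verification oracles (linear magnetizable sphere, dielectric sphere,
    uniform-eigenstrain inclusion) so every pipeline stage is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
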