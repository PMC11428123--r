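Package: xtalgrow
Title: Thermodynamics and Growth Simulation of Doped Molecular Crystals
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale modelling of molecular-crystal solid solutions and
    crystal habit. Builds and dopes supercells of monoclinic purine crystals
    (guanine host, hypoxanthine/xanthine guests) by least-squares rigid
    substitution, scores the resulting solid solutions with lattice energies,
    ideal mixing entropy and a vibrational trendline against the physical
    mixture reference, enumerates symmetry-unique intermolecular interactions
    with per-interaction free energies of crystallization, and grows crystals
    on the interaction graph with a stochastic attachment/detachment engine to
    predict facet areas, axis extents and cross-sectional shape under
    different solvent and dopant regimes. Includes synthetic generators for
    every input so the full pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
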