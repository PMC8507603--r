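Package: membind
Title: Peripheral Membrane-Binding Analysis of Coarse-Grained Protein-Bilayer Ensembles
Version: 0.1.0
Authors@R:
    person("Membind", "Developers", email = "membind@example.org", role = c("aut", "cre"))
Description: Tools to quantify how peripheral membrane-binding protein domains
    (such as C2 domains) associate with lipid bilayers. Provides a rigid-body
    Brownian-dynamics toy simulator of a charged bead protein above a planar
    PC/PS/PIP2 bilayer with analytically known free energies, encounter-kinetics
    analysis (minimum-distance traces, event segmentation, exponential decay
    fits), orientation-density binding-mode analysis via the Rzz rotation-matrix
    statistic, a from-scratch WHAM solver for umbrella-sampling potentials of
    mean force with bootstrap errors, BAR/MBAR multistate free-energy estimation
    for alchemical PIP2-to-PC head-group transformations, lipid contact and
    clustering statistics, and an internal consistency check comparing total
    alchemical free energies against PMF well-depth differences.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
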