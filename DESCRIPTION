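Package: iqadecomp
Title: Interacting Quantum Atoms Energy Decomposition for QM/MM Systems
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Real-space energy decomposition of hybrid quantum
    mechanics/molecular mechanics (QM/MM) calculations using the
    interacting quantum atoms (IQA) approach over QTAIM atomic basins.
    Reads Gaussian-basis wavefunctions (AIM wfx, Molden), partitions the
    electron density into atomic basins by gradient ascent on
    atom-centred quadrature grids, and decomposes the QM energy into
    atomic net energies and diatomic electrostatic/exchange-correlation
    interaction terms.  QM-MM coupling terms (basin-integrated
    electrostatics against point charges, Lennard-Jones van der Waals),
    pairwise D3 dispersion with Becke-Johnson damping, and implicit
    Poisson-Boltzmann surface-area (PBSA) solvation terms decomposed to
    atoms are merged into the same additive bookkeeping.  Atomic terms
    regroup into interacting quantum fragments (IQF) for
    MM-PBSA-style binding scorings of host-guest and enzyme-inhibitor
    complexes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
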