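Package: fddh
Title: Hybrid Finite-Difference Poisson-Boltzmann / Debye-Huckel Protein
    Electrostatics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Structure-based continuum electrostatics for ionizable groups in
    proteins and ion channels. Reads and parameterizes united-atom PDB
    structures, assesses the maximal solvent accessibility attainable by
    sidechain rotamer repacking (self-consistent mean field), and builds a
    hybrid site model in which buried groups are treated with a
    finite-difference linearized Poisson-Boltzmann solver and
    solvent-accessible groups with a Debye-Huckel screened-Coulomb model.
    Ionization thermodynamics are computed by exact enumeration or Metropolis
    Monte Carlo over protonation microstates, yielding titration curves,
    pK-half values, net charge and pH-dependent ionization free energies.
    Analysis tools difference conformers (pKa scatter with a physiological
    sensor window, repacking-tolerance perturbation scans), classify mutations
    as pH-sensing versus pH-coupled, and locate pH50 crossovers; electrostatic
    potential maps can be exported, differenced and contoured in OpenDX format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
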