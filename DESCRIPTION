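Package: alchemforge
Title: Active-Learning Conformer Sampling, CCSD(T)*/CBS Extrapolation and
    Molecular Property Dataset Tooling
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for building quantum-chemistry training datasets by
    ensemble-disagreement-driven active learning. Provides the normalized
    ensemble disagreement measure rho and batch selection, four conformer
    sampling strategies (Langevin molecular dynamics, harmonic normal-mode
    displacement, periodic-box dimer extraction, and relaxed dihedral scans),
    a composite CCSD(T)*/CBS complete-basis-set extrapolation of
    Hartree-Fock, MP2 and DLPNO-CCSD(T) component energies, reading, writing
    and validation of conformer-property HDF5 files with a key-filtered
    loader, dataset diversity statistics (per-element energy baselines,
    atomic environment vectors, bonded-neighbor labels), and surrogate
    potential ensembles plus synthetic fixtures so the full pipeline runs
    and is testable without any electronic-structure engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    rhdf5,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
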