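Package: nmrstructkit
Title: Biomolecular NMR Spectral Analysis and Structure Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale toolkit for protein NMR structure determination
    workflows: Sparky UCSF spectrum and peak-list I/O, automated and
    restricted NOESY/HSQC peak picking with spin-system noise filtering,
    spectral-series analytics (chemical shift perturbation, titration
    traces, relaxation decay fits), NOE intensity-to-distance restraint
    calibration with the inverse sixth power law, hydrogen-bond restraint
    generation, and structure-ensemble validation (per-residue Ca RMSD,
    inter-proton contact maps, Ramachandran voxel densities, RDC
    alignment-tensor fits with Q-factors, solvent accessible surface, and
    per-residue classifiers with molecular-viewer script emission).
    Includes seed-deterministic synthetic-data generators so every tool is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    xml2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
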