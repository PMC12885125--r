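Package: ensdock
Title: Ensemble Docking Enrichment and Conformational Analysis for Protein Variants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis layer for ensemble-based drug-resistance prediction in
    mutant kinases. Provides Calpha-only structure and multi-model PDB
    trajectory input/output, mutation-specification parsing, Kabsch rigid-body
    superposition with windowed RMSD, pairwise-RMSD hierarchical clustering of
    structure sets with wild-type/mutant composition summaries, GROMOS-style
    neighbor-count clustering of molecular-dynamics trajectories, per-residue
    RMSF profiles, ensemble docking-score enrichment analysis with random
    baselines and top-fraction active recovery, multi-conformation hit
    selection, ligand-pocket residue extraction, and interaction-energy
    assembly from component single-point energies. A synthetic-data generator
    produces toy chains, trajectories with planted conformers, mutant
    variants, ligand complexes, and docking score tables with planted actives
    so every analysis is testable without external simulation output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
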