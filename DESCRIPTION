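Package: vardyn
Title: Variant-Impact Analysis of Protein Molecular Dynamics Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for characterising how deleterious missense
    variants reshape protein conformational dynamics, built around the TREM2
    immunoglobulin domain and its complementarity-determining loops.
    Aggregates per-tool deleteriousness calls into consensus vote counts and
    tool-agreement matrices; reads and writes multi-model PDB trajectories;
    computes ensemble descriptors (RMSD, radius of gyration, Shrake-Rupley
    solvent-accessible surface area, RMSF and derived B-factors); dynamic
    cross-correlation matrices; essential-dynamics PCA with trace, RMSIP
    subspace overlap and cosine-content convergence diagnostics; Kabsch-Sander
    secondary-structure assignment with per-region occupancies; inter-loop
    anchor distances and contact-occupancy maps with persistence filtering;
    and Boltzmann-inversion free-energy landscapes over the (RMSD, Rg) plane
    with representative-conformer extraction. Ships seeded synthetic-ensemble
    generators with known ground truth so every stage is testable without
    molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
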