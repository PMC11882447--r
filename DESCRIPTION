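Package: hydronet
Title: Water-Mediated Allosteric Network Analysis and Ion-Site Sampling for
    Designed Seven-Helix Receptors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying water-mediated hydrogen-bond networks at
    static-switchable transmembrane-helix interfaces of G protein-coupled
    receptors and designed variants. Reads PDB structure ensembles with
    explicit waters, detects hydrogen bonds with configurable geometric
    criteria, builds residue/water interaction graphs, clusters ensemble
    water positions into consensus solvent nodes, and counts water-mediated
    static-switchable interactions. Implements a two-stage voxel-grid
    protocol for sampling buried ion placements with a pluggable scorer,
    a solvated-bulk reference state, and Boltzmann occupancies with an
    REU-to-kcal/mol scale sweep. Converts conformational free energies to
    predicted basal activities via the allosteric two-state model, fits
    activity-energy relations, applies three design-selection criteria,
    and computes site conservation and designed-motif co-occurrence over a
    pre-filtered class-A GPCR alignment. Includes a deterministic
    synthetic-fixture generator (annotated helix bundles, planted water
    networks, planted ion sites, activity/energy tables) with
    machine-readable ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    Biostrings,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
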