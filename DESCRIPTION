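Package: consdock
Title: Consensus Docking, Pose Filtering and Trajectory Occupancy Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the bespoke computational stages of a hierarchical,
    consensus-docking virtual screen against ALDH1A3: substructure and
    Gaussian shape-overlap prescreening, geometric hydrogen-bond pose
    filtering against catalytic residues, symmetry-aware pose-RMSD matrices
    with complete-linkage consensus clustering and consensus-level selection,
    and molecular-dynamics trajectory interaction-occupancy analysis.
    Includes a synthetic-data module that emulates multi-program pose
    ensembles, receptors with planted binding pockets, and trajectories with
    planted interaction occupancies, so the full pipeline is testable without
    commercial docking engines or an MD package.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ChemmineR,
    bio3d,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
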