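Package: globulomeR
Title: Constrained Assembly and Ensemble Analysis of Amyloid-Beta Oligomer Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds symmetric amyloid-beta (Abeta42) oligomer models under
    residue-contact constraints and evaluates them with structural statistics
    used in oligomer modelling studies: Shrake-Rupley solvent accessible
    surface areas and relative SASA against extended reference tripeptides,
    amide-proton protection fractions, per-residue atomic contact (desolvation)
    energies, Monte-Carlo packing densities, interface buried surface area,
    and trajectory ensemble statistics (Kabsch RMSD, radius of gyration,
    B-factors, sidechain distance monitors, convergence diagnostics).
    Includes a synthetic-structure and trajectory generator (ideal-geometry
    peptide builder, Cn-symmetric assembly, Gaussian fluctuation model with
    progressive N-terminal helix unwinding) so the full pipeline runs without
    external data, plus exhaustive grid rigid-body docking with C3
    symmetrization and hexamer stacking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
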