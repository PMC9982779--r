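Package: mabflex
Title: Conformational Flexibility Analysis of IgG Antibody Trajectories
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Trajectory analysis for hinge-linked antibody conformational
    dynamics. Computes per-Fab latitude/longitude orientation angles in an
    Fc-anchored reference frame with Y/T-shape classification, reweights
    accelerated-MD ensembles onto a (theta1, theta2) free-energy surface via
    Maclaurin expansion of the Boltzmann boost factor with minimum-energy
    frame selection, and provides GROMOS conformational clustering, essential
    dynamics with eigenvector-filtered rotation descriptors, and structural
    descriptors (RMSD/RMSF/Rg, CH2 opening distance, glycan distances,
    heavy-atom contacts, hydrogen bonds, glycosidic dihedrals). Includes a
    deterministic synthetic toy-antibody generator so every stage is testable
    without molecular-dynamics input.
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
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
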