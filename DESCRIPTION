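Package: raydock
Title: Surface-Pocket Ray-Casting Shape Complementarity Docking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Rigid-body protein-ligand docking by ray casting. A surface
    pocket is mapped on a grid (protein/solvent/pocket labelling in the
    LIGSITE tradition), reduced to a set of rays cast from an origin inside
    the protein, and candidate ligand poses are scored by how closely the
    first ray-ligand intersection distances match the stored ray-pocket
    distances. Pose optimization uses particle swarm optimization with a
    two-stage batch scorer (per-ray contributions, then per-particle
    reduction) and a conservative angular-bounds ray-elimination shortcut.
    Includes analytic synthetic fixtures (planted complementary ligands, toy
    receptors, decoy libraries) and an independent brute-force scoring
    oracle, plus a command-line interface for rayfile generation, scoring,
    docking and library screening.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ChemmineR,
    jsonlite
Config/testthat/edition: 3
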