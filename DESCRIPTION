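Package: rotdock
Title: Rigid-Body Protein-Protein Docking by Uniform Rotational Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Generates rigid-body protein-protein docking poses by uniformly
    sampling the rotational space of both molecules, using approximately
    uniform point distributions on the sphere (energy-minimized for small
    counts, generalized-spiral for large ones) and a square-root twist rule.
    For each orientation the optimal center-to-center separation is obtained
    from grid-projected distance-to-surface matrices of the two molecules,
    and poses are filtered with a fast residue-based desolvation score built
    from precomputed per-residue solvation contributions. Includes an
    evaluation layer (Kabsch superposition, ligand RMSD, near-native success
    rates, ranked-set merging), restraint-restricted direction sampling,
    synthetic rigid-body fixtures in PDB format, and a command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
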