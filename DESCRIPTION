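Package: abensemble
Title: Structural Analysis of Amyloid Beta Monomer and Dimer Conformational Ensembles
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for conformational ensembles of amyloid
    beta-protein (Abeta40/Abeta42) monomers and dimers sampled by molecular
    dynamics. Provides interpeptide contact numbers and contact maps,
    center-of-mass geometry including the N-terminal effective-radius
    coordinate, salt-bridge detection and propensity tables with
    trajectory-level standard errors, per-residue solvent accessible surface
    area (Shrake-Rupley), two-dimensional potential-of-mean-force landscapes
    with GROMOS-style RMSD clustering for representative conformations,
    per-residue water radial distribution functions, convergence diagnostics,
    a coarse-grained four-bead to united-atom reconstruction procedure, and a
    seeded synthetic-ensemble generator for testing every stage without
    trajectory data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    stats,
    utils,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
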