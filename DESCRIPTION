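Package: pdirac
Title: Persistent Dirac Operators for Molecular Structure Representation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds filtered simplicial complexes (Vietoris-Rips, Alpha,
    complete) from 3D atomic point clouds, assembles discrete and weighted
    Dirac matrices together with their Hodge Laplacian blocks, tracks their
    eigenspectra along the filtration, and condenses each snapshot spectrum
    into twelve persistent spectral attributes (Fiedler value, graph
    energies, Dirac zeta values, Euler-Poincare number, spanning-tree
    number, persistent multiplicity). The stacked attribute series form
    fixed-length topological fingerprints of molecules for downstream
    machine learning. Persistent boundary operators and persistent Hodge
    Laplacians for nested pairs of complexes are provided, along with
    simplex-weighted metric inner products, homology and non-homology
    generator extraction, molecule readers (XYZ, PDB, SDF), atom subsetting
    and physicochemical weighting schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils
Suggests:
    bio3d,
    ChemmineR,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
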