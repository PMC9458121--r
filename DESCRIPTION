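Package: amberDecomp
Title: Fragment Partitioning of AMBER Molecular Mechanics Energies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-point AMBER molecular mechanics energies (harmonic bonds
    and angles, cosine-series torsions, out-of-plane terms, Lennard-Jones and
    Coulomb with 1-4 scaling and 1-2/1-3 exclusions, no cutoff) partitioned
    into user-defined fragments plus pairwise, triple and quadruple
    inter-fragment interaction terms whose arithmetic sum exactly
    reconstructs the total energy. Reads AMBER PRMTOP/PARM7 topologies with
    inpcrd or PDB coordinates, converts parameters to and from the
    Gaussian-style MM record format, and ships a synthetic-system generator
    with an independent brute-force energy oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    parallel,
    stats,
    utils,
    jsonlite,
    bio3d,
    igraph,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'constants.R'
    'amberDecomp-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'gaussian-params.R'
    'prmtop.R'
    'coordinates.R'
    'topology.R'
    'energy.R'
    'partition.R'
    'fragspec.R'
    'report.R'
    'fixtures.R'
    'oracle.R'
    'cli.R'
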