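Package: latticeFold
Title: General Protein Lattice Models on Square and Triangular Lattices of
    Arbitrary Dimension
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A lattice-agnostic toolkit for simplified (HP-style) protein
    lattice models. Square and triangular (FCC-generalising) lattices are
    built parametrically in any dimension from their basis matrices and main
    directions; protein conformations are handled as self-avoiding walks in
    integer lattice coordinates, with differential encodings, rigid motions
    and n-dimensional plane rotations. Contact potentials (the classic HP
    potential and a generalised pairwise model) are evaluated
    lattice-agnostically, a generalised Monte Carlo move set (end, kink-jump,
    crankshaft, slithering-snake, pivot and pull moves) is provided with
    usage statistics, and two reference optimizers (chain growth and
    simulated annealing behind a strategy-pattern foldit() hook) search for
    minimum-potential conformations of benchmark HP sequences.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), igraph, optparse, bio3d
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'utils.R'
    'lattice.R'
    'conformation.R'
    'potential.R'
    'moves.R'
    'optimizers.R'
    'io.R'
    'latticeFold-package.R'
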