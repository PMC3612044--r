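# latticeFold

Simplified protein lattice models — the HP model and its relatives — treat
a protein as a self-avoiding walk on a regular lattice: hydrophobic (H)
and polar (P) residues sit on vertices, consecutive residues on adjacent
vertices, and the energy of a conformation is minus the number of H–H
contacts (non-bonded residue pairs on adjacent vertices),

```
ε = Σ_{j ≥ i+2}  g(d(p_i, p_j)) · C(s_i, s_j),      HP: g(1) = 1, C(H,H) = −1.
```

Classic implementations hard-wire one lattice (the planar square or the
cubic lattice).  **latticeFold** makes the lattice a parameter: square and
triangular lattices of any dimension are built from their basis matrix and
*main directions* (the integer vectors joining a vertex to its
neighbours), and everything downstream — adjacency and hop distances,
conformation handling and rigid rotations, contact potentials, a
generalised Monte Carlo move set (end, kink-jump, crankshaft,
slithering-snake, pivot, pull) and two reference optimizers (chain growth
and simulated annealing behind a pluggable `foldit()` hook) — is written
lattice-agnostically.  Coordination numbers come out as `2n` (square) and
`n(n+1)` (triangular): 4, 6, 6 and 12 for the four familiar lattices, with
the 3-D triangular lattice being FCC.  The package is aimed at people
studying conformation spaces, move-set statistics and folding heuristics
across lattice families and dimensions, where the neighbourhood of real
protein cores (roughly 3–20 Cα neighbours within interaction range)
bounds the sensible coordination numbers.

## A worked example

Fold the 48-residue benchmark sequence HI 4 on the planar triangular
lattice with the chain-growth optimizer:

```r
library(latticeFold)

lat <- Lattice("triangular", 2)
lat
#> triangular lattice in dimension 2 (coordination number 6)
#> basis matrix (columns = primitive vectors):
#>      [,1]  [,2]
#> [1,]    1 0.500
#> [2,]    0 0.866

seqHI4 <- benchmarkSequence("HI 4")      # validated 48-mer, 24 H
m <- LatticeProtein(seqHI4, lat, build = "linear")
optimizer(m) <- CgOptimizer(runs = 50, seed = 1)
res <- foldit(m)
res
#> chain_growth result: best potential -31 over 50 runs

bestPotential(res)
#> [1] -31
countContacts(bestModel(res), "H", "H")
#> [1] 31
```

The best conformation found buries 31 H–H contacts (HP potential −31,
the value of the published reference conformation on this lattice).
`writeConformation()` serialises it as JSON;
`simulatedAnnealing()` runs the Monte Carlo optimizer instead and
additionally reports per-move-type usage statistics (hit rate `h`,
improvement fraction `sigma`) via `moveStats()`.

A thin command-line front end over the same functions lives in
`inst/scripts/latticefold.R`:

```sh
Rscript inst/scripts/latticefold.R fold --bench "HI 4" \
    --lattice triangular --dim 2 --optimizer cg --runs 50 --seed 1 \
    --out hi4.json
Rscript inst/scripts/latticefold.R energy --conf hi4.json
Rscript inst/scripts/latticefold.R lattice-info --lattice triangular --dim 3
```

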