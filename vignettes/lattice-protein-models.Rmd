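---
title: "Lattice-agnostic HP protein models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lattice-agnostic HP protein models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(latticeFold)
```

## The model

Simplified lattice models represent a protein as a self-avoiding walk on a
regular lattice: residue $i$ occupies a vertex, consecutive residues occupy
adjacent vertices, and no vertex is used twice.  In the HP abstraction the
residue alphabet is reduced to hydrophobic (H) and polar (P), and the
energy of a conformation is

$$\epsilon \;=\; \sum_{j \ge i+2} g\!\big(d(p_i, p_j)\big)\, C(s_i, s_j),$$

a sum over residue pairs not adjacent along the backbone.  The classic HP
potential is the contact special case: $g(1) = 1$ and zero otherwise,
$C(H,H) = -1$ and every other coefficient zero, i.e. minus the number of
H–H contacts.  `hpPotential()` evaluates it; `genericPotential()` accepts
arbitrary symmetric coefficient tables (a 20-letter table can be supplied
as a CSV matrix through `PotentialModel()`) and longer-range distance
factors.

What makes this package different from fixed 2-D/3-D implementations is
that the lattice is a *parameter*.  A `Lattice` is specified by a kind and
a dimension $n$:

* **square**: the standard basis; main directions $\pm e_i$; coordination
  number $c = 2n$.
* **triangular**: unit basis vectors at pairwise $60^\circ$ (Gram matrix
  with unit diagonal and $1/2$ off-diagonal), built iteratively by
  embedding the $(n-1)$-dimensional basis and appending the unique unit
  column with inner product $1/2$ against every previous one and positive
  last component.  Main directions $\pm e_i$ and $\pm(e_i - e_j)$;
  $c = n(n+1)$.  For $n = 3$ this is the FCC lattice.

Every geometric operation downstream — adjacency, distance, moves,
potentials, optimizers — is written against the basis matrix and the
lexicographically sorted main-direction list, never against a particular
lattice, which is how the same optimizer code runs unchanged on a planar
square lattice and a 5-D triangular one.

The surface rationale for the triangular family comes from the packing of
real protein cores: counting C$\alpha$ neighbours within the 5–8 Å
interaction range (see `radialNeighborProfile()` and
`meanRadialNeighborProfile()`, which implement exactly that count for a
coordinate cloud) bounds plausible coordination numbers roughly between
3–4 and 19–20.  Square lattices stay inside this *admissible range* up to
$n = 10$, triangular ones up to $n = 4$ ($c = 20$).

```{r}
vapply(2:6, function(n) coordinationNumber(Lattice("triangular", n)),
       integer(1))
```

## Distances

Hop distance (minimum number of lattice edges) on square lattices is the
Manhattan distance.  For the triangular family the package uses a closed
form valid in every dimension:

$$d_{hop}(\Delta) \;=\; \max\Big(\sum_i \max(\Delta_i, 0),\;
  \sum_i \max(-\Delta_i, 0)\Big).$$

Every step $\pm e_i$ changes one of the two partial sums by one, and a
step $\pm(e_i - e_j)$ can reduce both at once; pairing positive against
negative needs and finishing with single steps attains the bound, so the
formula is exact.  In two dimensions it coincides with the familiar "sum
of the two smallest of $|\Delta_1|, |\Delta_2|, |\Delta_1 + \Delta_2|$"
rule.  The test suite validates both forms against an independent
graph-search oracle on every vertex of the $[-4, 4]^n$ box (square
$n \le 5$, triangular $n \le 4$), so no cutoff-plus-approximation scheme
is needed.

## Conformations and rigid motions

`LatticeProtein` stores the absolute encoding (integer coordinates, one
residue per row, 1-based indexing, builders anchored at the origin); the
differential encoding (step list) is derived on demand and inverted by
`fromDifferential()`, which deliberately does *not* validate
self-avoidance so that illegal candidates can be represented and then
rejected by `isSelfAvoiding()` (hash-table occupancy, linear time).  The
relative encoding used by some 2-D/3-D codes does not generalise cleanly
across dimensions and is intentionally out of scope.

Rotations follow the linear hypothesis: an $n$-dimensional rigid rotation
acts in the plane spanned by a source and a destination main direction and
fixes the orthogonal $(n-2)$-dimensional subspace.  `planeRotation()`
constructs the Cartesian rotation and conjugates it into lattice
coordinates.  Two numerical choices matter:

* when source and destination are opposite, the half-turn plane is chosen
  deterministically as the plane of the source and the lowest-index main
  direction not parallel to it;
* rotated branch coordinates are accepted as lattice vertices when within
  $10^{-6}$ of integers (then rounded) — far below half the lattice
  spacing, and only there to absorb floating-point noise from the
  conjugation $B^{-1} R B$.  On triangular lattices a rotation can
  legitimately map vertices off the lattice; such images are flagged and
  the pivot move rejects them.

## The move set

Six generalised move types operate through adjacency and occupancy alone:
single-residue `endMove()`, `kinkJump()` (corner) and the two-residue
`crankshaftMove()` (the local VSHD set); and the global
`slitheringSnake()` (reptation), `pivotMove()` (branch rotation) and the
semi-local `pullMove()`.  Conventions adopted where the classic
definitions leave room:

* a destination equal to the current position counts as infeasible — a
  move must produce a *different* admissible conformation;
* the crankshaft pair may reuse one of the two old vertices in swapped
  roles; only the exact current pair is excluded;
* pull moves displace the target by the topology constant
  $\nu$ = `pullDisplacement()` (2 on square lattices, 1 on triangular
  ones, derived by enumerating direction pairs); on square lattices the
  route goes through a free intermediate vertex which receives the first
  pulled residue, and each further pulled residue drops into the position
  vacated two steps earlier in the pulled order, stopping at the first
  residue already adjacent to its predecessor's new position;
* `randomMove()` samples the move type from a try-rate distribution and
  all free parameters uniformly among legal values, with no heuristics;
  pivot branch sides are chosen with probability 1/2 each;
* pulls that stop early (the semi-local case, by far the most common) are
  reversible by another pull; a pull that propagates through the whole
  branch is not, because undoing it would need the relaxed end-move
  variant of the pull family, which — like detailed-balance weighting —
  is out of scope here.

Only the slithering-snake try rate (5%) is a canonical value; the rest of
`defaultTryRates()` (pull 50%, kink-jump 15%, end/crankshaft/pivot 10%
each) are package defaults, configurable and reported with results.  The
pull move dominates by design — it is the accepted workhorse for compact
conformations — and the recorded `MoveStats` (hit rate $h$, improvement
fraction $\sigma$) let a user reproduce that characterisation.

## Optimizers

Both optimizers plug into the strategy hook: attach a configuration with
`optimizer(model) <- CgOptimizer(...)` or `SaOptimizer(...)` and call
`foldit(model)`; the model is never mutated.

**Chain growth** (`chainGrowth()`): exhaustive look-ahead of the next $k$
residues ($c^k$ direction words, enumerated against the occupancy map),
scored by the HP potential of the aggregate; the first $l$ steps of a
minimum-potential chunk are committed.  Among minimum-potential chunks
those closest on average (Cartesian distance) to the centroid of the
placed aggregate are preferred; the surviving ties are broken by a
uniform seeded draw.  That final random draw is what differentiates
independent runs — a fully deterministic tie-break would make every run
identical and defeat the restart mechanism.  Dead ends abort the run
(no backtracking); the result is the best over `runs` runs.  Defaults
$k = l = 3$.

**Simulated annealing** (`simulatedAnnealing()`): Metropolis acceptance
($\Delta E \le 0$ always, otherwise probability
$e^{-\Delta E / k_B T}$, $k_B = 1$), exponential cooling
$T \leftarrow \alpha T$, sessions repeated from the best conformation
while fruitful.  The numeric defaults are $T_0 = 2.0$, $T_f = 0.15$,
$\alpha = 0.97$, `stepsPerT` $= 20N$ — calibrated so that a 48-residue
2-D square run finishes in about two sessions; all configurable and none
canonical.  During the first half of the temperature steps of the first
session (the half is counted on the cooling-step index, which is well
defined for an exponential schedule) the acceptance objective is the
compaction potential: $C(H,H) = -1$ as in the HP model plus a uniform
weak attraction of $-0.25$ for every other contact pair, which drives the
chain towards a globular shape faster; the best conformation is always
tracked under the pure HP potential.  Partial-aggregate scoring inside
chain growth, by contrast, always uses the pure HP potential.

A practical numerical note: reptation lets the whole chain drift, so the
annealer re-anchors the conformation at the origin whenever coordinates
leave a fixed window.  All potentials are translation-invariant, so this
is observationally a no-op; it keeps the hashed occupancy keys in their
fast packed range.

## Benchmarks

`loadBenchmarks()` ships the classic benchmark catalogue: the ten
48-residue Harvard instances (24 H each), the 24-residue first half of
instance 9, and four longer chains (90–200 residues).  The published
(length, H-count) pair of each entry is treated as ground truth: the
loader expands the run-length notation and refuses any entry that does
not reproduce its pair.  The run-length strings of HI 1–7 were
transcribed from the canonical benchmark notation and verify exactly; for
HI 8–10 and the four long entries a fully verified transcription was not
available, so those rows are catalogued (visible with
`validate = FALSE`) but refused by the validating loader rather than
returned corrupted.  The HI 9/2 entry is determined by its pair up to the
placement of a single P residue, fixed here as a trailing P$_2$ run; the
hydrophobic layout is identical under either placement.

## Problem sizes and verification scope

The acceptance computations reproduce the potentials of the reference
conformations: HI 4 must reach $-16$ (square 2-D), $-31$ (triangular
2-D), $-27$ (cubic), $-60$ (FCC), and HI 9/2 must reach $-31$ on the 5-D
triangular lattice.  The search recipe is chain growth with $k = l = 3$
(100–300 restarts on the cheap lattices, 15 on the 5-D one, where a
single run enumerates $30^3$ chunk words per extension) plus one
annealing invocation per lattice, with `stepsPerT` halved on FCC and
quartered in 5-D and more chain-growth restarts in exchange.  On the
square lattices chain growth saturates around $-13$ / $-23$ (the parity
constraint and the short look-ahead punish long all-P stretches there)
and the annealing supplement is what crosses the reference values; on
triangular lattices chain growth alone reaches them.  The whole batch
runs in a few minutes on one CPU.

Property-style suites run at reduced but representative sizes: $10^4$
randomized move applications across six lattices, 200 random models for
the dual-route potential check, walks up to length 50 for the
self-avoidance oracle, and exhaustive move-feasibility enumeration on all
5-vertex square walks.  What passing these tests shows is internal
consistency of the geometry, moves and optimizers under the stated
conventions — synthetic self-avoiding walks are not real proteins, and
the HP potential is a deliberately minimal abstraction: no claim about
side chains, solvent, or real folding kinetics follows.

## Known limitations

* Honeycomb/hexagonal lattices are excluded by construction (not a
  Bravais lattice; its step set is vertex-dependent).  The planar
  honeycomb case can be emulated on the triangular lattice by
  constraining successive bond angles, which is left to the user.
* Chain growth's occupancy packing supports chains up to length ~200 on
  lattices up to dimension 8 (beyond that the packed keys would lose
  exactness and the implementation refuses).
* The optimizers are reference implementations for exploring the model
  family, not state-of-the-art folders; no optimality guarantees are
  made or implied.
* Chain-breaking moves and detailed-balance-weighted pull moves are out
  of scope.

## A worked session

```{r, eval = FALSE}
lat <- Lattice("triangular", 2)
seqHI4 <- benchmarkSequence("HI 4")
m <- LatticeProtein(seqHI4, lat, build = "linear")
optimizer(m) <- CgOptimizer(runs = 50, seed = 1)
res <- foldit(m)
bestPotential(res)
writeConformation(bestModel(res), "hi4-tri2.json")
```
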