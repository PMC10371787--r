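---
title: "Reverse engineering origami designs: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reverse engineering origami designs: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revnano)
```

# The problem

A scaffolded origami is a single long scaffold strand pinned into shape by
short staples, each of which hybridises several disjoint scaffold regions
and thereby creates crossovers between helices.  Published designs usually
consist of the scaffold sequence plus a 5′→3′ staple list and nothing else.
`revnano` recovers the design's *contact map* — per scaffold base, the
staple base hybridised to it or "unpaired" — and from it a geometric guide
schematic.

Recovering the contact map is a constraint-satisfaction problem: the
decision variables are staples, the candidate values are their possible
Watson–Crick routes across the scaffold, and a solution assigns one route
per staple with no staple–staple overlap.  The solver does not attempt
generic CSP search with backtracking; it exploits two physical properties of
origami: staples cover the scaffold densely (so footprints of committed
staples prune the alternatives of others), and the folded object is a highly
connected mesh (so graph distances between a staple's end anchors separate
plausible from implausible routes).

This document records the modelling assumptions, the tunable parameters, the
behaviour of the synthetic-design generator, and the decisions taken where
the design space was genuinely open.  Every empirical statement here is
asserted by the test suite (`tests/testthat/`) or recomputed by
`scripts/acceptance.R`; no other numbers are claimed.

# Sequence model and conventions

* Scaffold bases are indexed 0-based from the 5′ end; a section `(start: μ)`
  occupies bases `start, start-1, …, start-μ+1` — staple and scaffold are
  antiparallel, so a staple read 5′→3′ walks the scaffold toward its 5′ end.
  Circular scaffolds index modulo `N`; linear scaffolds never wrap.
* Staples are DNA.  A DNA scaffold pairs A↔T, C↔G; an RNA scaffold (hybrid
  origami) pairs scaffold U with staple A and scaffold A with staple T.
* Non-hybridising staple subsequences (end dangles, interior loop-outs,
  often polyT) cannot be detected from sequence alone and must be pre-marked;
  the markup dialect is lowercase letters.  Before solving, each staple is
  split into *virtual staples*, one per hybridising segment; they are routed
  independently and reassembled afterwards, with the connecting edges typed
  `staple_loopout`/`staple_dangle` in the domain graph.  A parent with some
  but not all segments routed is counted unplaced in SP% but keeps its placed
  segments in the map, flagged in the run report — the alternative (dropping
  placed segments) would discard verified pairings for no gain.

# Solver stages and parameters

**Stage 0 — routing trees.**  Matches are *maximal runs only*: an alignment
is extended greedily until mismatch or staple end, and no sub-maximal split
points are generated.  This is deliberate: sequence matching cannot know
where a designed junction sits, so when complementarity happens to continue
past a crossover the match "overshoots" (a 16–16 staple may only be
representable as 17–15).  `μ_min` (default 6, wireframe preset 5) is the
shortest admissible section; `σ` (default 4, wireframe 2) keeps, within each
sibling set of the tree, only matches within σ bases of the best sibling.
Sections of one route may not claim a shared scaffold base (physically
impossible), but may abut.  A per-staple node cap (10^6) aborts
pathologically repetitive staples with an empty tree rather than hanging.
Only complete tilings are kept as routes; partial routes are discarded.

**Stage 1 — propagation.**  Staples are polled in input order (deterministic
mode) or in a freshly seeded shuffle per sweep (non-deterministic mode, for
probing solution stability).  Claims update immediately within a sweep
(Gauss–Seidel style), which propagates cascades faster than batching updates
to sweep end and matches how constraint propagation is usually implemented;
both modes are reproducible, the second given its seed.  A route dies when
any of its sections is ≥ β-claimed **by other staples** (a staple never
blocks itself); the β test is applied per section, not pooled over the
route, so local conflicts cannot hide inside long routes.  Footprints only
ever grow (asserted as an invariant in the tests).

**Stage 2 — clearest shortest path.**  The scaffold base graph `B` contains
one vertex per scaffold base, backbone edges, and one edge per placed-staple
crossover.  Route value is the shortest-path *edge count* between the bases
paired to staple 5′ and 3′; the candidate staple's own crossovers are never
in `B` (it is built from placed staples only).  The margin is the difference
between the best and second-best route value over all surviving routes,
regardless of whether they share endpoints — excluding same-endpoint routes
would discard genuine ambiguity evidence.  An infinite margin (only one
route reachable) is the clearest possible signal and wins; a staple whose
best route is unreachable is unselectable, and ties are broken toward the
highest staple id.  The Stage-1 propagation re-runs after every forced
placement and `B` is rebuilt only after that ripple quiesces.  The 65 %
Stage-2 entry threshold is fixed: below it `B` is too sparse for distances
to mean anything, and the solver refuses (`E2`) rather than guessing.

**Stage 3 — overlap repair.**  β-tolerant placement can leave two sections
sharing bases.  Because greedy matching extends sections only in the staple
5′→3′ direction, an overshoot always extends a section's staple-3′ terminus;
the repair therefore trims the section whose staple-3′ terminus lies inside
the overlap.  A head-on tie yields the higher staple id.  Three staples on
one base, an overlap with no terminus-only resolution, or a trim that would
erase a section raise `E4`: such a map is structurally wrong and repair
would only disguise it.

**NAIVE baseline.**  Commit the longest match of the remaining staple prefix
(ties to the lowest scaffold start), truncate, repeat; staples are solved in
isolation.  It exists to demonstrate *why* the constraint machinery is
needed: one duplicated binding site suffices to lure it (see the decoy
fixtures), while the full solver recovers the design exactly.

# The domain-level graph and layout

The contact map converts losslessly to a typed graph `D`: maximal
same-section runs become `ds_scaffold` edges, unpaired runs `ss_scaffold`
edges, a linear scaffold contributes a `scaffold_nick`, and staples
contribute `staple_crossover` / `staple_loopout` / `staple_dangle` edges.
Nodes sit at domain boundaries (identified by the scaffold base starting the
following domain).  `to_domain_graph()` / `from_domain_graph()` are mutual
inverses — tested as a property on every fixture class, including markup-
bearing designs pushed through the whole solver.

Scaffold-domain and dangle edges weigh their base count, crossover and nick
edges weigh 1, so helices render with proportional lengths.  The embedding
minimises Kamada–Kawai stress against all-pairs weighted graph distances,
starting from nodes on a circle (in 3D with seeded jitter out of plane,
since a perfectly planar start is a saddle point); the final stress is
checked against the circular start's on every fixture.  An optional
force-refinement pass (spring attraction toward edge target lengths, weak
all-pairs repulsion, per-iteration displacement capping against oscillation)
separates coincident nodes; it is bounded in the tests to at most 1.5× the
embed stress.  The layouts inherit the well-known "chicken-wire" inflation
of rectilinear cells — Euclidean distances chase Manhattan-like graph
distances — which is accepted, not corrected.  The exported HTML is fully
self-contained (inline JSON + vanilla SVG/JS): pan, zoom, node dragging,
tooltips with staple ids, section sequences and scaffold ranges, in three
views (per-staple colouring; scaffold routing only; junction ambiguity with
immovable junctions green and moveable ones red).

# Junction ambiguity

A junction is a scaffold boundary whose two flanking bases belong to
different staple sections.  It can migrate one base if the staple on one
side can take over the pairing of the first base on the other side while
staying complementary — which reduces to a single letter comparison: the
junction is immovable exactly when the scaffold letter following the
crossover differs from the scaffold letter on the other side of the
crossover.  Slack counts how many bases it can slide each way, capped at the
shorter flanking section length minus one.  Staple letters are tested
regardless of hybridising/non-hybridising markup: a complementary dangle
base is precisely what makes a junction physically ambiguous.  Multi-arm
meeting points are evaluated one pairwise boundary at a time.  When every
junction is immovable and every staple placed, the topology is encoded in
the sequences with zero loss, reported as `i2_zero`.  The incremental
computation is verified against a brute-force re-pairing oracle on over a
thousand random junctions.

# The synthetic-design generator

`forward_design()` lays a serpentine scaffold over a `rows × cols` grid and
tiles it with staples of `n_sections` equal sections, crossing between
adjacent rows at alternating block edges; staple sequences are derived as
Watson–Crick partners of their scaffold bases, so the emitted ground truth
is exact by construction.  Scaffolds are seeded-random, De Bruijn
(repeat-deficient; a seed-derived rotation of the cycle gives distinct
scaffolds with identical uniqueness guarantees), or user-supplied.  Defaults
target desk-scale runs: grids of 2–8 rows and a few dozen columns, scaffolds
well under 2 knt, so the full pipeline runs in seconds.

By default the generator emulates a *well-designed* origami
(`junction_distinct = TRUE`): scaffold letters are post-edited so that (a)
every junction is sequence-immovable and (b) greedy matching stops exactly
at every designed section boundary — including boundaries onto unpaired
scaffold, such as a single-stranded tail.  Without this rule, roughly one
junction in four on a random or De Bruijn scaffold permits a one-base
overshoot, producing skewed-junction defects and a nonzero hamming distance
even though the solver behaves correctly; perfect-recovery claims are
therefore statements about overshoot-free designs, and
`junction_distinct = FALSE` is available to study the defect regime.
`implant_decoy()` copies a staple's 5′ prefix into the unpaired tail to
build the decoy-repeat fixtures; `has_unique_kmers()` asserts their
"only repeat is the decoy" premise.  `add_noise()` models imperfect
transcription of published lists: per-base substitutions and surplus random
contaminant staples, appended at the end or shuffled in.

What the generator does **not** emulate: wireframe multi-arm junction
routing, M13-specific repeat structure, base insertions/deletions for twist
correction, and scaffolds beyond a few knt.  Passing tests therefore
demonstrate correctness of the machinery on raster-like, modestly sized
designs; behaviour on large repeat-rich scaffolds is exercised only
qualitatively (decoy fixtures, tree-size guard, E2/E4 paths).

# Numerical and degenerate-input choices

* All tie-breaks are deterministic: sibling and route generation order by
  scaffold start; Stage-2 staple ties toward the highest id; NAIVE match
  ties toward the lowest start.
* An empty staple list yields an empty map with SP% reported as 100 by
  convention (and logged); an empty scaffold is an error.
* Disconnected domain graphs are embedded per component and tiled side by
  side; a zero-node graph is rejected.
* The E2 threshold (0.65, strict `<`), the β test (`≥`, i.e. exactly β is
  unavailable) and the Stage-2 margin definition are boundary-tested
  explicitly.

# Known limitations

* Misplaced staples that survive Stage 2 are hard to detect without ground
  truth; the two-direction consistency filter sketched as future work for
  such solvers is not implemented.
* Non-hybridising staple regions must be pre-marked; no automatic detection.
* The guide schematic is a connectivity rendering, not a mechanical model:
  no twist, no finite-element relaxation, no export to coarse-grain
  simulation formats.
* Performance targets desk-scale inputs; the SRT stage is the dominant cost
  and grows with scaffold length and repeat content.
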