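---
title: "Methods: cell-centered simulation on a dynamic Delaunay/Voronoi grid"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-centered simulation on a dynamic Delaunay/Voronoi grid}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vcellsim)
```

## The model

`vcellsim` is an off-lattice, cell-centered agent-based simulation framework.
Each agent owns a single generator point in 2D or 3D continuous space; the
agent's spatial extent is the Voronoi cell (*V-cell*) of that generator —
the region of space closer to it than to any other generator. The dual of
the Voronoi tessellation is the Delaunay triangulation of the generator
points, and the framework works entirely on that dual:

* a V-cell's boundary vertices are the circumball centers of the Delaunay
  simplices incident to its generator;
* an agent's *neighborhood* — its entire observable environment — is the set
  of generators one Delaunay edge away (1-hop);
* whenever any generator moves, appears or disappears, the triangulation is
  recalculated, so cell shapes and neighborhoods respond automatically.

This representation suits tissue-scale questions (cyst morphogenesis, wound
closure, collective behavior of epithelial layers) where the spatial
arrangement should *emerge* from individual cell decisions rather than be
imposed by a fixed grid: agents have no prescribed neighborhood shape, cells
have varying numbers of neighbors, and the grid granularity follows the
point density.

Four agent types are built in. `lmn` maps to a cyst lumen, `lec` to luminal
epithelial cells, `mec` to myoepithelial cells; `media` agents are inert
boundary generators whose only role is to enclose the biological agents so
that every biological V-cell is bounded (a hull generator's Voronoi cell is
unbounded, and none of the size-dependent rules would be defined for it).
The *media enclosure* invariant — no alive non-media agent on the convex
hull — is validated after construction and after every engine action, and
its violation is a loud, classed error rather than a silent degradation.

## The triangulation kernel

The Delaunay triangulation is built by incremental Bowyer–Watson insertion,
one code path parameterized by dimension: insert a point, *carve* every
simplex whose open circumball contains it, and re-fan the cavity boundary to
the new point. Points are inserted in ascending id order, so the output is a
deterministic function of the input map.

Two design choices deserve explanation.

**Hull handling via an infinite vertex.** Instead of bootstrapping with a
large finite super-simplex (the textbook construction), the kernel keeps one
symbolic vertex "at infinity": every hull facet carries an *infinite
simplex*, and the conflict test against an infinite simplex is an
orientation test on its hull facet (is the new point strictly outside?),
referenced against the finite simplex on the inner side. A finite
super-simplex — at 10x the data diameter or any other fixed multiple — is
wrong whenever a near-collinear hull triple's circumball reaches the super
vertices, which does happen on random clouds at the package's own test
sizes; the symbolic formulation is exact for every hull configuration and
costs nothing.

**Tolerances and ties.** All predicates (orientation, in-circumball) are
evaluated in extended precision (`long double`) as determinants normalised
by the sum of the absolute values of their monomials, so one dimensionless
tolerance `1e-12` applies at any coordinate scale. Values within tolerance
are reported as 0: cocircular/cospherical points are *never carved*
(ties-outside), which keeps the cavity well-defined under degeneracy. In 2D
a post-pass canonicalises remaining cocircular ambiguity: for each adjacent
triangle pair whose four vertices are cocircular, the diagonal through the
lexicographically smallest vertex is kept. Duplicate points — closer than
`1e-9` x the data diameter — are rejected as errors before insertion.

The mesh is rebuilt from scratch after every topology-mutating action rather
than updated incrementally. At the framework's target sizes (tens to a few
thousand agents) a rebuild costs well under a millisecond through the
compiled core, and a full rebuild removes the entire class of incremental
update bugs; agents acting later within a step always observe a correct
neighborhood.

## V-cell extraction

In 2D, the V-cell of an interior generator is the ring of circumcircle
centers of its incident triangles, ordered angularly around the generator
(valid because the cell is convex and contains its generator); its area is
the shoelace area of that ring. In 3D the cell has one planar face per
Delaunay neighbor: the face shared with neighbor `q` is the ring of
circumsphere centers of the tetrahedra incident to the Delaunay edge
`(g, q)`, ordered cyclically around the edge axis; the volume is the sum of
pyramid volumes from the generator to each face. Requesting the V-cell of a
hull generator raises an unbounded-cell error — by construction this can
only be a media agent in a valid scenario.

Note that the V-cell of an interior generator near the hull can legitimately
extend far *outside* the convex hull of the generators (it is bounded, but
only by distant circumcenters). The test oracles account for this by
clipping against a box 50x the local point spread.

## Agent behaviors

All behaviors read only the acting agent's own fields and its 1-hop
neighborhood, and none of them ever moves, grows, divides, removes or
absorbs a media agent.

* **Movement** (`act_move`): displacement `step_length * u` with `u` a
  uniform random unit vector; with a per-type bias direction,
  `u = normalize(bias + noise_weight * r)`, so `noise_weight = 0` gives a
  deterministic directed step. A displacement landing within the
  duplicate-point threshold of another center is rejected and logged, never
  applied.
* **Growth** (`act_grow`): while the V-cell measure is below the target and
  fewer than `k_grow` (default 50) iterations have run, every non-media
  1-hop neighbor is pushed outward along the center-to-neighbor direction by
  `delta_push_frac` (default 0.02) times the mean neighbor distance, and the
  mesh is rebuilt. The grower's own center never moves. Because each
  bisector half-space of the grower's cell can only relax when its neighbor
  recedes and all other generators are unchanged, the grower's measure is
  provably non-decreasing across iterations. The mean distance is taken over
  the non-media neighbors being pushed (keeping the increment strictly
  local); the defaults converge on the hexagon fixture in 11 iterations to a
  1.5x area target, overshooting by under 5% per the discrete increment.
* **Division** (`act_divide`): the daughter inherits type, step length,
  division threshold and bias; it is placed `eps_div_frac * step_length`
  from the parent in a random direction (resampled up to 10 times on
  collision); both parent and daughter get half the parent's pre-division
  target size, so division pressure is self-limiting. For a non-motile
  divider (`step_length = 0`) the offset degenerates, and the fallback is
  `1e-3` x the mean neighbor distance.
* **Removal** (`act_remove`): the generator is deleted and the mesh rebuilt;
  surviving cells expand passively into the void (re-tessellation conserves
  the total measure of the biological region exactly when the removed
  agent's neighborhood was fully biological). `lambda_fill > 0` additionally
  drifts the former non-media neighbors toward the void center by that
  fraction of their distance — a minimal stand-in for active void
  competition, which the framework deliberately does not model in more
  detail.
* **Absorption** (`act_absorb`): the target moves by at most its step length
  per iteration toward the centroid of the absorber set until every
  non-media neighbor is an absorber; it is then flagged with a group label.
  Its type is unchanged: absorption is membership, not transdifferentiation.
  A capture that does not complete within `k_absorb` iterations is an error,
  not an infinite loop.
* **Rotation** (`act_rotate`, 2D only): one rigid rotation of the whole
  group about the pivot center per activation, preserving pairwise distances
  to machine precision.

## The engine

A step activates every alive non-media agent exactly once, in an order
uniformly shuffled by the single seeded random stream; each agent runs its
type's ordered behavior program (`move`, `grow`, `divide` — gated on the
division threshold —, `die` — a Bernoulli removal). Agents born during a
step first act in the next step. The triple (scenario, config, seed) fully
determines the trajectory.

The random stream is R's default generator; its serialized state is part of
the simulation state and of every checkpoint, so resuming from a checkpoint
reproduces the exact event log of an uninterrupted run. Checkpoints are
versioned JSON with all doubles encoded as 17-significant-digit strings:
bit-exact round trips, with `Inf`/`NA` surviving (plain JSON numbers provide
neither). Tampered or truncated files produce a classed
checkpoint-format error.

## Parameters

| parameter | default | units / meaning |
|---|---|---|
| `step_length` | 0.05 | displacement per move activation, length units |
| `noise_weight` | 0.5 | weight of the random component under a bias |
| `target_factor` | 1.0 | target size as multiple of initial V-cell measure |
| `division_factor` | Inf | divide at this multiple of initial measure |
| `death_prob` | 0 | per-activation removal probability |
| `delta_push_frac` | 0.02 | growth push, fraction of mean neighbor distance |
| `k_grow` | 50 | max growth iterations per activation |
| `eps_div_frac` | 0.1 | daughter offset, fraction of `step_length` |
| `lambda_fill` | 0 | post-removal drift fraction toward the void |
| `theta` | pi/6 | rotation per activation, radians |
| `k_absorb` | 1000 | max capture iterations |

Lengths are in abstract simulation units and steps in abstract time; the
framework deliberately does not map them to micrometres or minutes.

## What the synthetic scenarios do and do not establish

The packaged fixtures emulate the geometry of the demonstrations the
framework is built around: an idealized cyst (one `lmn` at the origin, a
`lec` shell, an outer `mec` shell, an enclosing media ring or
Fibonacci-sphere shell) and random general-position clouds. Default cyst
counts are 1/8/12/24 in 2D; shell radii default to 2, 3.2 and 5.5 lumen
radii, leaving enough margin that 100 steps of jittered random motion cannot
reach the media hull. The 2D shells are phase-offset so that no three
generators are exactly collinear through the origin, which would otherwise
create avoidable degeneracies at `jitter = 0`. These are idealized layouts:
real cysts have polydisperse cells, irregular shells and an extracellular
matrix, none of which the generator emulates. A green test therefore
establishes the *mechanics* — correct tessellation, correct bookkeeping,
deterministic replay — not any biological claim about cystogenesis.

Degenerate inputs are handled by policy, not by accident: duplicate points,
all-collinear/coplanar inputs, growth/V-cell queries on hull generators,
media in any behavior argument, and empty absorber sets are all classed
errors; cocircular ties resolve deterministically as described above.

## Known limitations

* No force-based mechanics, adhesion energies, or subcellular resolution:
  "pushing" during growth is a fixed radial increment, not a solved
  mechanical equilibrium.
* Weighted (Laguerre) tessellations, periodic boundaries and kinetic updates
  are out of scope; cell size control works through point density only.
* Rotation is 2D only, matching the behavior set it reproduces.
* The engine is serial; determinism is defined with respect to the single
  activation stream.
* Robustness is tolerance-based (normalised predicates in extended
  precision), not exact-arithmetic; inputs engineered to sit within `1e-12`
  of degeneracy across many points may resolve ties arbitrarily, though
  still deterministically.
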