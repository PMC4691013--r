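---
title: "Methods: probe-size-resolved accessibility from voxel segmentations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probe-size-resolved accessibility from voxel segmentations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(tomoaccess)
```

This vignette explains the model behind `tomoaccess`, the numerical
choices made in implementing it, and what the package's synthetic
phantoms do and do not establish about real tomography data.

## The accessibility model

The input is a 3D label grid separating *biomass* from *void* (with an
optional *lumen* label on void voxels), on an isotropic voxel grid with
spacing in nanometres. The model treats a catalyst as a rigid sphere of
radius `r` diffusing through void space from a seed region Σ.

Four scalar fields build on one another:

1. **EDT** — exact Euclidean distance from every voxel centre to the
   nearest biomass voxel centre. `EDT(x)` is the largest sphere that can
   be *centred* at `x`.
2. **CRT** — the largest sphere that can *cover* `x`:
   the maximum of `EDT(c)` over all centres `c` whose sphere reaches
   `x`. This is the classic local-thickness / pore-size field and is
   computed by maximal-sphere painting: each centre raises the output
   within its inscribed sphere to at least its own EDT value.
3. **aEDT** — accessibility enters through the superlevel sets
   `Void(r) = {EDT > r}`, the positions where a radius-`r` sphere can
   sit. `aEDT_Σ(x)` is the largest `r` for which a connected path within
   `Void(r)` joins Σ to `x`: a widest-path (maximum-bottleneck) value.
   It is at most `EDT(x)`, and it is 0 for void unreachable at any
   positive radius.
4. **aCRT** — painting applied to the aEDT instead of the EDT: the
   largest sphere that can both arrive from Σ and overlap `x`. A cavity
   guarded by a bottleneck of radius `b` receives the uniform value `b`.

Surface accessibility evaluates the aCRT on the biomass surface. Because
the aCRT is discontinuous there (zero inside biomass), interpolation is
meaningless; instead each mesh vertex takes the *maximum* aCRT over all
voxel centres within a range of interaction ε. The accessible area at
radius `r` is the summed area of triangles whose accessibility reaches
`r`, reported raw (nm²), as a fraction of total mesh area, and per unit
biomass volume (1/µm). Both normalizations are emitted because both are
in common use; the per-volume form is the one that permits comparisons
across samples of different sizes.

### Computing the aEDT: the join tree

Searching over all paths is avoided by indexing the connectivity of
every `Void(r)` at once with the join tree of the EDT's superlevel sets:
a descending sweep over the distinct EDT values, merging components with
union–find. Leaves are pore maxima (possible probe destinations or, on
the image boundary, probe sources), branch nodes are bottlenecks, and
each void component is closed by a root at level 0. Every void voxel is
mapped to the arc whose level span contains it.

Tagging then computes, per arc, the widest-path value `B` from the seed:
arcs containing seed voxels start at the seed voxels' own EDT values
(the seed caps every path through it — a probe must fit where it
starts), and `B` propagates across nodes, each node's level capping the
value. Where `B` equals the arc's upper level the arc lies on a seeded
descent path and the EDT itself governs; the stored tag is the `+Inf`
sentinel. The voxel lookup is `aEDT(x) = min(EDT(x), tag(arc(x)))`.
For a seed consisting of whole leaves this reduces exactly to the
familiar three-step tagging (select seed leaves; descend to the roots
preserving EDT values; give each untagged subtree the level of the
branch it hangs from). The generalisation to arbitrary seed *voxel sets*
matters for thin lumen slivers, whose own clearance may be the binding
bottleneck.

One modelling choice deserves emphasis: the lookup takes the *minimum*
of the local EDT and the arc tag. Taking the maximum would let a voxel
report a radius larger than a sphere that fits there, contradicting the
defining path condition and the uniform labelling of guarded cavities.
The package asserts the min-rule's correctness by demanding exact
voxelwise equality with two literal implementations of the definition
(a maximum-bottleneck Dijkstra sweep and a threshold-sweep flood fill)
on irregular random masks, at both 6- and 26-connectivity.

### Discretization and connectivity

Paths live on the voxel graph. The default connectivity is 6
(face-adjacency): a finite-radius sphere cannot pass through an
edge- or corner-contact between voxels, so 6-connectivity is the
conservative physical choice. The convention is configurable (18, 26)
and shifts recovered bottleneck radii by up to about one voxel diagonal;
the tree, the oracles and the component labelling always use the same
setting. The grid boundary is open void, not biomass — boundary voxels
measure distances only to biomass inside the grid, which is what allows
boundary seeding to model access from outside the imaged volume.

All distances are physical (nm) between voxel centres. The painting
predicate `|y − x| ≤ D(x)` is evaluated on squared distances in voxel
units with a 1e-7 absolute slack; since squared lattice distances are
integers and `D²` is an integer for EDT input, the inclusive comparison
is exact. Ties in the sweep (plateaus of equal EDT value) are broken in
column-major voxel order, and same-value plateau artefacts are collapsed
so that node values strictly decrease from leaf to root and a plateau
yields exactly one leaf.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `connectivity` | 6 | – | path/component adjacency (see above) |
| `epsilon` | 1.1 × spacing | nm | range of interaction for surface sampling; just over one voxel suppresses partial-volume artefacts, larger values only inflate areas |
| `prefilterWeight` | 0.1 | – | 3-tap indicator prefilter before marching cubes (below) |
| `rule` | `"all"` | – | a triangle is accessible when **all** its vertices are (conservative lower-bound area); `"mean"` available |
| `radii` | step grid | nm | default curve grid is 0 plus every distinct positive vertex value — the exact step curve |

The curve defaults favour exactness: `aArea(0)` equals the total mesh
area identically, and the curve is non-increasing by construction.

## Surface extraction

The biomass surface is extracted by marching cubes at iso-level 0.5 on
the biomass indicator, implemented as per-cube contour tracing:
interpolated edge crossings are joined into face segments (ambiguous
faces resolved by the mean of the four corner values, identically on
both sides of a shared face, keeping the mesh watertight away from the
grid boundary) and the resulting loops are fan-triangulated. Biomass cut
by the grid boundary is left open there — cross-sections are not real
surface and are excluded from area integrals.

Raw binary marching cubes carries a staircase bias: on a voxelized ball
of radius 20 voxels it overestimates the area by roughly 8–9%. The
indicator is therefore pre-filtered with a separable 3-tap kernel
(edge weight `w = 0.1`, centre `0.8` per axis) before meshing. The
weight is chosen so the filtered centre value of an isolated voxel,
`0.8³ ≈ 0.51`, stays above the iso-level: single-voxel features keep a
(tiny) closed surface, while the measured ball-area error drops to
about 3% and a voxelized box stays within 4% of its half-voxel-offset
surface area. `prefilterWeight = 0` recovers the raw binary mesh.

Vertex accessibility sampling deliberately uses voxel *centres* within
ε (not trilinear interpolation) to avoid averaging across the
discontinuity at the surface.

## Seed strategies

- `lumen`: all LUMEN-labelled voxels. The physiological entry route;
  a lower bound on accessibility, since real paths may also leave and
  re-enter the imaged volume.
- `boundary`: all void voxels on selected grid faces — by default the
  two faces normal to the thinnest grid dimension, which for tomograms
  is the axial section axis (stored as the first array index, z). Any
  face subset can be selected; the natural choice is the set of faces
  through which the pore system plausibly continues. An upper bound.
- `none`: everything accessible; the aCRT equals the CRT.

Whenever the boundary faces cut through the wide part of the void space
that the lumen occupies (the situation in section tomography), the three
strategies are ordered voxelwise: lumen ≤ boundary ≤ none. The package
asserts this on its slab and dumbbell phantoms. The ordering is not a
theorem for arbitrary face choices — a face that only grazes a thin
sliver of lumen seeds the tree with small clearances and can undercut
the full lumen — which is why the faces are explicit parameters.

## What the phantoms emulate

The generators produce segmentations with analytically known
accessibility structure, rasterized by voxel-centre inclusion so that
recovered radii are accurate to about one voxel:

- `spherePorePhantom` — a single spherical pore: CRT ≈ R everywhere in
  the pore; with a degenerate full-width opening, boundary accessibility
  equals the CRT.
- `dumbbellPhantom` — two cavities joined by a channel of radius `a`,
  the canonical bottleneck; optional openings and a labelled lumen pad.
  The saddle of the join tree and the aCRT throughout the guarded cavity
  both recover `a` to within a voxel.
- `delaminatedSlabPhantom` — a wall with internal planar gaps that touch
  only the axial faces, reproducing the lumen-vs-boundary seeding gap of
  delaminated cell walls; an optional neck connects the first gap to the
  lumen, whose radius then governs lumen accessibility of the gaps.
- `roughWallPhantom` — a cavity-free undulating wall whose ridges run
  along the section axis, so the geometry continues through the axial
  faces as real walls do; the default amplitude/wavelength (4 nm / 32
  nm) keep the surface slope below 1, making the void star-shaped away
  from the wall. Under these conditions all three seed strategies
  coincide exactly, and the accessible-area decay is driven purely by
  surface texture; at large probe radii a rough wall's accessible
  fraction falls below a flat wall's, the texture-crossover effect.
- `randomBlobsPhantom` — thresholded smoothed Gaussian noise at a target
  porosity (default 0.5, kernel sd 1.5 voxels), with a lumen label on
  void near one face; used for the oracle-equivalence property tests on
  geometry with no special structure.

What passing these tests shows: the algorithms implement the stated
definitions exactly on the discrete grid, and the derived quantities
recover known geometry to within rasterization error. What they do not
show: anything about segmentation quality, reconstruction artefacts,
missing-wedge anisotropy, or partial-volume effects in real tomograms —
the phantoms are clean labellings, not simulated images. Real analyses
inherit whatever bias the upstream segmentation carries.

## Problem sizes and costs

The test-suite geometry sizes are chosen so every oracle comparison is
literal: EDT exactness on 16³ masks against the all-pairs oracle,
painting on 20–24³ against the double-loop oracle, aEDT equivalence on
25 random 24³ masks × 3 seed strategies × 2 connectivities, and full
phantom pipelines at 32–64³. The painting step is the only
super-linear one (O(m·n) in void voxels times sphere volume); the
non-redundant-centre pruning (`nonredundantCenters`) removes centres
whose spheres are contained in a neighbour's and reproduces the full
painting exactly, which the tests assert.

## Known limitations

- Isotropic grids only; anisotropic spacing is rejected at I/O rather
  than resampled, and no resampling is provided.
- Spherical probes only; no shape or flexibility effects.
- The lumen/boundary bounds bracket, but do not identify, the true
  accessibility of structures that exit the imaged volume.
- TIFF output is restricted to values in [0, 1] (a limitation of the
  underlying bindings) and carries no spacing metadata; NRRD is the
  lossless interchange format.
- The CRT/aCRT of very open volumes (deep void with large EDT values)
  makes painting the dominant cost; pruning helps, but the package does
  not parallelise it.
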