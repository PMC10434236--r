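---
title: "Generating dense white-matter fibre substrates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Generating dense white-matter fibre substrates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmphantom)
```

Monte Carlo diffusion simulators need numerical phantoms — explicit 3D
geometries of white-matter tissue — whose packing density, axon calibres,
myelin content and fibre orientation statistics match histology.  Plain
cylinder packings saturate around 75% fibre volume fraction (FVF), while
electron and light microscopy report intracellular fractions up to 90–95%.
`wmphantom` closes that gap with a three-stage pipeline: substrate
initialisation, joint fibre optimization, and voxel-based fibre radial
growth, followed by surface meshing and a metrology layer.

## The model

**Fibres as capsule chains.**  A fibre skeleton is an ordered set of 3D
control points $x_i$ with per-point radii $r_i$; each consecutive pair forms
a *capsule* (a swept sphere with linearly interpolated radius), the
collision primitive.  Adjacent capsules share their common control point and
radius, so a fibre with $m$ points has $4m$ free parameters — far fewer than
per-slice circle parameterisations.  Control points are spaced between half
and twice the local radius (with a 1 um ceiling), so the sampling frequency
increases as radii decrease.

**Overlap cost.**  For two capsules on different fibres, the closest points
of their axes are found in closed form: minimise
$g(t_a, t_b) = \lVert (1-t_a)p_0 + t_a p_1 - (1-t_b)q_0 - t_b q_1 \rVert^2$
over the unit square, clamping and re-projecting at the boundary.  With
closest centres $c_1, c_2$ and interpolated radii $r_p, r_q$, the overlap
depth is $D = 1 - \lVert c_1 - c_2 \rVert / (r_p + r_q)$, and the pairwise
penalty is

$$ f_1 = D^2\, \lVert p_1 - p_0\rVert\, \lVert q_1 - q_0 \rVert\, r_p\, r_q
   \quad (D \ge 0), \qquad f_1 = 0 \ (D < 0). $$

The cost vanishes quadratically at contact, so it is $C^1$ across the
boundary, and its analytic gradient with respect to all eight capsule
parameters is implemented in compiled code, differentiating *through* the
closest-point parameters ($2\times2$ implicit system when both are
interior, one-dimensional projection when one is clamped).  For exactly
parallel segments the overlap midrange is used, a deterministic tie-break
under which coincident segments return $t_p = t_q$; the gradient there
treats $t_p$ as locally fixed (a measure-zero configuration).

**Regularizers.**  Four smooth penalties keep fibres coherent, ordered by
priority below the overlap term: curvature
$\sum_i \lVert x_{i-1} - 2x_i + x_{i+1} \rVert^2$; length (squared positive
part of the polyline length excess over the initial length); radii change
$\sum_i (r_i - r_i^{\text{target}})^2$; and compactness (squared distance
of the fibre centroid to the bundle central axis).  These are this
package's own definitions, chosen to be smooth, analytic, and zero for a
straight fibre at its initial length with unchanged radii; they match the
stated intent of the penalties rather than any specific published formula.
Default weights (1, 0.1, 0.05, 0.02, 0.005) decay by rank so the ordering
is unambiguous.

## Substrate initialisation

Fibre outer *diameters* are drawn from a gamma distribution — default shape
0.5, scale 1.1, truncated to 0.5–4 um, giving a mean diameter of 1.25 um —
a long-tailed calibre distribution of the kind reported by histology.  The
shape/scale reading of the two gamma parameters, and sampling on diameters
rather than radii, are deliberate choices documented here once; the
truncated-gamma mean used in tests comes from numerical quadrature, not
from the sampler.

Disks with those radii are packed onto the bottom face of an
$L \times L \times H$ cuboid by random placement plus repulsive relaxation
under a radius ramp; packing stops when the sampled disk areas reach the
target density (the greedy sampler stops within one disk of the target).
If the target density exceeds 0.75 — the practical jamming ceiling for this
packer — all radii are shrunk by $\sqrt{0.75/\text{target}}$ so the packed
face density is exactly 0.75, and every fibre records its full-size radius;
radial growth restores the difference later.

**Dispersion.**  The mean angle $\eta$ between fibre chords and the bundle
axis is realised by pairing each bottom disk with a top-face disk displaced
laterally by $d = H \tan\varphi$, with $\varphi$ drawn from a folded normal
$|N(\eta, \eta/3)|$ whose mean equals $\eta$ to within 0.01% at this
spread, and the azimuth drawn uniformly over directions that keep the disk
inside the face (so boundary clamping cannot bias the mean downwards).  The
top face is then re-packed by relaxation from those target positions.  At
300+ fibres the realised mean chord angle is within 1 degree of $\eta$.

**Crossings.**  Two bundles are built in their own cuboids and moved by
rigid transforms only — bundle 1 onto $+X$, bundle 2 at $\theta$ degrees in
the XY plane — preserving lengths, radii and intra-bundle dispersion.
After optimization, `trim_crossing()` keeps only fibres meeting the central
region (default: the axis-aligned cube with half the box side) and clips
their chains to it.

## Joint fibre optimization

Adagrad descent (base rate 0.05, accumulator offset $10^{-8}$) alternates
blocks of 50 overlap-only iterations with 10 guarded polish iterations on
the regularizers, until no cross-fibre capsule pair has $D > 0$; a final
polish budget (50 iterations) then runs under a hard no-overlap guard: any
step that re-creates an overlap or increases the summed regularizer cost is
rolled back with up to five step halvings.  Fibre endpoints stay pinned to
the cuboid faces (moving them would change the dispersion); interior points
and all radii are free, radii clamped to 0.4–1.0 of their targets so the
cost cannot collapse fibres.

One numerical point deserves emphasis: a penalty $\propto D^2$ has a
vanishing gradient at the contact boundary, so plain descent approaches
zero overlap only asymptotically.  The overlap phase therefore descends on
the cost of radii inflated by a 4% margin, while termination is checked
against the *true* radii — the gradient stays alive until the true
overlaps have strictly cleared.  Pair candidates come from a
fixed-radius-cell hash grid whose cell size is twice the largest capsule
half-extent plus radius, so the 27-cell neighbourhood provably contains
every overlapping pair; the grid is rebuilt every iteration.

## Fibre radial growth

The box is discretised at resolution `min(0.1 um, smallest diameter / 5)`
(at least five voxels across the smallest fibre).  Voxels whose centres lie
inside a fibre's capsule chain are claimed by that fibre (ties at touching
surfaces go deterministically to the lowest id).  Growth then proceeds in
breadth-first layers: each layer visits the frontier in seeded random
order and claims unclaimed 6-connected neighbours whose centres lie within
the fibre's *Euclidean radius cap* — the per-point full-size target radius
times a cap factor — measured against a local window of the fibre's
capsules.  Masks may touch but never interpenetrate, stay connected, and
total fibre volume is non-decreasing per layer.  Because the cap is
Euclidean (not a layer count), grown cross-sections stay round rather than
acquiring the Manhattan-ball bias of naive BFS dilation.

Two seeding strategies are exposed: `uniform` (the whole rasterized capsule
is the seed; smooth fronts, radius variation within a narrow band) and
`random` (a seeded random subset of capsule voxels; irregular fronts and
tortuous surfaces, variation up to about half the local radius).  Explicit
longitudinal radius patterns — e.g. alternating 1 um / 2 um capsules — are
set with `radius_modulation()`.  With cap factor 1 an isolated fibre
regrows exactly to its target radius; the max-density preset raises the
factor to 1.5 so fibres can fill the extracellular pockets between
cylindrical shapes, which is what pushes FVF beyond the ~75% cylinder
ceiling.  Growth can also stop when the FVF over the analysis region
reaches a requested value; the stop is checked per claimed voxel, so a
target FVF is hit essentially exactly.

**Myelin.**  The inner (axonal) mask is the 6-connected morphological
erosion of each outer mask by a per-fibre depth
$k_f = \mathrm{round}(r_f\,(1-g)/\text{res})$, with $g$ from the aggregate
relation below; a greedy refinement then adjusts each $k_f$ by one voxel
(largest fibres first, two passes) to minimise the substrate-level myelin
count error over the analysis region.  Fibres whose shell would be thinner
than a voxel keep $k_f = 0$ and are reported as unmyelinated-thin.  On the
grid, AVF + MVF = FVF and FVF + EVF = 1 hold exactly by voxel counting.

## Meshing

Surfaces are extracted by marching tetrahedra on the Freudenthal (Kuhn)
subdivision of the voxel-centre lattice.  This variant was chosen over
table-based marching cubes deliberately: on binary masks it has no
ambiguous cases, so the 0.5-isosurface is a closed, consistently oriented
2-manifold *by construction* — the property Monte Carlo simulators actually
require — at the cost of roughly twice the triangle count.  A consequence
worth knowing: the smallest closed isosurface, around one isolated voxel,
encloses half a voxel volume.  On a digital ball of radius 20 voxels the
mesh volume is within 2% of the analytic sphere.

Meshes are then smoothed (uniform Laplacian, default 10 iterations at
relaxation 0.5) under a volume guard that rolls back any iteration pushing
the enclosed volume more than 2% from the input, and decimated by
shortest-edge midpoint collapse (default to 25% of the input triangles)
under a link-condition check (manifoldness), a normal-flip check, and the
same cumulative volume guard.  `validate_mesh()` reports watertightness,
orientation, component count, self-intersections (grid-accelerated
triangle-triangle test), volume and area; binary little-endian PLY is the
primary export.

## Metrology

Volume fractions are voxel-count ratios over an analysis region — by
default the central 80% of the box per axis, which excludes the face
artefacts of pinned endpoints and clipped fibre ends.  The aggregate
g-ratio is computed as

$$ g = \sqrt{1 - \mathrm{MVF}/\mathrm{FVF}} = \sqrt{\mathrm{AVF}/\mathrm{FVF}}, $$

the square-root volume-fraction relation; with MVF = 35 and FVF = 60 it
gives 64.5%.  Equivalent-radius profiles slice each fibre mesh orthogonally
to the local skeleton tangent at 1 um arc-length steps, assemble the
cross-section polygons from the plane-mesh intersection, select the loop
containing the skeleton point, and report $\sqrt{\text{area}/\pi}$; slices
with no containing polygon are flagged missing, never interpolated.  The
per-substrate radii distribution uses each fibre's mean profile radius; its
distance to the truncated target gamma is the Wasserstein-1 metric
(chosen over KS as the primary number because it is robust at small fibre
counts; the KS statistic is reported alongside).

## What the generator does and does not emulate

The synthetic substrates carry realistic packing density, gamma-distributed
calibres, controllable dispersion and crossings, myelin shells with a
target g-ratio, and tortuous non-circular cross-sections produced by
competitive voxel growth.  They do not model Ranvier nodes, beading, glia,
vasculature, permeable membranes, fanning or kissing configurations, or
more than two bundles.  Passing tests therefore demonstrate geometric and
statistical fidelity to the stated targets — not biological completeness of
the microstructure.

## Problem sizes and numerical choices

The test suite and the acceptance analyses run at desk scale, chosen as the
smallest sizes at which each claim is meaningful: the density and
target-fidelity analyses use a 50 um box at 0.1 um resolution (~1000
fibres, 125M voxels); dispersion recovery uses 35 um bundles (300+
fibres); the radii-distribution size trend compares 8 um and 16 um boxes
over five seeds; diameter targeting uses a seven-fibre toy at 0.05 um.
The same code runs cluster-scale boxes (hundreds of um) unchanged — only
memory and patience differ.  Determinism: every stage draws from a
substream derived from the one pipeline seed by fixed offsets, so a config
plus seed reproduces byte-identical metrics, and stage-wise resumption
equals a single-shot run.

Known limitations: erosion depths are integer voxels, so very thin myelin
sheaths quantise (mitigated by the per-fibre refinement; unresolvable for
shells under half a voxel); the 2D packer is a relaxation method without a
jamming guarantee, so initial densities above ~0.75 are reached via the
shrink rule rather than packed directly; and the parallel-segment gradient
tie-break is non-smooth on a measure-zero set.
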