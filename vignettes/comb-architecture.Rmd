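---
title: "Quantifying honey bee comb architecture from volumetric scans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying honey bee comb architecture from volumetric scans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(combscan)
```

## The problem

*Apis mellifera* workers build comb as double-sided sheets of hexagonal
cells that meet back-to-back at a median interface. The canonical cell
geometry is remarkably stereotyped: lumen edge lengths of roughly
2.25–2.75 mm, wall thicknesses near 0.75 mm, depths of 10–11 mm, a
center-to-center spacing of 7–10 mm between parallel sheets, and an
upward tilt of the cell axis of about 13° away from the interface
normal, against gravity. When the colony's environment is perturbed —
for example by rotating the enclosure mid-build — the comb responds
with curvature, branching lobes, and cells whose tilt records the
gravity direction that prevailed when they were made. Micro-CT scans of
such combs are therefore an archive of construction behavior, but
reading that archive requires quantitative geometry rather than visual
inspection.

`combscan` provides that geometry. It maintains three linked
representations of a scanned comb and a set of analysis layers over
them, each validated against a deterministic synthetic comb phantom
with complete ground truth.

## Representations and their numerical choices

A scan enters as a **density volume**: a regular voxel grid with
isotropic spacing in mm and values normalized to [0, 1]. Normalization
is per volume (min–max); the typical working resolution is 0.2 mm,
i.e. roughly a fifth of a cell wall, and `downsample()` provides
block-mean pooling for heavier computations. Binarizing at an
iso-threshold yields the **signed distance field** (SDF): the exact
Euclidean distance from every voxel center to the nearest voxel of the
opposite phase, negative inside. We use the exact (Felzenszwalb)
transform rather than a chamfer approximation so that small-grid
results are reproducible to machine precision; the default threshold is
0.5 of the normalized range and is deliberately not auto-tuned
(determinism matters more here than adaptivity). The **surface mesh**
is extracted by marching tetrahedra on the six-fold (Kuhn) subdivision
of each grid cube. This choice has no case tables to transcribe, is
conforming across cube faces (no cracks), and after welding coincident
vertices produces closed orientable meshes: an analytically sampled
ball of radius 10 mm meshes to within 0.1% of its true area with Euler
characteristic 2. Triangles are wound so normals point toward positive
distance (outward).

## Morphology on distance fields

Dilation and erosion by a ball of radius $r$ act directly on the SDF: a
voxel belongs to the dilation when its signed distance is at most $r$,
and survives erosion when its interior depth exceeds $r$. Every
composite operator re-establishes an exact SDF afterwards, so level-set
drift never accumulates beyond one voxel; the dilated grid is padded by
$\lceil r/h\rceil + 2$ voxels so offsets cannot clip. These discrete
definitions coincide voxel-for-voxel with brute-force Minkowski set
arithmetic, which is how the test suite checks them, and they make
closing/opening exactly idempotent. Boolean union, intersection, and
subtraction are the pointwise min/max compositions of the distances,
redistanced.

One practical subtlety: the morphological **closure** of a comb — the
roof over the open cell mouths — also wraps the comb's outer rim in a
thick fillet ("collar") wherever the slab is thicker than the ball
diameter. The cell-extraction stage removes it with a component-volume
filter (components outside 0.25–3 times the median component volume are
discarded and counted in `n_filtered`).

## Curvature at the scale of a bee

Comb curvature is estimated by local quadric fitting. Around every
vertex, all vertices within a **mesh-geodesic** ball are collected —
geodesic, not Euclidean, so the opposite sheet 7–10 mm away is never
captured — and expressed in a tangent frame whose z axis is the
area-weighted vertex normal, pointed inward so that convex solids carry
positive principal curvature. The height function
$z = ax^2 + by^2 + cxy + dx + ey$ (no constant term: the surface passes
through the query point) is fitted by least squares with a singular
value rank check (condition number above $10^8$ flags a degenerate
neighborhood, which inherits the nearest valid value and is marked in a
QC channel). The shape operator of this Monge patch at the origin gives
the principal curvatures, hence $K = \kappa_1\kappa_2$ and
$H = (\kappa_1 + \kappa_2)/2$. The default sampling radius is 15 mm,
matching the tactile reach of a worker bee; it is a plain parameter.
Two rounds of neighbor-mean smoothing follow by default, after which
$K$ and $H$ are recomputed from the smoothed principal curvatures so
the per-vertex identities hold exactly.

A caveat the phantom makes explicit: most of a comb's surface area lies
*inside* the open lumens, so curvature of the raw comb surface is
dominated by cell-scale relief. Macro-scale curvature (lobe bending) is
best measured on the comb **envelope** — the morphological closure —
which is how the package's own bent-versus-flat comparison is run.

## Density-weighted geodesics and build direction

Travel cost solves the eikonal equation $|\nabla u| = 1/s$ by
first-order fast marching (Godunov upwind, 6-neighborhood) on the voxel
grid; the heat-method alternative was deliberately not implemented
because fast marching is deterministic and directly comparable to graph
shortest-path oracles. With $s \equiv 1$ the cost is geodesic distance
in mm; with `metric = "density"` the speed is the local normalized
density clamped to $[10^{-3}, 1]$ — clamping is ours, to avoid infinite
slowness in air — which makes travel through dense material cheap and
reproduces the bees' substrate-outward growth parameterization.
First-order fast marching carries an $O(h)$ error with a noticeable
constant on paths oblique to the grid: a 30 mm in-plane distance at
0.5 mm spacing is recovered to 2%, while a helical path on a thin
curved shell needs 0.25 mm spacing and a ~1 mm shell to reach 3%; those
are the resolutions the validation suite uses for such cases.

The regional **build direction** is the mean of unit gradient vectors
of $u$ over a voxel region (unit vectors, not raw gradients, because
the gradient magnitude varies with the metric while only direction is
sought), re-normalized, with dispersion $1 - |\bar g|$ reported: 0 for
coherent growth, 1 for isotropic growth. On phantoms grown downward
from a substrate slab the recovered direction aligns with the planted
growth axis to better than 0.99 dot product.

## Spectral segmentation and curve skeletons

The Laplace operator is assembled either with cotangent weights and a
lumped (barycentric) mass matrix — the default for manifold harmonics —
or as the uniform graph Laplacian. Eigensolving reduces the
generalized problem by $M^{-1/2}$ and calls a dense symmetric
eigendecomposition; this caps practical mesh sizes at a few thousand
vertices, so surface meshes are first reduced by vertex clustering
(`n` target clusters) in which connectivity is inherited from the full
edge set and the largest component is kept. Clustered meshes are
usually non-manifold, which the cotangent assembly rejects; skeleton
and segmentation workflows therefore run on the graph Laplacian, whose
Fiedler vector carries the same ordering information. Eigenvector signs
are fixed deterministically (first non-negligible component positive).

Segmentation takes equal-mass quantile bins of the Fiedler vector —
deterministic, unlike k-means — and equips each segment with the plane
of its first two principal components. The curve skeleton takes the
centroid of every connected component of every Fiedler quantile band
(components under 3 vertices are dropped with a warning), links the
centroids with Prim's minimum spanning tree under Euclidean weights
(ties to the lowest index), and assigns tangents pointing toward
increasing Fiedler value. Oriented cross-sections resample the volume
on the plane normal to a node's tangent.

## Cells, tilt, and gravity

The negative space of a comb section is the Boolean difference between
its 10 mm closure and the section itself. An opening of increasing
radius (step = one voxel) severs the thin sheet connecting cell mouths;
the schedule stops when the 6-connected component count repeats across
two consecutive radii, and if clipped section boundaries keep the count
from ever settling, the most persistent (modal) count is used instead.
For cropped sub-regions a fixed `opening_radius_mm` (about the wall
thickness) can replace the schedule entirely. Components are filtered
by the volume rule above; cells whose voxels come within an
opening-radius margin of the grid edge are flagged as boundary-clipped
and excluded from orientation statistics.

Each cell gets a principal-component frame (axes by descending
variance, right-handed, long axis oriented away from the median plane;
near-spherical blobs are flagged degenerate). The **median plane** is
the least-squares plane through the cell base points, where a cell's
base is its voxel farthest from the cell's own mouth — the mouth being
the lumen voxels bordering the exterior of the closed comb. Measuring
each cell against its own mouth (by a small per-cell distance
transform) is what keeps base points meaningful when a crop slices
through neighboring cells.

**Tilt** is the angle between the cell's long axis and the median-plane
normal. This is the convention under which the canonical comb cell
measures 13°; the complement convention (angle to the plane itself)
would report 77° and contradicts both the canonical value and the
phantom's planted geometry, so it is not used. Because honey-holding
cells tilt upward, gravity at construction time is recovered as the
negated robust mean (componentwise median, re-normalized) of the unit
in-plane projections of the cell axes; if the median projection is
below 0.05 — cells essentially perpendicular to the plane, e.g. a 0°
phantom — the estimate is refused as unresolvable rather than returned
as noise. **Width** is the minimal caliper extent over directions
perpendicular to the long axis: for a hexagonal lumen that is the
flat-to-flat width ($\sqrt3 \times$ edge $\approx 4.33$ mm for a
2.5 mm edge), which is the quantity apiarists call cell width. The mean
caliper over the two PCA minor axes was rejected because those axes are
rotationally degenerate for a hexagon and the mean caliper of a hexagon
is 8–12% larger than flat-to-flat. Depth is the voxel extent along the
long axis plus one voxel; volume is voxel count times voxel volume.

On the 37-cell validation phantom at 0.2 mm these recover the planted
count exactly, width and depth within two voxels, gravity within 1°,
and tilt within 2° — the residual tilt bias of about +1.5° comes from
the mouth and base of each lumen being cut parallel to the comb face
rather than perpendicular to the cell axis, exactly as in real comb.

## Materials

Attenuation of light organic materials is approximately proportional to
physical density, so a least-squares line through reference points
(e.g. a 1.19 g/cm³ printed substrate and 1.4 g/cm³ honey) calibrates
normalized values to g/cm³; with two references the line interpolates
them exactly, and non-monotone references are rejected. Material bands
are half-open intervals $(lo, hi]$ — ties go to the denser band so
adjacent bands partition cleanly — and band volumes are voxel counts
times voxel volume, with no partial-volume correction (a known,
documented bias of the estimate). Calibration is global; no spatial
field correction is attempted. The honey-volume convenience multiplies
out to ml and can be restricted to extracted cell interiors.

## Build order

The construction timeline walks the curve skeleton from its endpoints
toward the substrate along decreasing geodesic cost. Segment boundaries
are skeleton nodes of degree ≥ 3 — and, beyond that, sharp bends of
the skeleton tangent (default threshold 45°), because a mid-build
rotation of the hive produces a reorientation without any branch.
Reversing the walk orders segments root-first; siblings are ordered by
ascending mean geodesic cost and ties are flagged, since the heuristic
genuinely cannot distinguish them. Per-segment build direction is the
mean geodesic gradient over the voxels nearest the segment's nodes, and
per-segment gravity re-runs the tilt estimator on the segment's cells
(segments with fewer than 5 usable cells inherit the parent's gravity,
flagged). For strongly bent combs the more robust route — used by the
package's own validation — is regional: Fiedler-segment the comb into
two regions, crop each, and run the cell pipeline per region; on a 90°
mid-build rotation phantom this recovers the two planted gravities to
within a degree of their true 90° separation.

## The phantom generator, and what passing it does and does not show

`generate_phantom()` voxelizes an idealized comb with the canonical
geometry above as defaults (edge 2.5 mm, wall 0.75 mm, depth 10.5 mm,
tilt 13°, lobe spacing 8.5 mm, 0.2 mm voxels). Cells are true hexagonal
prisms about the tilted axis — point-up, one vertex toward the
substrate — whose mouths and bases are cut parallel to the median
plane, as in real comb; a solid rim band surrounds the outermost
lumens; an optional denser substrate slab spans the comb top (full
width, so the closure cannot manufacture pocket artifacts under an
overhang). Warps (cylinder bend, saddle, 90° L-bend, Y-branch hinged at
the comb faces so branches clear each other) emulate perturbed builds,
and materials (wax 0.93, honey 1.4, substrate 1.19, repair seam
1.05 g/cm³) are encoded as normalized value = density / 2, the
phantom's known calibration line. Honey can be planted to an exact
voxel budget (the validation suite uses 9300 mm³). The same spec and
seed reproduce the volume bit for bit.

What the phantom does **not** emulate: scanner noise and artifacts
(beam hardening, rings), partial-volume blur at material boundaries,
biological irregularity of cells, propolis, brood, or wax of spatially
varying density. Passing the phantom suite therefore demonstrates that
the geometry pipeline is correct and self-consistent at realistic
scales — not that segmentation thresholds or calibrations transfer to
any particular scanner without per-scan references, which is why the
calibration API requires user-supplied reference points per scan.

## Problem sizes used in validation

The validation suite runs phantoms at 0.2 mm (cell metrics, the paper's
working resolution), 0.3–0.45 mm (material budgets, warped combs,
spectral workflows), meshes of up to ~20k vertices (clustered to ≤2.5k
for spectral work), and 16³ grids for the exact morphology oracles.
These sizes were chosen so each check runs in seconds to a few minutes
while staying above the two-voxel wall-resolution floor the generator
enforces.
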