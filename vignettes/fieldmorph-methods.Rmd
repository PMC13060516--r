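---
title: "Morphing, flattening and transferring projected-field annotations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphing, flattening and transferring projected-field annotations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fieldmorph)
```

Sensory neuroprosthesis studies ask participants to annotate where an
electrically evoked sensation is felt. When those annotations live on a 3D
triangle mesh they must be brought into register with other representations
— a flattened 2D body diagram, or another participant's patient-specific
mesh — before any quantitative comparison is possible. This vignette
describes the geometry `fieldmorph` uses to do that, the assumptions behind
each step, and the design choices that were genuinely open.

## Data model

A mesh is vertices plus counter-clockwise-wound triangles; annotations
(`projected_field`) are stored **face-level**, because faces are the
paint/erase unit of annotation interfaces, with per-vertex binary arrays as
a derived view (a face sets its 3 vertices; a face is recovered when all 3
of its vertices are set). Hotspots are 3D surface points, not face indices,
since they mark loci rather than regions; scale ratings (naturalness, pain,
overall intensity) are normalized to [0, 1] independent of any slider's
pixel range; each quality descriptor carries its own intensity and an
above/at/below-skin depth. Internally all indexing is R's native 1-based;
OBJ (1-based) and GLB/JSON (0-based) are converted at the I/O boundary, so
serialized annotations remain language-neutral.

Landmark sets name their points: *primary* landmarks sit on the joint
hierarchy, *accessory* landmarks are width markers tied to a primary by
base name (`Rdip` owns `Rdip_t`, `Rdip_p`; the base name is the text before
the first underscore, `_t` thumb-side, `_p` pinky-side). The canonical hand
scheme counts 22 primary (5 digit tips, 8 finger DIP/PIP joints, 1 thumb
interphalangeal joint, 5 MCP joints, palmar and dorsal palm centers, wrist
base) and 32 accessory (28 segment width markers, 2 wrist junctions, 2 palm
width markers) — 54 in total. Canonical landmark *names* are this package's
own convention (digit initial + joint slot, with the thumb's single
interphalangeal joint in the `dip` slot so suffix handling stays uniform);
annotation tools in the wild do not agree on names, only on the scheme.

## The morph

**Whole-model alignment.** An unrestricted similarity Procrustes fit
(translation, uniform scale, orthogonal matrix with reflection permitted —
the standard SVD solution) is computed over the full matched landmark
complement and applied to mesh and landmarks; afterwards the model is
rigidly translated so its wrist anchor coincides exactly with the target's.
Reflection is allowed here because a right-hand mesh may need to match a
left-hand illustration. The fit requires at least 3 non-collinear points;
collinear configurations are rejected (the rotation about the common line
would be arbitrary).

**Segment assignment.** Temporary landmarks are interpolated along each
dependency pair at most `spacing` apart (default 5% of the anchor-to-
farthest-primary distance — scale-free, and fine enough that every finger
vertex finds landmarks of its own segment). Each vertex's primary segment
is its nearest temporary landmark's segment, ties broken toward the
earliest segment in dependency order (deterministic). Partial influence
uses an exponential falloff `w_s ∝ exp(−d_s / λ)` over the primary segment
and its dependency-linked neighbours, normalized to sum to one. The default
`λ` is 25% of each segment's parent-to-child landmark distance: falloff
should scale with local anatomy — a thumb segment and a pinky segment need
different blending widths — and a quarter segment length confines blending
to the joint region without making it a step function.

**Iterative segmented fit.** Walking the dependency list in topological
order, each `(parent, child)` pair gathers its two primary landmarks plus
all accessory landmarks sharing their base names, fits a **no-reflection**
similarity from current to target positions, and applies it to those
landmarks and to the influenced vertices. Reflection is excluded here
because an individual finger segment must never mirror; scale *is* fitted
per step, since digit proportions differ between model and illustration.
Landmark updates compose sequentially down the tree — a later pair starts
from positions its ancestors have already moved. For vertices, two
interpretations of "all vertices controllable by the pair" are defensible;
both are implemented. The default blends: a vertex's final position is the
weight-average of its images under each segment's fit (vertices on the root
segment stay put). `hard = TRUE` moves each vertex rigidly with its primary
segment. Blending is the default because it prevents tearing at the
knuckles, at the cost of slight shrinkage where weights straddle a joint.

Because each pair's fit re-targets the *current* positions, small
inconsistencies (e.g. a parent's width markers, which do not move with the
child's similarity) do not accumulate: on synthetic hands deformed by known
per-segment similarities the morph recovers target landmarks to 0.3–0.8% of
hand length (the tests assert < 1%).

## Flattening and scoring

Faces are classified by the angle between their outward normal and the
depth vector (convention: +z toward the viewer, the 2D illustration in the
z = 0 plane; nothing in the geometry fixes axes, so this is a declared
convention). Palmar is the half-open interval [0°, 90°), dorsal [90°, 180°]
— the boundary must belong somewhere, and exactly-90° faces are edge-on,
so assigning them to dorsal is an arbitrary but deterministic tie-break.
Oblique faces (strictly between 60° and 120°) stay in their palmar/dorsal
class; obliqueness of an annotation is annotated-oblique area over total
annotated area. The denominator is the annotation's own area (not the whole
map): the score describes *that annotation's* visibility in a flat
projection.

Flattening zeroes the depth component of every vertex. Occlusion is
deliberately **not** resolved: overlapping same-aspect faces all rasterize,
so the mask records the union silhouette — exactly what a flat drawing of a
curled or self-occluding surface shows. Rasterization sets a pixel when its
center lies inside or on the boundary of an annotated projected triangle
(pixel-center sampling, no anti-aliasing, matching binarized 2D annotation
maps; boundary tolerance scales with coordinate magnitude). The Jaccard
index of two masks on the same grid is intersection over union; two empty
masks score 0 by convention, since no spatial agreement is demonstrable.

## Cross-mesh transfer

After both meshes are in a common frame (typically source morphed onto
target), each target face takes its k nearest source faces by centroid
distance (k-d tree; centroids stand in for "face location" everywhere —
the one-point summary of a triangle). All vertices are re-zeroed at the
target face centroid and rotated so the target normal points along +z
(Rodrigues construction; the antiparallel case rotates 180° about x);
source vertices have z zeroed, giving the perspective view of the source
along the target normal. Each source face's clipped overlap with the
projected target face, divided by target face area, is its proportional
coverage, written to **every (target-vertex, source-vertex) combination**
of the two faces and accumulated additively across faces sharing an entry.
The per-entry value is the full coverage `p` (not `p/3` or `p/9`): full-`p`
makes the threshold arithmetic exact — a face 50% covered with all 3 source
vertices annotated sums to 3 × 0.5 = 1.5 per target vertex, and the
inclusive threshold `s ≥ 1.5` is the annotation rule. The default k is
max(30, ⌈30 · source faces / target faces⌉): 30 at the typical 1:1 retopo
ratio, scaled up when the source is denser so the neighbourhood still
covers the target face, never scaled below 30.

Back-facing source faces are kept (proximity is the only filter) because
annotations must cross silhouette folds on retopologized scans; a
`filter_backfacing` flag exists for heavily folded geometry. Whether source
faces *behind* the target surface should be excluded is not decidable from
first principles; proximity-only is the implemented behaviour. Hotspots and
quality descriptors are not resampled by the matrix — qualities are copied
verbatim, hotspots only travel with the mesh through the morph.

One behavioural consequence worth knowing: on self-transfer (identical
meshes) the threshold rule reproduces an annotated patch *plus* the faces
whose vertices all touch it — a vertex just outside the patch already
accumulates ≥ 2 from two incident half-annotated faces. The tests pin this
down against a combinatorial oracle on a sphere, where only a face's own
projection covers it.

## The synthetic generator

`make_hand()` emulates the study conditions — an articulated right-hand
mesh carrying the full 54-landmark scheme and its dependency tree — at toy
scale: a palm plate with four fingers and a tilted thumb, each digit a
chain of tapered segments with rounded tips, built as an extruded silhouette
(ear-clip triangulated, 0.008·width boundary bulge so no three boundary
points are collinear) into a closed genus-0 manifold. Width markers sit on
the silhouette edge halfway along each segment, i.e. on the dorsoventral
midline. Default proportions (palm 1.3 × 1.0 × 0.25, digit lengths 0.85–1.2
model units) approximate a human hand; the defaults produce 276 vertices
and 548 faces, enough to exercise every algorithm while keeping the full
suite under half a minute. The generator is a pure function of its spec.

`make_2d_reference()` stands in for illustration landmarks: flatten to
z = 0 and perturb each digit segment by a similarity about its parent joint
(default draws: rotation uniform on ±6°, scale on [0.95, 1.05], palm and
MCP segments rigid — the magnitude of pose differences one sees between a
neutral drawn hand and a relaxed 3D model), applied hierarchically and
returned as a record for recovery tests. `make_patch_field()` grows a
connected patch by shortest paths over the face-adjacency graph weighted by
centroid distances — a deterministic geodesic approximation adequate at
test scale.

What the generator does **not** emulate: scan noise, non-manifold defects,
photogrammetry artifacts, realistic finger cross-sections, or human
annotation variability. Tests passing on these fixtures validate the
geometry pipeline, not robustness to dirty scans (meshes are expected to
have been cleaned and retopologized upstream).

## Numerical choices and degenerate inputs

* Degenerate faces (area < 1e−12) are dropped at load with a warning; the
  vertex set is untouched so stored annotation indices stay valid.
* OBJ coordinates are written with 17 significant digits, so text
  round-trips reproduce doubles exactly; GLB stores float32 (the format's
  native precision).
* GLB import accepts exactly one mesh primitive — multi-primitive files are
  rejected loudly rather than silently merged.
* Clipped polygons with area < 1e−12 contribute zero coverage; clipping is
  Sutherland–Hodgman against the (convex) target triangle with orientation
  normalized first.
* `rotation_to_z` treats |cos| within 1e−12 of ±1 as the parallel /
  antiparallel special cases.
* Procrustes rejects < 3 points and collinear configurations (second
  singular value < 1e−9 relative).
* k larger than the source face count is clamped with a warning rather than
  erroring, so tiny toy constructions still run.

## Problem sizes

The test suite builds all fixtures in code: the 548-face synthetic hand,
spheres up to ~2.6k faces for transfer identity, a 10,800-face cylinder for
the obliqueness limit (facet columns aligned with the 60°/120° band so
discretization does not straddle the threshold), 500-pixel-wide rasters for
area convergence, and 1,000 random configurations for the Procrustes
recovery and no-reflection properties. These sizes were chosen as the
smallest at which each asymptotic claim is comfortably observable.

## Known limitations

Segmented Procrustes is piecewise-similarity, not a smooth warp: it cannot
represent bending *within* a segment, and heavily flexed poses leave
residual misfit that a thin-plate spline would absorb. Transfer assumes the
morph has brought corresponding anatomy into proximity; a bad landmark set
degrades transfer silently. Obliqueness depends on the declared depth
vector, not on any estimated camera. The CLI is single-process plumbing
around the package functions; survey administration (interactive painting,
streaming, session management) is out of scope.
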