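---
title: "Morphometry of lobula plate tangential cells: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Morphometry of lobula plate tangential cells: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lptcmorph)
```

The lobula plate of the fly optic lobe is organized into four
direction-selective layers, with layer 1 the most anterior. Its wide-field
tangential cells (the horizontal-system HS cells, the centrifugal CH cells,
the vertical-system VS cells and smaller VS-like cells) are reconstructed in
serial block-face EM volumes as *skeletons*: node-and-edge tracings of each
neurite's centreline, with a per-node diameter annotation where volume
estimates are needed. This package implements the quantitative machinery
around such reconstructions — skeleton I/O, geometry, a layer model of the
plate, axon–axon contact estimation, and image-tile montaging — together
with synthetic generators that provide ground truth for every stage, so the
whole pipeline is testable without an EM volume.

All internal coordinates are nanometres. The convention is `x` =
mediolateral (the slicing axis, lateral face at 0), `y` = dorsoventral,
`z` = anteroposterior; functions that depend on it take an `axis` argument.
Slices are cut at 25 nm, so `slice_to_depth()` maps a slice index to
micrometres from the lateral end; the printed start-plane depths in the
source data are these products rounded up to whole micrometres.

## Skeletons: formats, resampling, volume

`read_nml()`/`write_nml()` handle the KNOSSOS/webKnossos XML dialect
(positions and radii stored in voxels; converted with the file's `scale`
element, radii by the in-plane scale). `read_swc()`/`write_swc()` cover the
classic rooted-forest format (micrometres, radius column), and
`export_hoc()` writes section-based morphology scripts, one section per
unbranched run. Reconstructions made in two sub-datasets split along the
slicing axis are joined by `merge_parts()`: free endpoints within a
tolerance of each other across the seam get a bridging edge; an endpoint
with several candidates raises an error rather than guessing, mirroring the
manual correspondence step such data requires. The tolerance is exposed as
a parameter (default 500 nm) because no canonical value exists.

`resample_max_spacing()` normalizes a skeleton to a maximum internode
distance (default 400 nm) by splitting each edge of length $L$ into
$\lceil L/400\,\mathrm{nm} \rceil$ equal colinear sub-edges with linearly
interpolated radii. Original nodes stay fixed, cable length is conserved
exactly, and the operation is idempotent. After resampling, node counts are
proportional to cable length, which is why the layer histograms below count
nodes.

Neurite volume uses a frustum model: each edge contributes
$\tfrac{\pi}{3} L (r_1^2 + r_1 r_2 + r_2^2)$. Overlap at branch points is
*not* corrected; the model is therefore accurate in the regime where radii
are small relative to branch spacing, and the test suite validates it
against an independent fine-voxel counting oracle (20 nm grid, agreement
within 2%) on trees in that regime. Thick, densely branching neuropil would
be overestimated. The soma is excluded by flagging nodes whose comment
contains `"soma"` (case-insensitive) — the interchange formats carry no
structured soma marker — and `largest_component()` selects components by
cable length, not node count, which is robust to uneven annotation density.
Cells at least 500 μm³ in volume are classified as large VS-type candidates;
the comparison is inclusive (≥) to avoid floating-point equality
pathologies at the threshold.

## The layer model

The plate is modelled from an expert outline skeleton. `split_outline()`
separates the outline points into anterior and posterior sets — by label if
present, otherwise by the sign of the residual against a least-squares
quadratic mid-surface (a coplanar point cloud is rejected as degenerate).
`build_layer_model()` interpolates each side into a surface
$z = f(x_{ml}, y_{dv})$, piecewise linear over the Delaunay triangulation
of its support points: linear interpolation adds no invented curvature,
reproduces planar outlines exactly, and its error on a gently curved slab
is bounded by the support spacing (the tests verify < 5% thickness error
with 200 points over a 100 μm plate). The *footprint* is where both
interpolants are defined (intersection of the convex hulls); thickness must
be positive there, and crossing surfaces are reported as an error with a
location.

Every node with (ml, dv) inside the footprint gets a normalized depth
$d = (z - a)/(p - a)$, evaluated by vertical projection onto the two
surfaces (the simplest reading of projecting into the model; closest-point
projection would differ only where the plate is strongly tilted). The
plate is quartered into layers 1–4 with half-open bins
$[0, .25), [.25, .5), [.5, .75), [.75, 1]$; $d = 1$ belongs to layer 4, and
the bin edges are a tie-break convention since no canonical choice exists.
`layer_histogram()` reports node-count fractions over six bins (four layers
plus anterior- and posterior-of-plate); with resampled input this is a
cable-length proxy, and an optional `weights` argument allows exact
cable weighting. `depth_boxplot_stats()` first drops depths outside
$[-0.5, 1.5]$ (nodes further than 50% of the thickness outside the plate),
then computes Tukey five-number statistics: hinges by the midpoint rule
(`fivenum()`), whiskers at the most extreme values within 1.5 IQR. Other
quartile rules differ by a fraction of an internode spacing at these sample
sizes.

## Contact analysis in the axonal tract

Contacts between the medially running axons are measured on a voxel
representation, by default over the 86–203 μm depth window where the tract
runs:

1. `voxelize()` rasterizes each resampled, radius-annotated skeleton as a
   capsule sweep onto an isotropic 140 nm grid; a voxel claimed by two
   different processes stays background, so labels are disjoint from the
   start.
2. `close_labels()` applies a morphological closing (2 rounds of dilation
   then erosion with the 3×3×3 cube, i.e. 26-connectivity) to each label
   independently, bridging small rasterization gaps; disjointness is then
   re-enforced. Per-label closing is chosen over closing the union because
   the union variant can weld near-touching processes together.
3. `constrained_dilate()` grows all labels simultaneously for 7 sweeps.
   Each sweep dilates every label into background only; a background voxel
   reachable by two or more labels in the same sweep is *contested* and
   stays background permanently. The synchronous update with permanent
   ties makes the result independent of label numbering (sequential growth
   in label order would not be), and the implementation is validated
   voxel-exactly against a naive per-sweep oracle. Seven sweeps give a
   growth reach of ~0.98 μm: the scale within which two axons are
   considered apposed.
4. `contact_area()` dilates one label once more (others frozen) and counts
   its overlap with each other label; dividing by 51 voxels per μm² — the
   reciprocal face area of a 140 nm voxel, $1/0.14^2 = 51.02$, rounded to
   the integer used in the original procedure — converts counts to areas.
   `exact_face_area = TRUE` selects the unrounded divisor.
   `contact_matrix()` symmetrizes the two directed measurements by their
   mean and flags zero-area pairs for manual review.

The cube structuring element makes the growth metric Chebyshev, not
Euclidean: reach along a diagonal is larger in Euclidean terms. A known
limitation is that for processes separated by a gap (no wall contact), the
measured "area" comes from the growth-front fringe on the equidistant
bisector, where whether the final one-voxel dilation reaches the other
label depends on the odd/even voxel parity of the local gap. Such values
are resolution-dependent and should be read qualitatively; areas between
processes in actual wall contact are adjacency-dominated and stable (the
tests check consistency between 140 nm and 70 nm grids in that regime, and
linear scaling with interface length). Labels closer than ~2 voxels to the
array boundary can lose voxels during closing; `voxelize()` pads its
bounding box so the default pipeline never operates near the edge.

## Tile montage alignment

SBEM mosaics are stitched from overlapping tiles by translation only (no
rotation or scale, matching the acquisition geometry). `measure_shift()`
scores candidate displacements around the nominal grid offset by the
normalized cross-correlation of the overlapping pixels — zero-mean,
unit-variance, hence robust to block-face brightness drift — and reports
the argmax plus a peak-sharpness score: the peak value divided by the mean
absolute correlation in a ring (Chebyshev radius 2–4 px) around it. The
score separates genuine from chance correlations only when the image
texture decorrelates within the ring radius, which holds for fine-grained
EM texture. The default acceptance floor of 6 is the 99th percentile of
the score on 100 independent-noise pairs (`calibrate_quality_floor()`),
rounded up.

`reweight_shifts()` multiplies weights by a Huber-style factor
$\min(1, \text{tol}/\|\text{shift} - \text{expected}\|)$ (so a deviation of
twice the tolerance halves the weight), zeroes measurements whose peak
quality is below the floor, and rejects outright anything deviating more
than 5 tolerances — a linear down-weight alone would still let a gross
mismatch drag the solution by several pixels. `solve_layout()` then
minimizes $\sum w_{ij}\|(p_j - p_i) - s_{ij}\|^2$ as two decoupled sparse
weighted least-squares systems (exact for pure translations), anchoring the
first tile at the origin to fix the gauge; it is exact on consistent
measurements and reports per-measurement residuals. One
reweight-then-re-solve pass is the default (`align_tile_grid()`), with the
iteration count configurable. `z_only_stack()` covers stacks whose lateral
alignment is done manually: nominal positions, slice order only.

## Synthetic data: what it emulates, what it does not

The generators provide machine-readable ground truth and are deterministic
given a seed.

* `gen_plate_outline()` samples side-labeled points on two analytic
  surfaces (a sinusoidally corrugated slab, amplitude 5 μm over a
  100 × 100 μm extent, thickness 20 μm by default — the scale of the fly
  lobula plate) and returns the closed-form surfaces for oracle use.
* `gen_tangential_cell()` grows a branched random walk whose cable is
  placed layer by layer to match prescribed per-layer fractions (bands are
  kept 3% of the thickness clear of the bin edges so that edge-crossing
  smearing stays within the ±0.02 recovery tolerance), appends a
  medially-running axon leaving the plate and a soma-flagged stub, and
  reports the realized fractions measured analytically against the
  generating surfaces. Default 5 mm of cable at 0.4 μm dendrite radius —
  a large-tangential-cell scale. It makes no attempt at biophysically
  realistic branching statistics; it provides controlled depth occupancy,
  nothing more.
* `gen_axon_bundle()` emulates the axonal tract: tubes with radii drawn
  from 1.0–1.5 μm rest on a ring (default radius 7.5 μm) in the
  cross-section and meet pairwise, slot by slot along the tract, in slight
  wall overlap; one designated pair is never scheduled, sits on opposite
  sides of the ring, and is the constructed zero-contact pair. Because
  every meeting happens near the bundle centre, tubes dipping in nearby
  slots come within the contact method's growth reach of each other even
  unscheduled; the schedule therefore groups the slots of the two omitted
  tubes at opposite ends of the tract with at least three slots between
  the blocks. The truth table reports each pair's minimal wall-to-wall gap
  from the generating curves and classifies pairs as touching (gap ≤ 0)
  or expected-zero (gap > 2.6 μm, just above the 7 + 7 + 1 voxel reach of
  the default measurement).
* `gen_tile_grid()` crops a band-limited noise texture into an overlapping
  tile grid at integer-jittered true positions and adds per-tile intensity
  noise. Real mosaics also show brightness gradients, focal drift and
  charging artifacts; none of that is simulated, so passing alignment
  tests demonstrate correctness of the estimator, not robustness to every
  acquisition pathology.

Passing parameter-recovery tests on these generators shows that the
analysis chain inverts the generative model it was pointed at — including
unit handling, bin conventions and geometry — not that it would be free of
bias on real annotation error patterns (human mis-tracings, redundant
tracing consensus, diameter annotation noise), which are out of scope here.

## Problem sizes and numerical choices

The test and reproduction runs use desk-scale problems chosen to exercise
every code path at full fidelity: 5 mm synthetic cells (≈ 15,000 resampled
nodes) for layer recovery, a 9-tube braid of ~86 μm (≈ 1.5 × 10⁷ voxels at
140 nm) for the contact chain, 4 × 4 tile grids of 128² px tiles at jitter
σ = 2 px for alignment, and 20 nm voxel grids for the volume oracle. The
voxel budget guard in `voxelize()` (default 2 × 10⁸ voxels) exists so a
mis-specified window fails fast rather than exhausting memory.

Remaining conventions: depth evaluation returns `NA` outside the footprint
and such nodes are excluded from all layer statistics; histogram fractions
are over in-footprint nodes only; `merge_parts()` renumbers the medial part
with a power-of-ten offset and keeps an id map; morphological operations
use separable three-pass min/max filters (exact for the cubic element);
and all RNG use is confined to the generators through an explicit seed.
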