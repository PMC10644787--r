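---
title: "Automatic anatomical coordinate systems for foot and ankle bones"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automatic anatomical coordinate systems for foot and ankle bones}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(footacs)
```

## The problem

Kinematic and morphological studies of the foot and ankle — weightbearing CT,
biplane fluoroscopy, surgical planning — need an anatomical coordinate system
(ACS) attached to each bone: an origin plus orthonormal medial–lateral (ML),
anterior–posterior (AP) and superior–inferior (SI) axes. Manual landmarking
is slow and rater-dependent; fitting geometric primitives oversimplifies
irregular tarsal bones; pure inertia axes are not anatomical. `footacs`
assigns ACSs automatically to surface meshes of the fourteen major foot and
ankle bones (tibia, fibula, talus, calcaneus, navicular, cuboid, three
cuneiforms, five metatarsals), in any scanner pose and either laterality,
and provides the comparison metrics needed to validate such assignments.

## The procedure

For each bone the pipeline is:

1. **Laterality.** Right-side bones are mirrored across the sagittal plane
   (`x -> -x`, winding reversed) so that a single left-side template per bone
   suffices. The arbitrary mirror plane is absorbed by the rigid
   registration that follows.
2. **Template alignment.** The bone is rigidly registered to a pre-oriented
   template whose frame is, by construction, the canonical anatomical frame:
   medial +x, anterior +y, superior +z. Registration is initialized by
   matching principal axes of area-weighted surface samples and refined by
   point-to-surface iterative closest point (ICP); rotation and translation
   only, never scale, since subject and template share physical units and
   scaling would distort the region extents used below.
3. **Volumetric regions.** In the aligned frame the bone is partitioned into
   equal-width slabs along each anatomical plane: 3 slabs per plane for the
   talus, cuneiforms, metatarsals, tibia and fibula; 5 for the navicular and
   cuboid; 10 for the calcaneus. Slab centroids are means of area-weighted
   surface samples (20,000 by default, seeded), which makes them insensitive
   to tessellation density and usable on open (cropped) meshes.
4. **Axes.** The *primary* axis joins the centroids of the two extreme slabs
   along the bone's characteristic plane — ML for the navicular and the
   tibiotalar talus, SI for the tibia and fibula, AP for everything else. A
   *third point* (the most superior slab centroid, or the most lateral one
   for tibia and fibula) is projected orthogonally onto the primary line;
   the unit vector from the projection toward the third point is the
   *secondary* axis, and the *tertiary* axis is their cross product. The
   three axes are relabeled ML/AP/SI per bone, sign-corrected toward the
   template's +x/+y, and SI is recomputed as `ML x AP` so every reported
   frame is right-handed to 1e-9.
5. **Origin.** Either the area-weighted surface centroid (`bone_center`) or
   the first intersection of a ray from that centroid along the joint
   direction of the chosen variant (`joint_surface`), e.g. anterior for the
   talonavicular and calcaneocuboid variants, superior for the tibiotalar
   one.
6. **Both spaces.** The frame is reported in the aligned space and mapped
   back to the bone's original scanner space; the output table carries both.

Joint-specific variants (three for the talus, two for the calcaneus) are
separate templates with their own rules, giving 17 bone/variant coordinate
systems in total.

### Right-side frames

Mapping an aligned-space frame back through a mirrored registration reflects
the axes, which would leave a left-handed triad. We restore right-handedness
by flipping the reported ML axis, the usual side-specific sign convention:
for right bones, +ML reads lateral. Comparisons between sides are made in
the shared aligned (leftified) space, where the convention plays no role.

## Alignment details

* **Initialization.** Principal axes of 2,000 area-weighted surface samples
  are matched to the template's. Eigenvectors are defined only up to sign,
  and when two spreads are within 10% of each other their order and
  in-plane mixture are essentially arbitrary (a near-square calcaneus
  cross-section, for instance), so the candidate set contains every proper
  sign assignment and every permutation exchanging near-degenerate axes.
  Each candidate is polished by a 20-iteration ICP burst on a 500-point
  subsample before the RMS comparison; without that polish, genuinely
  different poses of an almost-symmetric bone are indistinguishable at the
  coarse stage. Shapes whose two spread ratios both exceed 0.98 fall back to
  a centroid-only translation and flag low confidence.
* **ICP.** Each iteration computes closest points on the template (a
  uniform-grid accelerated exact query, implemented in C++), then evaluates
  two candidate pose updates: the Kabsch point-to-point optimum and a
  linearized point-to-plane step. The better one (by the RMS point-to-surface
  residual) is kept. The Kabsch optimum can never increase the residual, so
  the recorded residual history is monotonically non-increasing, while the
  point-to-plane step converges fast near the optimum. Iteration stops when
  the improvement falls below 1e-4 mm (default) or at 100 iterations.
* **Determinism.** Every sampling step takes an explicit seed and restores
  the caller's RNG state, so batch outputs are byte-identical under a fixed
  seed.

## Partial bones

Scanner fields of view frequently crop the tibia, fibula and metatarsals.
When the subject's extent along its primary axis, estimated after the
provisional alignment, falls below 0.6 of the full template's extent, the
partial-length template (distal half) is used instead; below 0.3 a warning
is attached because so little geometry makes the slab construction
unreliable. Both thresholds are arguments of `select_template()`; the values
are package choices, chosen so that a typical distal-third tibia scan takes
the partial route while near-complete bones do not.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `n_surface_samples` | 20,000 | points | slab centroids; Monte-Carlo error well under 0.1 mm |
| `icp_sample_count` | 2,000 | points | registration samples |
| `max_iterations` | 100 | – | ICP budget |
| `tolerance` | 1e-4 | mm | ICP improvement threshold |
| vertex merge | 1e-9 | mm | collapses format-duplicated vertices on load |
| partial switch / warning | 0.6 / 0.3 | ratio | cropped-bone template choice |

## The synthetic bone generator

Real bone meshes and population templates cannot ship with the package, so
every claim is validated on synthetic bones with known ground truth. A bone
is a star-shaped radial surface: a superellipsoid with per-bone semi-axes
(millimetre scale chosen to match adult anatomy, elongated along the bone's
primary plane) plus three Gaussian bumps. The bumps are the load-bearing
design element:

* they break every mirror symmetry, so all 24 axis-to-axis registrations of
  the base ellipsoid are distinguishable and the anatomical frame is
  unambiguous;
* no bump maps near another under any 180-degree flip, and their amplitudes
  and widths differ, so wrong registration basins retain a clear residual;
* they sit near the equator of the SI axis, keeping the extreme-slab
  centroids close to the canonical axes — the ground truth of a generated
  bone is the identity frame of its canonical pose, and the slab
  construction must be able to reproduce it.

Blockier bones (calcaneus exponent 4, navicular and cuboid 3, others 2.5)
get flatter superellipsoid ends, which keeps the thin extreme slabs (one
tenth of the extent for the calcaneus) well populated the way real
tuberosities and facets do.

The generator also produces: canonical templates for all 17 bone/variant
pairs (written in the template directory layout, partial variants included);
"re-segmentation" twins (radial remeshing to a chosen face-count factor plus
surface-normal noise, ground truth unchanged); and populations in which
group mean shapes differ by seeded bump-amplitude offsets, individuals
jitter around their group mean (1.5% semi-axis scatter, 0.3 mm bump scatter,
random pose), and correspondence particles sit at fixed parametric
directions so index *k* marks the same relative location on every shape.
Group means are generated directly rather than averaged from individuals;
statistical shape-model mean computation is out of scope.

What the generator does **not** emulate: genuinely anatomical cortical
detail, articular facet geometry, pathology-specific deformity, or the
entropy-optimized particle distributions of shape-modeling pipelines (our
particles are quasi-uniform Fibonacci directions). Tests passing on these
shapes demonstrate the correctness and robustness of the construction — not
clinical accuracy on patient data, which requires real templates built from
a real population.

## Evaluation metrics

`angle_difference()` compares two frames axis-by-axis in a shared space,
direction-sensitively — a flipped axis reads near 180 degrees on purpose,
because sign conventions are already enforced at assembly, so a large
reading is a failure signal, not a wrap-around artifact. Comparisons are
made in the shared template-aligned frame, the only frame common to bones
from different scanner spaces. `correspondence_distance()` projects each
axis from the origin to the surface, finds the nearest correspondence
particle on the reference shape, and measures the distance to the
same-index particle on the target shape. Group comparisons use the classic
equal-variance one-way ANOVA and Tukey's honestly-significant-difference
post hoc (`stats::oneway.test`, `stats::TukeyHSD`, studentized-range
quantiles from `stats::qtukey`); summary tables report sample SD (n − 1).
Angle-difference summaries treat the three axes as separate observations
and also report per-axis columns, since either pooling convention is
defensible.

## Numerical choices and degenerate inputs

* Slabs are half-open `[b_i, b_{i+1})` except the last (closed); empty slabs
  raise an error naming the axis rather than silently producing a shifted
  centroid.
* Coincident extreme centroids (< 1e-6 mm) and third points on the primary
  line (< 1e-6 mm perpendicular distance) are degenerate-geometry errors.
* The anchor point of the primary line is the midpoint of its two extreme
  centroids; any point on the line gives the same secondary axis, the
  midpoint is simply symmetric.
* Frames are re-orthonormalized by polar decomposition (SVD) after space
  mapping; all ACS invariants are enforced at 1e-9, mapping round trips at
  1e-12.
* An assembled frame whose SI axis points inferior after sign correction
  aborts with an alignment/laterality error — it cannot arise from a sane
  registration.

## Problem sizes used in the tests

The test-suite geometry is deliberately desk-scale: bones are triangulated
at roughly 1,300 faces (650 vertices), templates likewise, and the
validation experiments span all 17 bone/variant rules — around 200
randomized assignments for frame validity, 20 bones times 5 poses for rigid
invariance, 20 left/right twins, 51 ground-truth recoveries at 0 and 0.2 mm
noise, and ten repetitions of a 3-group-by-8-bone segmentation-twin
experiment with remeshing and 0.2 mm surface noise. These sizes give stable
statistics while keeping the whole suite fast on a single CPU; all of them
scale up by changing `mesh_resolution` and the loop counts.

## Known limitations

* Validation is synthetic; no real templates or patient meshes are included.
* The ACS of one bone never depends on another bone, by design; articulated
  joint coordinate systems (joint angles between two frames) are a separate
  analysis this package does not perform.
* Binary output dialects are not written (ASCII STL/PLY/VTK only), though
  binary STL and PLY are read.
* The keyword-mesh reader supports only `*NODE` and `*ELEMENT_SHELL` cards;
  anything else in the file is skipped, and other cards' state lines error
  loudly rather than being guessed at.
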