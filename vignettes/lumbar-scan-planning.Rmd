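---
title: "Methods: phantom-based validation of lumbar scan-plane planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: phantom-based validation of lumbar scan-plane planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumbarplan)
```

`lumbarplan` implements the postprocessing and geometry that sit between a
disc-localization network and an MRI console: heatmap peak extraction,
anatomical disc labeling by distance-template matching, scan-plane and
saturation-band computation, and a lumbar morphometry suite with diagnostic
rules. Because those stages are purely geometric, they can be validated
end to end on a synthetic phantom whose ground truth is known analytically.
This vignette describes the models, the tunable parameters, the numerical
choices, and what the phantom-based validation does and does not show.

## The synthetic lumbar phantom

`phantom_spec()` describes a lumbar localizer scene in world RAS+
coordinates (+X right, +Y anterior, +Z head; world position of voxel
`[i, j, k]` is `origin + (index - 1) * spacing`). The anatomy is a chain of
elliptic-cylinder segments stacked head to foot: five vertebral bodies, five
discs, and a sacral base, with the spinal canal as a tube behind the bodies,
spinous-process blocks behind the canal, and two elliptic psoas cylinders
lateral to the spine.

Lumbar lordosis is modeled as a circular arc in the sagittal plane,
discretised once per level: structure *j* of the chain is a straight segment
tilted about the left-right axis by
`lordosis_angle * (j - (n + 1)) / (2 n)` degrees, so adjacent disc normals
differ by exactly `lordosis_angle / n_discs`. This keeps the ground-truth
disc normals closed-form while reproducing the key geometric property the
planner must handle — every level needs its own transverse plane.

Defaults (chosen once, from normal adult ranges): 1.5 mm isotropic voxels on
an 80 x 96 x 168 grid; disc height 10 mm, vertebral body height 27 mm
(adjacent disc centres 37 mm apart); disc semi-axes 16 mm (AP) x 22 mm (LR);
canal diameter 14 mm (measured posterior disc edge to spinous process);
foraminal height 18 mm; lateral recess 5 mm / 45 degrees; facet angle 40
degrees; psoas semi-axes 15 x 10 mm; total lordosis 40 degrees; Gaussian
intensity noise with sd 5 on class-mean intensities. Pathology is planted by
deforming the specification — a narrowed canal, a shallow recess, a
posterior half-ellipsoid disc bump — never by editing voxels, so the
analytic truth stays exact. A rigid pose (rotation about the volume centre
plus translation) emulates patient positioning variation.

**Rasterization.** Each structure is rasterized by sampling the eight
half-voxel subcell corners plus the voxel centre and assigning the label on
a 5-of-9 majority. On a locally straight boundary this reduces exactly to
the unbiased midpoint rule (the corner pairs cancel), while the corner
samples stabilise thin or strongly curved structures; rasterized psoas
cross-sections land within about 1% of the analytic `pi * a * b` at 1.5 mm
voxels. A plain 8-corner majority was rejected because it dilates edges
anisotropically (about +3% on ellipse areas).

**What the phantom does not model:** MR physics (no bias field, k-space or
sequence simulation — intensities are class means plus Gaussian noise),
transitional vertebrae and six-disc variants, non-elliptic cross-sections,
and degenerative shape change beyond the planted parameters. Tests passing
on the phantom therefore validate the *geometry* of the pipeline — peak
extraction, labeling, plane fitting, measurement definitions, thresholds —
not robustness to realistic image appearance, which requires a trained
segmentation model and clinical data.

## Heatmaps and losses

Keypoint targets are Gaussian fields `256 * exp(-||x - k||^2 / (2 sigma^2))`
evaluated at voxel centres in world mm, so a voxel-centred keypoint attains
the peak 256 exactly. `sigma` defaults to 6 mm: on the same scale as the
6 mm identification tolerance, and small against the 37 mm disc spacing, so
neighbouring peaks remain separable. Heat values are kept in raw units (peak
256) throughout, including in the MSE; they are not renormalised.

Candidates are strict local maxima over the 26-connected neighbourhood with
heat above a threshold (default 128, half peak). Plateaus are resolved
toward the lowest linear index, making extraction deterministic; the
implementation is checked against a brute-force exhaustive scan on random
volumes.

The focal loss uses `p_t = p` where the voxel label is the positive class
and `1 - p` otherwise, and `FL = -(1 - p_t)^gamma log(p_t)` with gamma = 2
by default. Only `p_t <= 0` is clamped (at 1e-7): the loss is finite and
exactly zero at `p_t = 1`, and with gamma = 0 the implementation agrees with
an independently coded cross-entropy to 1e-12. Dice of two empty masks is
defined as 1 (perfect agreement of absent structures).

## Disc labeling

The distance template `T(i, j)` holds empirical inter-disc centre distances.
The default is parametric — 37 mm between adjacent centres, longer ranges
composed as chord lengths of the lordosis arc — and fully overridable with a
measured matrix. Matching minimises
`sum over unordered pairs i < j of |D(c_i, c_j) - T(i, j)|` over injective,
head-to-foot ordered assignments of pooled candidates to labels. Pooling
across channels means a network that swapped two channel outputs is still
labeled by spatial order. Design choices worth stating:

* The number of assigned labels is maximised first (`min(d, n_candidates)`),
  then the error minimised — otherwise assigning nothing would trivially
  minimise the sum. Unmatched labels are reported MISSING.
* The search is a depth-first branch-and-bound over order-preserving
  injections; its result is verified against exhaustive enumeration (200
  randomized instances, up to 6 levels and 3 candidates per channel) in the
  test suite.
* The caudal reference (L5/S1) rule — most caudal candidate above threshold,
  Z-ties broken by heat — is exposed as `find_reference_disc()`; the
  matcher itself reports the caudal end of the optimal assignment as the
  reference rather than hard-anchoring it, so the returned assignment is
  always the global minimum.
* The matching error depends only on pairwise distances, hence is invariant
  under rigid motion of all candidates (tested to 1e-9 mm).

Label fusion assigns each connected component of the generic disc
segmentation to the nearest assigned candidate within a 15 mm gate (about
half a vertebral height); conflicting claims are resolved by proximity and
the loser demoted to unlabeled. Vertebra labels are inferred from the
flanking discs. A disc counts as *identified* when the nearest truth
centroid carries the same label and each per-axis error is strictly below
6 mm.

## Scan planning

Per-disc transverse planes take the principal axis of the disc mask closest
to the head-foot direction as normal (sign toward +Z) and the posterior edge
point as centre, defined as the centroid of the most-posterior 5% of
mid-disc voxels — a single extreme voxel would be noise-sensitive. A
near-isotropic mask (variance ratio below 1.05) falls back to the +Z normal
with a warning. The sagittal and coronal planes share the total-least-squares
line through the disc centres (first principal component) and are centred at
their centroid; if the long axis degenerates onto +Y the planes fall back to
the world axes. The saturation band is a slab normal to the coronal
direction whose near face sits `offset` mm (default 10) anterior of the most
anterior disc voxel, with default thickness 30 mm; placement fails loudly,
reporting the maximum feasible offset, rather than silently clipping.

The quality factor is defined here as
`(n_present / n_total) * exp(-mean |d_i - t_i| / t_i)` over adjacent
assigned disc spacings `d_i` against template spacings `t_i`. It is 1
exactly when all spacings match and no disc is missing, decreases
monotonically with spacing deviation and missingness, and is bounded in
[0, 1] — the properties required of a reliability score that combines
spacing information and tracks labeling uncertainty inversely. The exact
functional form is this package's choice.

Display slices are trilinear resamplings of the intensity volume on the
plane's in-plane grid at native spacing; out-of-volume pixels are zero and a
coverage fraction is attached. The "best display" sagittal/coronal images
are defined as the fitted long-axis planes.

## Morphometry and diagnosis

Measurements operate on per-level landmark sets (ground truth or an
extraction routine), decoupling measurement definitions from segmentation
quality; the two area-based quantities (psoas cross-sectional area,
herniation ratio) count labeled voxels. "Vertical" distances are projections
onto the level's own head-foot axis — the pose- and curvature-corrected
direction a radiologist reads on a correctly planned sagittal image — so a
10 mm disc measures 10 mm regardless of tilt. Canal diameter is the
Euclidean distance from the posterior disc edge midpoint to the spinous
process midpoint.

The MSU-style herniation classification grades the apex depth against the
intra-facet line (under 50% of the margin-to-line distance: grade 1; up to
the line: grade 2; beyond: grade 3) and zones the apex laterally along the
line (central two quarters A, outer quarters B, beyond the endpoints C).
The 50% increments and quarter partition are this package's
operationalisation of the published grade/zone scheme.

Diagnostic thresholds are strict inequalities with boundary values negative:
canal stenosis below 10 mm, lateral recess stenosis below 3 mm height *or*
below 30 degrees angle. The angle direction is configurable
(`recess_angle_direction = "less"` or `"greater"`) because the source
literature states both conventions in different places; the default follows
the results-section convention (angle below 30 degrees indicates stenosis).
Missing measurements yield `NA` (indeterminate), never a silent negative.

## Validation design and problem sizes

The acceptance-style checks run on a 50-phantom cohort at the default grid
(1.07M voxels per label volume), with total lordosis drawn uniformly from
15-37 degrees (per-disc tilts up to about 15 degrees), 1 mm Gaussian jitter
on the disc-centre candidates used for line fitting, and pathology planted
deterministically in exactly 20% of phantoms per condition (a seeded
permutation, not Bernoulli draws, so detection rates must match prevalence
exactly). On this cohort the planned transverse normals recover the true
disc normals to a mean error well under 1 degree (max under 1 degree at zero
pose), landmark-based measurements recover the analytic truth to machine
precision, rasterized psoas areas to about 1%, and the per-disc planning
beats a single global axial orientation (the manual-operator baseline) by a
factor of 30 or more in mean offset angle whenever lordosis is nonzero.
Template matching agrees with exhaustive enumeration on all randomized
instances tested. The brute-force matching oracle is kept to 6 levels and 3
candidates per channel, where enumeration is exact and fast.

Two known resolution effects are documented rather than hidden: at 1.5 mm
voxels the *ratio* of left/right psoas areas compounds two alignment errors
and can drift to about 2.5% in the worst edge-aligned configuration (the
ratio property is validated on a 1 mm phantom, the per-area 2% bound on the
default grid); and the herniation ratio measured on axial voxel slices
differs from the analytic in-plane value by a few percent for strongly
tilted discs.

## Limitations

The pipeline's clinical performance claims (segmentation Dice, clinical
identification rates, detection rates in patient cohorts, reader agreement)
cannot be reproduced here: they require a trained network and clinical
images. What this package establishes is that every deterministic stage
downstream of the network — and every measurement and threshold rule — is
implemented to specification, with exact geometry to test against.
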