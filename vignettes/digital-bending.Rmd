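---
title: "Digital bending of intervertebral joints: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital bending of intervertebral joints}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vertebend)
```

## The model

`vertebend` estimates osteological range of motion (oROM) by constrained
rigid-body rotation. A motion segment holds a fixed anterior vertebra, a
mobile posterior vertebra, a joint frame, and ten landmarks. All motion is a
rotation of the posterior body about one frame axis through the centre of
rotation (COR), optionally followed by a world translation (the relief
shift). Rotations are always composed fresh from the neutral pose — a probe
at angle θ is a single rotation by θ, never an accumulation of half-degree
steps — so no floating-point drift can build up across a sweep.

The model's central assumption is that soft tissue limits can be expressed
as bounds on geometric quantities referenced to the neutral pose:

* **Bony intersection.** The overlap of the two solids is measured as the
  surface area of their boolean intersection; motion stops when it exceeds
  `intersection_threshold` × mean vertebral surface area. A small nonzero
  threshold exists because tightly fitting joints slide across one another
  and slight mesh unevenness would otherwise stop motion prematurely.
* **Zygapophyseal strain.** The craniocaudal (frame-x) component of the
  facet landmark separation, relative to its neutral value: capsular
  ligaments prevent excessive disarticulation (ventroflexion) and overlap
  (dorsiflexion).
* **Centrum strain.** The Euclidean distances of the four endplate landmark
  pairs, relative to their neutral values: annular ligaments and disk limit
  tension and compression around the centrum rim.

Strain constraints are evaluated in *all six* bending directions, not only
the directions they nominally govern; which constraint stops which
direction is an outcome of the geometry, and on realistic segments the
familiar pattern emerges by itself (intersection limits axial twist,
zygapophyseal strain limits sagittal bending, centrum strain and
intersection share lateroflexion).

Each joint is analysed independently from its own neutral pose.
[chain_segments()] composes hierarchical world poses for export and
visualisation, but chaining does not alter a single joint's admissible
angles, so per-joint oROM never depends on the rest of the column.

## Parameters and defaults

| parameter | default | units | rationale |
|---|---|---|---|
| `increment` | 0.5 | degrees | half-degree probe grid; stop angles are multiples of it |
| `max_angle` | 45 | degrees | cap for unconstrained directions |
| `intersection_threshold` | 0.005 | fraction of mean area | 0.25–0.5% both behave well; the upper value is the default, and the sensitivity design brackets it with 0.25/0.5% |
| `zyg_bounds` | (−0.5, +0.5) | strain | ~50% disarticulation/overlap reproduces cadaveric magnitudes better than 75% or 100% |
| `centrum_bounds` | (−0.5, +0.5) | strain | physiological disk strains reach ~50%; 25% is overly restrictive |
| `translation_fraction` | 0 | fraction of √area | translation has little effect when strain constraints are on, so it is off by default |

The stop angle reported is the **last non-violating** probe — the pose the
joint can actually attain — rather than the first violating one; with a
0.5° grid the two conventions differ by exactly one increment.

Translation relief, when enabled, shifts the posterior vertebra toward the
bending side, perpendicular to the rotation axis in the plane of bending
(dorsally/ventrally for sagittal bending, left/right for lateroflexion;
axial twist has no in-plane perpendicular and receives no relief). The
budget is a *total*: one relief application consumes it, is attempted at
most once per probe angle, and only when intersection is the sole violated
constraint — a strain violation is a soft-tissue limit that translation
should not be allowed to bypass.

When several constraints are violated at the same probe angle all labels
are recorded; tallies ([tally_constraints()]) resolve ties by a fixed,
configurable priority (intersection > zygapophyseal > centrum).

## The boolean backend

No general mesh-boolean library is part of the package's dependency
footprint, so the overlap measurement is implemented in two tiers:

1. **Exact half-space clipping** for convex bodies and for assemblies of
   convex pieces (what the synthetic generator emits). The intersection of
   convex solids is the polytope cut from one body by the other's face
   planes; its surface area and volume are exact. For assemblies the area
   is summed over overlapping piece pairs — exact whenever one piece pair
   overlaps, which is the usual situation near first contact, and an upper
   bound otherwise. A degenerate (zero-volume) clip, as when two solids
   merely touch, reports zero.
2. **Voxel overlap** for anything else (non-convex scan meshes, jittered
   surfaces), with pitch √(mean area)/200 so that 0.25% area thresholds are
   resolvable, a 2×10⁶-cell cap on the grid, and an exposed-face area
   estimate. Voxel results are flagged `approximate`.

"Area of the boolean object" is interpreted as the surface area of the
intersection solid; volume is recorded alongside for diagnostics, and a
configuration switch (`intersection_measure = "volume"`, referenced to
mean area^1.5) exists for sensitivity checks of that interpretation.

## The synthetic generator

[block_segment()] builds a motion segment whose every reference quantity is
known analytically: cuboid centra separated by `gap` (all four centrum
reference lengths equal `gap` exactly), the COR at mid-gap on the centrum
axis, and optional dorsal zygapophyseal tabs overlapping by
`zyg_tab_overlap` (the zygapophyseal reference length). Side-by-side tab
clearance keeps the neutral pose intersection-free while letting tabs
collide during twisting and dorsiflexion, which is how the realistic
constraint pattern arises. For tabless blocks the first-contact angle in
sagittal and lateral bending has a closed form from the 2D cross-section:
with half-gap g and half-extent c, contact occurs at
θ = atan2(g, c) + asin(g/√(c² + g²)); axial rotation of tabless blocks
never makes contact. [vertebra_segment()] adds an elliptic-prism centrum
and a neural arch for shape-realism smoke tests; it has no closed forms and
is checked against the fine-sampling oracle instead.

Seeded vertex jitter (`jitter_sd`) emulates mesh unevenness. It exists to
exercise the nonzero intersection threshold and the voxel fallback; jitter
is reproducible (same seed, same mesh) and leaves the caller's RNG stream
untouched.

What the generator does *not* emulate: curved endplates, procoelous
ball-and-socket centra, facet curvature, and the bilateral asymmetries of
real columns. Passing tests on synthetic segments therefore validate the
*engine* — constraint logic, thresholds, aggregation — not the biological
fidelity of any particular mesh; real scan meshes enter through the same
scene interface and fall back to the voxel backend where non-convex.

## Numerical choices

* Clipping uses a relative tolerance of 10⁻⁹ of the body scale for plane
  sidedness, and discards intersection polytopes below (10⁻⁶ × scale)³ in
  volume, so grazing contact counts as zero overlap.
* Sphere fitting ([fit_sphere()], the four-point COR construction) solves
  the algebraic linear system; rank or conditioning failures (coplanar or
  coincident points) are errors, never a guessed sphere. With more than
  four points it is the algebraic least-squares fit, with the RMS residual
  reported.
* Spacing is quantified as the mean of the four centrum landmark-pair
  distances (no other numerical definition of "joint spacing" is standard),
  and [adjust_spacing()] translates along frame x only, rebuilding all
  references so the adjusted pose is the new neutral.
* The zygapophyseal reference uses the absolute x-component, so landmark
  ordering cannot flip its sign; a zero reference flags the constraint
  unusable (with a warning) instead of producing division by zero.
* Balanced-design ANOVA uses sequential sums of squares via `lm()`/
  `anova()`; on balanced designs all classical SS types coincide, and
  unbalanced input is rejected by a cell-count check rather than silently
  reinterpreted. Effect sizes only; no p-values.
* The stiffness worked chain has a `"printed"` mode that rounds the force
  proxy (h·w)^{3/2} to an integer before the division — matching
  display-style arithmetic — and a full-precision default for analysis.
  `normalize_stiffness()` implements both readings of "logged and scaled by
  centrum length" (log₁₀ then divide, and divide then log₁₀) because the
  composition is ambiguous; both preserve rank order, and the mode is
  recorded in the output.

## Direction sign conventions

With the frame x-axis caudal, y dorsal, and z to the animal's left
(right-handed), positive rotation about z closes the joint dorsally
(dorsiflexion), negative rotation about y closes it on the left
(left lateroflexion), and positive rotation about x rolls the dorsal side
leftward (left axial rotation). These signs are a documented convention of
the direction table, not an assumption about specimen orientation: a scene
whose frame axes are supplied with the same anatomical meanings gets the
same direction labels regardless of how the specimen sits in world
coordinates.

## Problem sizes used in the tests

The shipped tests run entirely on synthetic segments: single motion
segments of ~10 mm vertebrae, twenty randomized tabless blocks for the
oracle-equivalence check (three directions each against a 0.01° separating-
axis sweep), and 8-variant factorials for the sensitivity checks. These
sizes keep the whole suite in the low minutes while exercising every code
path; nothing in the engine is specific to them.

## Known limitations

* No coupled-axis motions: each direction is swept independently.
* Strain bounds assume uniform soft-tissue behaviour across joints,
  directions, and species; they are user parameters precisely because that
  assumption is crude.
* The assembly boolean's area is a sum over piece pairs; simultaneous
  multi-piece contact overestimates the union's area slightly (volume is
  unaffected). General non-convex meshes get the voxelized estimate, whose
  area error is bounded by the surface roughness of a cubic grid.
* Neutral-pose articulation ("endplates parallel, facets maximally
  overlapped") is an upstream curation step; the package consumes
  articulated scenes and does not attempt automatic articulation.
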