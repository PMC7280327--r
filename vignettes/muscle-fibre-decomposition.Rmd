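---
title: "Decomposing muscle surface meshes into polyline fibres"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decomposing muscle surface meshes into polyline fibres}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(muscledecomp)
```

## The modelling problem

Musculoskeletal multibody models need a geometric representation of each
muscle's line of action. The conventional representation — a handful of
straight segments through via points — concentrates a muscle's mechanical
effect on a few points, which misrepresents muscles with broad attachments
(glutei, iliopsoas) whose moment arms vary substantially across the muscle
belly. `muscledecomp` implements the alternative: decompose the segmented
muscle *surface* into many polyline fibres, each usable as an independent
actuator, with two user dials — the number of fibres (discretization) and
the number of straight segments per fibre (path complexity).

This vignette documents the model, its assumptions, the tunable parameters,
the numerical choices, and what the synthetic test bed does and does not
demonstrate.

## Decomposition model

The decomposition operates in the *rest pose* (the pose the meshes were
segmented in) and consists of six stages.

**Attachment projection and removal.** The origin and insertion areas are
given as ordered landmark outlines fixed on bones. Each landmark is
projected to its closest point on the muscle surface (a configurable
capture distance, default 0.02 m, guards against misregistered inputs),
snapped to a mesh vertex, and consecutive landmarks are joined by shortest
edge paths. The faces enclosed by this outline (the connected component of
the cut face-adjacency graph nearest the landmark centroid) are removed,
producing a surface with two boundary loops. Each removed region must be a
topological disk; annular or disconnecting regions are rejected rather than
silently patched.

**Harmonic field.** On the open mesh we solve the discrete Laplace equation
with Dirichlet values 0 (origin boundary) and 1 (insertion boundary). The
operator is the cotangent-weight Laplacian with negative edge weights
clamped to zero. Clamping sacrifices exactness of the cotangent operator on
obtuse triangulations but guarantees an M-matrix, hence the discrete
maximum principle: field values stay in [0, 1] on arbitrary (imperfect)
anatomical meshes, which the isoline extraction relies on. On a cylinder
the solution reproduces the axial coordinate to solver precision (~1e-15),
because the cylinder is developable and the axial coordinate is linear in
the unrolled plane.

**Isolines.** For fibres of `n_segments` segments we extract
`n_segments - 1` interior contours at levels `k / n_segments`; together
with the two attachment endpoints this gives `n_segments + 1` points per
fibre, uniformly spaced in field value. Marching-triangles crossings are
chained into closed loops; a vertex whose value equals the level exactly is
perturbed by 1e-12 first, so the crossing structure is always unambiguous.
If a level yields several loops (branching cross-sections) the
largest-perimeter loop is kept with a warning — branching anatomies are out
of scope. Contours are oriented consistently (counter-clockwise about the
mean field gradient) and resampled to a fixed count (default 64,
arc-length uniform).

**Template and barycentric transfer.** Fibre architecture is described in a
unit cube: fibres run from the z = 0 face to the z = 1 face as Bezier
curves. The shipped template has parallel straight fibres seeded on a
`ceiling(sqrt(n))`-square uniform grid — the layout within the
cross-section is a package convention, as is the mean-value variant of
generalized barycentric coordinates (well-defined for arbitrary simple
polygons, exactly reproducing affine maps). Each template section (fibre
points at one level, plus the unit-square outline sampled at the contour
count) is transferred onto its contour by evaluating the fibre points'
mean-value weights on the corresponding 3D contour samples.

Index correspondence between the square outline and the contour controls
twist: the first contour is anchored at the sample of minimum angular
coordinate about the origin-to-insertion axis, and each later contour is
cyclically aligned to its predecessor by minimising the summed
point-to-point distance (reversal allowed). On a cylinder this keeps
corresponding samples within a few degrees of each other, so parallel
template fibres map to parallel mesh fibres.

**Attachment connection.** The template's end faces are mapped onto the
attachment outlines with the same barycentric machinery (outline resampled
like a contour and aligned to the adjacent interior contour). The package
*appends* endpoints rather than moving the outermost contour points; this
keeps interior points strictly ordered in field value and puts endpoints on
the surface spanned by the attachment outline, distributing them
consistently with the template (100 template fibres give 100 distinct
endpoint positions whose mean is the area centroid, enabling distributed
force application in downstream models).

**Quadratic smoothing.** Each fibre minimises
`sum ||p - q||^2 + lam * sum ||second differences of q||^2` with endpoints
fixed — a small symmetric positive-definite solve per fibre and coordinate,
hence deterministic. `lam = 1` (default, dimensionless) removes the
sampling jitter the contour/template transfer introduces without visibly
shortening fibres; `lam = 0` is the identity, and collinear equispaced
fibres are fixed points at any `lam`.

The full pipeline is deterministic: identical inputs give bit-identical
fibre sets.

## Fibre kinematics

Bones move rigidly; a ball-and-socket joint (3 rotational degrees of
freedom) connects a fixed parent to a child. The joint centre can be
estimated by the algebraic least-squares sphere fit of a bone head surface
(`fit_sphere`), which is linear, deterministic, exact on noiseless data,
and accurate well below 1% of the radius at realistic noise — an iterative
geometric fit would add cost without benefit for joint-centre estimation.
Angles compose body-fixed Z (flexion), X (adduction), Y (internal
rotation); this mirrors common hip-model conventions, and the choice only
fixes the meaning of mixed poses — single-coordinate sweeps are unaffected.

Each fibre point blends the transforms of its two nearest bones (point to
surface distance in rest pose),

`V'_i = sum_{j=1,2} w_ij (R_j V_i + T_j)`, `w_i1 = f(t) = a t^2 - (a+1) t + 1`,

with `t` the relative position along the fibre from its origin. The
boundary conditions `f(0) = 1`, `f(1) = 0` are what make the fibre's first
and last points move rigidly with their bones — asserted to 1e-12 in the
tests. The single free parameter `a` controls how quickly the origin bone's
influence fades; it is a per-muscle configuration value (shipped defaults
from visual fitting against bone penetration: psoas −0.042, iliacus −0.024,
gluteus maximus −0.042, gluteus medius 0.0). There is no objective function
for `a` in this formulation; it stays user-supplied. Because every posed
point is an affine combination of two rigid images, poses are stateless —
sweeping and returning to the rest pose reproduces the rest geometry
exactly.

A limitation inherited by this formulation: every fibre point behaves like
an always-active via point, so at extreme poses fibres can adhere to or
penetrate bone surfaces. Contact handling (e.g. position-based dynamics) is
deliberately out of scope.

## Moment arms

For fibre fans we use the tendon-excursion method: lengths are sampled on a
uniform grid (defaults: flexion −10..60°, ab/adduction −40..40°,
internal/external rotation −30..30°, step 2°, other coordinates held at
zero), fitted per fibre with a degree-4 polynomial, and differentiated
analytically. The fit is computed in radians about the grid midpoint, so
coefficients are well-scaled and the derivative is a length (metres,
reported in cm). A quartic over a ±35° window reproduces the hinge-toy
closed form to ~0.03% of the moment arm; its derivative accuracy decreases
with window span, which is why the excursion/geometric comparison below
uses a narrower smooth window.

**Sign convention.** The derivative `dl/dtheta` is positive for a muscle
that lengthens as the coordinate increases — an antagonist. We report
`r = -dl/dtheta` by default so that agonists (a flexor during flexion)
carry positive moment arms; the sign is a configuration switch and
documented wherever values are printed.

For straight-lines paths with conditional via points (active only inside a
closed angle interval — the closed-interval convention is ours), `l(theta)`
is non-smooth at toggles, so polynomial excursion is inappropriate. These
paths use the exact geometric method about the joint centre `c` and axis
`a`: with the single joint-spanning segment from child-fixed `D` toward
parent-fixed `P`, `r = a . ((D - c) x u)`. On smooth paths the two methods
agree (to ~5e-8 m on the toy over a ±10° window); at toggles the geometric
method remains exact and the package reports the toggle poses.

Fans are summarised per pose (envelope min/max over fibres) and globally
(min, max, mean, population sd over all fibre-pose samples, in cm). The
choice to average over all samples rather than over envelope bounds is a
package convention. Range agreement against a reference curve is the
percentage of poses (inclusive bounds, rounded to integer percent) at which
the reference lies inside the envelope.

## Synthetic test bed

The generators provide every input the pipeline needs at anatomy-like
scales (lengths 0.1–0.4 m, radii 0.01–0.05 m, chosen so tolerances
transfer to real anatomical data):

* `make_tube_muscle()` — watertight straight/curved/fusiform tubes with
  12-landmark attachment rings on the cap perimeters; optional seeded
  vertex jitter exercises the cleaning and smoothing paths. Closed forms
  exist for fibre lengths (straight and bent tubes), mid-belly girth and
  surface area.
* `make_two_bone_skeleton()` — fixed parent box and articulated child box
  around a ball joint, arranged so the standard tube spans from parent to
  child.
* `hinge_toy()` / `make_hinge_fixture()` — a planar two-segment toy whose
  length and moment arm have closed forms
  (`l = sqrt(a^2 + b^2 - 2ab cos)`, `|r| = ab sin / l`), the independent
  oracle for the excursion machinery.

Default problem sizes used throughout the tests and the acceptance script —
a 642-vertex tube decomposed into 100 fibres × 15 segments, 2° sweeps, 64
contour samples — run the full pipeline in a few seconds and were chosen as
the smallest sizes at which the analytic comparisons are meaningful.

What passing on this test bed shows: correctness of the geometry processing
(field, isolines, barycentric transfer), the kinematic identities, and the
moment-arm machinery against independent closed forms. What it does not
show: realistic behaviour on branching or sharply twisted anatomies
(largest-loop selection would truncate branches), robustness to
badly-degraded segmentations beyond the three repaired defect classes, or
the anatomical validity of any particular `a` — those require real
anatomical meshes and attachment data.

## Numerical choices and degenerate inputs

* Weld tolerance 1e-6 m: below scan resolution, above double-precision
  noise. Welding uses grid rounding, which makes cleaning idempotent.
* Mesh smoothing is a Taubin shrink/inflate pair (`lambda = factor`,
  `mu = -(factor + 0.03)`, default factor 0.5) with boundary vertices
  pinned; a pure Laplacian would shrink tube muscles noticeably within the
  20-iteration budgets used here. Any gentle feature-preserving smoother
  would do as much.
* All geometry is metres internally; readers take a declared unit
  (`m`/`mm`/`cm`) and convert on load, with the same default everywhere
  rather than per-format heuristics.
* Isoline levels at vertex values: 1e-12 perturbation (degeneracy rule
  above). Contour resampling count 64 balances angular resolution of the
  correspondence against cost; it must exceed the fibre-grid circumference
  to keep distinct fibres distinct after mapping.
* Sphere fitting rejects coplanar inputs via the smallest singular value of
  the centred design matrix (threshold 1e-10 relative).
* `fit_quartic` requires ≥ 5 samples and rejects rank deficiency;
  `extract_isoline` rejects levels outside (0, 1) and levels with no
  crossings; `remove_region` rejects non-disk regions and disconnecting
  removals; landmark projection names the offending landmark when it lies
  beyond the capture distance.

## Interfaces

Meshes: STL (ASCII and binary), OBJ, PLY (ASCII). Landmarks: JSON with a
declared unit. Fibre sets: JSON and CSV. Configuration: YAML validated
against the known keys, with the effective configuration written next to
outputs so any run can be reproduced from its own artefacts. The
`inst/cli/musclefibres.R` script exposes `synth`, `decompose` and
`momentarms` subcommands over these files.
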