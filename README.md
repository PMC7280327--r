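# muscledecomp

Muscle fibre decomposition and moment-arm analysis from surface meshes.

Multibody musculoskeletal models usually represent a muscle as one or a few
straight line segments between via points. That is adequate for fusiform
muscles with compact attachments, but poor for muscles with broad attachment
areas and curved paths. `muscledecomp` implements, in R, an automated
pipeline that turns a segmented muscle *surface mesh* into an arbitrary
number of polyline "fibres" of user-defined resolution, animates them across
ball-and-socket joint poses, and computes per-fibre moment arms — plus the
conventional straight-lines (via point) model and the agreement statistics
used to compare the two. It is aimed at biomechanists building personalised
musculoskeletal models and at methodologists studying the effect of muscle
discretization on model outputs.

## Method

Given a muscle mesh, two attachment areas (ordered landmark outlines fixed
on the bones), and a fibre-architecture template:

1. **Decomposition** (rest pose). The attachment areas are projected onto
   the muscle mesh and their regions removed, leaving a surface with two
   boundaries. A discrete harmonic scalar field `u` with `u = 0` on the
   origin boundary and `u = 1` on the insertion boundary (cotangent-weight
   Laplacian, clamped to preserve the maximum principle) orders the muscle
   cross-sections; isolines of `u` are extracted at uniform levels
   `k / n_segments`. A unit-cube template with `n` fibres (Bezier curves;
   the shipped template has parallel fibres on a uniform grid) is sliced by
   the matching planes, and each section is transferred onto its mesh
   contour with mean-value (generalized barycentric) coordinates:
   `P_i = sum_q lambda_iq c_q`. Endpoints are attached to the attachment
   outlines with the same machinery and the fibres are smoothed by a
   quadratic penalty on second differences with fixed endpoints.
2. **Kinematics.** Every fibre point `V_i` is bound to its two nearest
   bones and posed as `V'_i = sum_j w_ij (R_j V_i + T_j)`, where the origin
   bone's weight follows the quadratic `f(t) = a t^2 - (a + 1) t + 1` of the
   relative position `t = (i-1)/(n-1)` along the fibre. Because `f(0) = 1`
   and `f(1) = 0`, the endpoints move rigidly with their bones; `a` is a
   muscle-specific parameter (shipped defaults: psoas −0.042, iliacus
   −0.024, gluteus maximus −0.042, gluteus medius 0.0).
3. **Moment arms.** Fibre lengths `l_i(theta)` are swept over one joint
   coordinate in 2° steps, fitted with a 4th-order polynomial, and
   differentiated analytically (tendon-excursion method,
   `r = -dl/dtheta` under the default moment-generating sign convention).
   Straight-lines paths with conditional via points instead use the exact
   geometric method `r = a . ((D - c) x u)`, which is robust where toggling
   via points make `l(theta)` non-smooth. Fans of fibre moment arms are
   summarised by per-pose envelopes, global peaks/mean/sd (in cm), and the
   percentage of poses at which a reference curve falls inside the envelope.

Synthetic generators (tube/fusiform muscles with ring attachments, a
two-bone toy skeleton, a hinge toy with closed-form length and moment arm)
make the whole pipeline runnable and testable without any external data.

## Worked example

```r
library(muscledecomp)
tube <- make_tube_muscle()                      # 0.2 m straight tube, r = 0.03 m
fib <- decompose_muscle(tube$mesh, tube$origin, tube$insertion,
                        n_fibers = 100, n_segments = 15)
print(fib)
#> <fiber_set 'tube_muscle': 100 fibres x 16 points (15 segments)>
summary(fiber_lengths(fib))
#>    Min. 1st Qu.  Median    Mean 3rd Qu.    Max.
#>  0.2000  0.2002  0.2004  0.2005  0.2007  0.2009

skel <- make_two_bone_skeleton()
fib <- assign_bones(fib, skel, a = -0.042, origin_bone = "parent_bone")
curve <- fit_quartic(sweep_lengths(fib, skel, coordinate = "adduction"))
fan <- summarize_fan(excursion_moment_arms(curve))
print(fan)
#> <fan_summary: min -7.3, max 7.3, mean -0.0 (sd 4.2) cm over 41 poses>
```

All 100 fibre lengths stay within 0.5% of the 0.2 m tube height, and the
ab/adduction moment-arm fan of the tube spans ±7.3 cm: fibres on opposite
sides of the ab/adduction axis act as agonists and antagonists, so the fan
is symmetric about zero.

A command-line front-end for the same pipeline lives at
`inst/cli/musclefibres.R` (subcommands `synth`, `decompose`, `momentarms`,
configured by YAML).

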