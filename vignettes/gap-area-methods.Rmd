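---
title: "Measuring the 3D gap area of tibial plateau fractures"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the 3D gap area of tibial plateau fractures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gaparea3d)
```

## The measure and why it exists

Tibial plateau fractures shatter the weight-bearing articular surface of the
knee into displaced fragments. How badly the joint surface is disrupted at
the moment of injury is the strongest determinant of post-traumatic
osteoarthritis and eventual conversion to a total knee arthroplasty (TKA),
yet the conventional assessment — the maximum gap and step-off measured on a
single 2D CT slice — is observer-dependent and blind to displacement outside
that slice.

The **3D gap area** addresses this: it is the area (mm²) of the surface
spanning *all* fracture lines between *all* fragments at the articular
level, measured on a 3D bone-surface model built from the diagnostic CT. A
pure gap of width $g$ along a fracture line of length $L$ contributes $L
\cdot g$; a pure step-off of height $s$ contributes the vertical ruled strip
$L \cdot s$; combined displacement contributes $L\sqrt{g^2+s^2}$, because
the spanning surface is the ruled sheet between the two articular edges.
The measure therefore aggregates every inter-fragment discontinuity of the
joint surface into a single number with a direct geometric meaning.

On top of the measurement sits a prognostic layer: four groups with
boundaries at 150, 550 and 1000 mm² (excellent / good / moderate / poor), a
high-risk flag at the Youden-optimal cut-off of 550 mm², Kaplan–Meier
native-knee survivorship, log-rank comparison of the groups, and Cox
proportional-hazards models adjusting for age, sex, smoking, BMI and
reduction adequacy (residual gap and step-off both ≤ 2 mm).

## Pipeline and its assumptions

1. **Segmentation** (`segment_bone`, `label_fragments`). Bone is
   thresholded at HU ≥ 226, the standard preset bone threshold. Fragments
   are separated by connected-component labelling (default 26-connectivity),
   which is equivalent to seeded region growing for spatially disjoint
   fragments; fragments that touch must be separated explicitly with
   `split_fragment` (an oriented plane or mask), the scripted counterpart of
   interactive manual separation. Components under `min_voxels` (default 50)
   are treated as speckle.

2. **Meshing** (`extract_mesh`). Each fragment's binary mask is
   anti-aliased with one separable 1-2-1 binomial pass and iso-surfaced at
   0.5 by marching tetrahedra (a six-tetrahedron cube decomposition with
   consistent face diagonals, hence watertight meshes). The binomial
   pre-filter removes the voxel staircase that would otherwise inflate
   surface areas by ~25%; because the kernel is symmetric, flat boundaries
   that fall midway between voxel centres do not move. The mesh is then
   smoothed with a volume-preserving Taubin lambda/mu relaxation whose
   positive-pass strength is the conventional smoothing factor 0.4 (10
   iterations, pass band 0.1). Smoothing changes enclosed volume by well
   under 2%.

3. **Articular delineation** (`delineate_articular`). The faithful input
   is a per-vertex annotation — the scripted counterpart of manually
   brushing the articular surface; this package deliberately does not claim
   to recognize articular cartilage automatically. A geometric heuristic
   (triangle normals within 45° of the proximal axis, centroids in the top
   15% of the fragment's proximal extent) exists so that idealized phantoms
   run unattended; it is not validated for anatomy.

4. **Contours** (`extract_contours`). The patch boundary (edges on exactly
   one member triangle) is chained deterministically into closed loops. A
   triangle-subset boundary zigzags at the mesh-edge scale, so the chained
   polyline is regularized by 10 cyclic Laplacian passes; straight and
   gently curved stretches are unaffected (the shrinkage of a circle of
   radius 25 mm is below a micrometre) while lattice-scale ripple, which
   otherwise inflates ruled areas, is removed.

5. **Trimming to fracture lines** (`trim_to_fracture_lines`). A contour
   point is *fracture* (rather than peripheral rim) when three conditions
   hold against the nearest point of another fragment's contour: (i)
   distance ≤ `d_max` (default 7.5 mm, chosen to exceed the largest
   clinically plausible single displacement of ~7 mm); (ii) the opposing
   point lies on the *outward* side of the contour — the side away from the
   patch interior — assessed on the in-plane component of the offset with a
   small tolerance (`facing_tol` 0.02) and skipped when that in-plane
   component is under `w_min` = 1 mm (a pure step-off sits directly
   underneath); and (iii) the approach is not *grazing*: the offset must
   point across the contour, not along its own continuation
   (tangent-cosine ≤ 0.9). Proximity alone is not sufficient: every rim
   point is within `d_max` of the displaced twin contour whenever the
   displacement magnitude is below `d_max`, so conditions (ii) and (iii)
   are what confine the fracture lines to the true opposing edges. The
   geometry fixes the tolerances: on a circular rim the outward cosine at
   an arc length $t$ past a fracture-line end falls like $-t/r$, so
   `facing_tol` = 0.02 bounds spurious rim arcs at about $0.02\,r$
   (≈ 0.5 mm on a plateau-sized fragment).

6. **Closure and surface** (`close_loops`, `build_surface`). Free line
   ends are paired greedily (closest first, lexicographic tie-breaks) with
   straight closure segments; a single original line never closes on itself
   while other lines remain, but a chain already containing two or more
   lines may, so independent fracture systems close into independent loops
   and areas add. Each loop is projected on its principal-component plane,
   checked for simplicity, ear-clipped (choosing the best-quality ear at
   each step), and the triangles are lifted back to the original 3D
   coordinates; Lawson-style diagonal flips that minimize the lifted area
   then converge to the natural ruled triangulation, so out-of-plane
   step-off inflates the area exactly as $L\sqrt{g^2+s^2}$ predicts. Before
   triangulation the loop's cyclic order is canonicalized with
   frame-invariant keys (distances from the loop centroid), which makes the
   result invariant under rigid motion to machine precision. Degenerate
   (collinear) loops contribute zero area.

The spanning surface of the original interactive workflow is not specified
beyond its name; planar-projected triangulation with retained 3D
coordinates was chosen because it is deterministic, oracle-checkable
against ruled surfaces, and consistent with the statement that the measure
incorporates distances between fracture lines in all planes. A lofted or
minimal surface would differ only at strongly non-planar loops.

## What the phantoms emulate — and what they do not

`make_phantom` renders idealized solids (cylinders or boxes) split by
vertical planes, with the positive-side fragment displaced by a gap $g$
along the cut normal and a step-off $s$ distally. The analytic truth is
$\text{chord} \times \sqrt{g^2+s^2}$ per cut. The voxel grid is aligned so
that cut planes and the articular plane fall midway between voxel centres;
the binary iso-surface then lands on the analytic boundary, and integer-mm
displacements at 0.5 mm spacing preserve the alignment. Phantom articular
annotations flag all vertices within 1.8 × spacing of each fragment's own
articular plane, reaching just below the smoothing-rounded edge so that
patch boundaries lie on the flat fracture walls where vertex positions are
exact.

```{r phantom-demo}
ph <- make_phantom(split_cylinder_spec(g = 2, s = 1, r = 15, h = 20))
ph$truth$total_area                       # analytic: 30 * sqrt(5)
res <- measure_gap_area(ph$meshes, annotations = ph$annotations)
res
```

Phantoms are *not* anatomical: no cancellous/cortical contrast, no CT noise
beyond optional Gaussian HU noise, no curved fracture surfaces, no
comminution, and the articular surface is flat bone rather than cartilage.
Passing the phantom suite therefore demonstrates that the geometric
machinery measures what it claims on known geometry — it does not
demonstrate segmentation or delineation accuracy on clinical CT, which in
practice is supplied by the user's annotation.

At study-scale geometry (cylinder radius 25 mm, 0.5 mm voxels) the measured
area agrees with the analytic truth within 10% over the full displacement
grid $g, s \in \{0,\dots,5\}$ mm (excluding the doubly degenerate
$g=s=0$, for which the relevant check is that the *uncut* phantom yields
exactly 0); most cells agree within 2%, and the worst cells are the pure
step-offs where the two articular edges sit at slightly different mesh
depths. The error shrinks when the voxel spacing is halved.

## The cohort simulator

`simulate_cohort` draws gap areas log-normally (default median 419 mm²,
sdlog 1 — the native-knee median of a representative multicentre cohort,
with a spread that places roughly 15% of patients above 1000 mm²), assigns
prognostic groups, and generates TKA times from an exponential baseline
(default 0.0037/year in the excellent group, matching ~96% 10-year
native-knee survival) with group hazard ratios 1.7 / 6.8 / 14.3, censored
administratively at a uniform 1–18-year follow-up. Covariates (age
53.1 ± 14.4, 29% male, 19.6% smokers, BMI 26.3 ± 4.6, 30% inadequate
reduction) are drawn from realistic marginals and by default do not enter
the hazard, so the simulated truth is exactly the group structure. These
defaults are configuration, not claims about any particular cohort.

```{r cohort-demo}
co <- simulate_cohort(n = 2000, seed = 1)
table(co$prognosis)
round(mean(co$tka), 3)
```

## Statistical layer

ROC analysis is empirical, oriented so that a larger gap area is more
indicative of TKA conversion; the AUC (trapezoid) equals the normalized
Mann–Whitney statistic. The critical cut-off maximizes Youden's
$J = \text{sensitivity} + \text{specificity} - 1$, ties to the smaller
value. Kaplan–Meier, log-rank and Cox models are computed by the
`survival` package (`survfit`, `survdiff`, `coxph`); Cox ties default to
Breslow, with Efron available, and fits showing monotone-likelihood
behaviour are flagged rather than silently reported. The group boundaries
are half-open on the continuous scale (a gap area of exactly 150 mm² is
excellent); note the deliberate, documented asymmetry that 550 mm² is
"good" by group but high-risk by the ≥ 550 flag — both conventions are in
clinical use and both are preserved.

```{r stats-demo}
select_cutoff(gap_cutoff_table())
km <- km_estimate(c(1, 2, 3, 4), c(1, 0, 1, 1))
km_surv(km, 3) # product-limit by hand: 3/4 * 1/2
```

## Numerical choices and degenerate inputs

* Iso level 0.5 on the anti-aliased binary mask; voxel centres at integer
  indices, world coordinates in mm, +z proximal.
* Taubin smoothing: lambda = factor (default 0.4), mu from pass band 0.1,
  10 iterations. Factor 0 disables smoothing.
* Contour chaining starts at the lexicographically smallest point and
  proceeds toward the lexicographically smaller neighbour, so outputs are
  reproducible bit-for-bit; loop orientation for the facing test is fixed
  by summing outward offsets against per-edge interior references, which is
  robust on vertical boundary bands where a single-edge test is noise.
* Loops with fewer than three distinct points, or collinear loops, yield
  zero area; self-intersecting projected loops raise `"non-simple loop"`.
* Fragments under 8 voxels refuse to mesh; empty patches and single-class
  outcomes raise errors rather than returning silent zeros.
* All tie-breaks (component ordering, endpoint pairing, cut-off ties) are
  deterministic; reports embed a config digest and rerunning a fixed
  configuration is byte-identical.

## Problem sizes used in the validation suite

Unit tests run on r = 15 mm cylinders at 0.5 mm spacing (~0.3 M voxels,
a few seconds each); the full-scale acceptance checks use the r = 25 mm,
0.5 mm-spacing geometry (~1 M voxels, 35 grid cells, about three minutes)
and n = 1000–50 000 simulated cohorts. These sizes were chosen so the whole
suite exercises study-scale geometry while remaining comfortably runnable
on a laptop.

## Known limitations

* No automatic anatomical recognition: the user crops the volume to the
  proximal tibia and supplies articular annotations for clinical data.
* Touching fragments are one connected component until split explicitly.
* DICOM series are not read directly; convert to NIfTI first (the HU
  rescale helper `hu_rescale` covers slope/intercept arithmetic).
* The fracture-line trim rule is a geometric reconstruction of an
  interactive step; `d_max`, the facing tolerance and the regularization
  strength are exposed for sensitivity analysis.
* Pure step-off phantoms carry the largest measurement bias (up to ~7% at
  0.5 mm spacing) because the opposing articular edges are sampled at
  slightly different depths of the rounded mesh edge.
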