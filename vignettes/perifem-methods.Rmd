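---
title: "Methods: voxel micro-FE comparison of microstructural and homogenized peri-implant bone models"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: voxel micro-FE comparison of microstructural and homogenized peri-implant bone models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## Scope and model

`perifem` quantifies how explicitly resolved trabecular microstructure changes
the stress and strain a loaded dental implant transfers to the surrounding
bone, relative to the homogenized model that coarse (CBCT-resolution) imaging
forces. Both models derive from one ground-truth labelled specimen and are
solved on the same voxel lattice under the same load, so the reported
differences are attributable to the constitutive treatment of the cancellous
compartment, not to geometry, mesh density or boundary conditions.

The mechanical model is small-strain isotropic linear elasticity. Each
foreground voxel becomes one 8-node hexahedral element (the standard µFE
construction); the implant–bone interface is a continuous bond realized by
node sharing (100% osseointegration — no contact, friction or partial
bonding). Materials (units mm / N / MPa):

| phase | refined model | simplified model |
|---|---|---|
| implant (Ti) | E = 110000, ν = 0.35 | same |
| cortical bone | E = 14400, ν = 0.309 | same |
| trabecular struts | E = 14400, ν = 0.309 (tissue level) | — (not resolved) |
| cancellous block | — (marrow not meshed) | E = 480, ν = 0.225 |

In the refined model trabecular and cortical tissue share one material, the
standard microlevel assumption; the marrow voids carry no elements. In the
simplified model the entire interior becomes a soft homogeneous block. Both
mesial and distal faces (the planes normal to the specimen's long axis) are
fixed in all directions, representing continuity with the rest of the
mandible; each implant receives a 50 N load along its long axis, split
equally over the nodes of its most-superior exposed faces (a
`per_implant = FALSE` switch shares the total instead — whether such a load
is per-implant or total is ambiguous in common usage, so both are supported).

## Synthetic specimens

No real micro-CT/CBCT pairs of implanted mandible blocks are publicly
available, so the package generates its own ground truth and emulates both
scanners from it. The trabecular interior is a thresholded, anisotropically
smoothed Gaussian white-noise field: the smoothing correlation length sets
the strut/void feature size, and the threshold is chosen (and iterated after
connectivity cleanup) so the realized bone volume fraction lands within
±0.01 of the target BV/TV. Struts disconnected from the cortical shell are
relabelled marrow — isolated fragments would be unphysical and mechanically
singular. This stochastic morphology reproduces a rod-like porous
architecture with controllable BV/TV and feature size; it does **not**
reproduce plate-like trabeculae, preferential trabecular orientation along
load paths, cortical porosity, or marrow-phase mechanics. Passing tests on
these specimens therefore validate the pipeline's mechanics and image
processing, not anatomical fidelity of any particular jaw.

Key generator defaults (all configurable via `specimen_spec()`):

* `domain_size_mm = c(6.3, 6.3, 10.8)`, `voxel_mm = 0.3` — a desk-scale
  lattice (21×21×36) chosen so the full paired analysis over several seeds
  runs in minutes on one CPU; the literal 18 µm pitch of a real micro-CT is
  reachable by configuration for users with patience.
* `cortical_thickness_mm = 0.9` (3 voxels), plausible for a mandibular
  premolar segment.
* `target_bvtv = 0.3`, `correlation_length_mm = 0.8` — mid-range cancellous
  values; no species-specific morphometry is claimed.
* implant: Ø4.1 mm × 8 mm, thread pitch 0.8 mm, depth 0.3 mm, modelled as a
  core cylinder plus rectangular annular rings (a voxel-friendly
  approximation of the helix that preserves the threads' mechanical
  interdigitation role).

Scanner emulation (`scanner_spec()`): per-label base intensities
(background 20, bone 100, implant 230 — arbitrary units spaced so the
noiseless image is exactly three-phase), multiplicative bone darkening
`1 − a·w(x)` with `w` a Gaussian bump centred at the midpoint of the two
implant centroids (scale = ¼ of their distance; zero with fewer than two
implants) emulating inter-implant metal artifacts, Gaussian blur, additive
Gaussian noise, and — for CBCT — block-averaging by an integer factor
(default: the largest factor ≤ 3 dividing the lattice), which preserves the
volume mean exactly. Beam-hardening physics, ring artifacts and detector
nonlinearity are out of scope.

## Segmentation

The recovery chain is: light Gaussian denoise → two-stage discriminant
(Otsu) thresholding → seeded graph-cut refinement → connected-component
cleanup.

*Denoise.* The pipeline default is a Gaussian of σ = 0.1 mm. A cube median
filter is provided, but at a 0.3 mm lattice its 3³ window erases one-voxel
trabecular struts, so it is not the default at desk scale.

*Thresholding.* Otsu's criterion (maximal between-class variance; ties to
the lower threshold; integer-valued data get one histogram bin per level,
making the search exactly exhaustive). Which side of the first split
contains two phases depends on phase proportions, so both candidate
secondary splits are evaluated and the stronger one (relative between-class
variance, floor 0.05) decides whether the image reads
background | bone | implant or has no implant class at all.

*Graph cut.* The two-label energy
`E(l) = Σ_v D_v(l_v) + λ Σ_{(u,v)} w_uv [l_u ≠ l_v]` with unaries from
add-one-smoothed seeded intensity histograms, boundary weights
`w_uv = exp(−(I_u−I_v)²/2σ²)` on the 6- (or 26-) neighbourhood, seeds as
infinite-capacity hard constraints and implant voxels held fixed, minimized
exactly by a single max-flow (igraph's push-relabel). Terminal capacities
are reduced by the per-voxel `min(D_bone, D_bg)` — a constant energy shift
that leaves the argmin unchanged and speeds the solver severalfold.
Defaults `λ = 2`, `σ_edge = 15` (intensity units, ≈ 2× the default noise
sd), 32 histogram bins. Optimality is verified in the test suite against
exhaustive enumeration on instances small enough to enumerate.

*Seeding protocol.* Interactive clicks are replaced by a reproducible rule:
each ground-truth phase is eroded by one voxel (a user clicks phase
interiors, not partial-volume boundary voxels) and seeds are taken at evenly
spaced intensity quantiles of the eroded phase, so the seeded histograms
span each class's full interior intensity range — including artifact-darkened
bone, which is exactly what rescues the regions thresholding loses. Seeding
from raw intensity extremes instead pollutes the background histogram with
bright partial-volume voxels next to the implant and collapses the cut.

*Cleanup.* Bone components below `min_voxels` or anchored to neither a
domain face nor the implant are relabelled background; implant components
below 25% of the largest are treated as bright speckle and removed (the
number of implants is unknown post-segmentation, so "largest component per
implant" is approximated by this ratio rule).

## Solver and numerical choices

* One stiffness template per distinct (E, ν) — all voxels share one spacing,
  the key µFE economy. 2×2×2 Gauss quadrature; the element matrix is
  symmetric PSD with exactly six rigid-body modes and scales linearly in E
  and h (verified).
* Fixed DOFs are eliminated by reduction (not penalties), keeping
  conditioning clean and reactions exact; prescribed non-zero displacements
  are supported (used by the patch test).
* Jacobi-preconditioned conjugate gradients to a relative residual of 1e-8
  (default); results change by far less than 0.1% when tightened to 1e-10
  (asserted in the suite). A sparse-Cholesky `method = "direct"` is retained
  as the oracle route and for small problems.
* Strains are evaluated at element centroids via the trilinear
  shape-function gradients — exact for linear fields, and the centroid
  convention keeps the interface census unambiguous (no nodal averaging).
* "Equivalent stress" is von Mises; "equivalent strain" is the deviatoric
  von-Mises-type `√(2/3 e:e)` (for isotropic elasticity
  `σ_vM = 3µ ε_eq`, asserted on random states). Total-strain conventions
  would rescale, not reorder, fixed-ν comparisons. Tensile/compressive
  measures are the first/third principal values, compressive reported as a
  positive magnitude.
* Interface statistics (max and arithmetic mean of the six measures) are
  taken over bone elements sharing a face with an implant element — implant
  stress itself is excluded.

## Paired comparison design

The simplified branch solves the homogenized truth on the same fine lattice
as the refined branch, rather than on the coarse CBCT lattice: this isolates
the constitutive effect of microstructure from element-size effects, which a
literal CBCT-lattice solve would confound. The CBCT image is still emulated
and carried through the artifacts for demonstration. Percent changes are
`100·(refined − simplified)/simplified` per measure, for max and mean.

## What the verification shows — and limits

The acceptance battery (see `tests/testthat/test-acceptance.R` and
`scripts/acceptance.R`) verifies: machine-precision patch-test and bar
solutions; global equilibrium to 1e-8; PCG–direct agreement; rotation
invariance and closed forms of the tensor measures against independent
oracles; Otsu and graph-cut exactness against brute force; segmentation
recovery (Dice) on the artifact-shaded two-implant specimen with graph-cut
refinement strictly beating thresholding; and, over five seeded specimens,
the paired-model direction (interface stress higher, interface strain lower
in the refined model) and localization (refined stress peak among the
trabecular interior elements, simplified peak in the cortical neck).

Known limitations worth keeping in mind:

* Desk-scale maxima are noisy. The *mean* interface measures separate the
  two models robustly; the *maximum* equivalent stress in the simplified
  model (cortical neck concentration) can approach the refined strut peak in
  some random specimens, so max-based directions are less stable than
  mean-based ones at this lattice. Voxel models also carry jagged-boundary
  stress concentrations; centroid evaluation tempers but does not remove
  them.
* Linear elasticity only: no damage, remodelling stimulus, viscoelasticity
  or interface nonlinearity.
* The stochastic specimen is a morphology stand-in, not an anatomical model;
  absolute stress/strain values should be read as model-class comparisons,
  not patient predictions.
* Segmentation carries no cortical/trabecular distinction from intensity
  (the refined model treats them as one material anyway); the cortical label
  exists only in ground truth and the homogenized model build.
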