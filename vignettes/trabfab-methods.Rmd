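---
title: "From binary micro-CT volumes to orthotropic elasticity: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From binary micro-CT volumes to orthotropic elasticity: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabfab)
```

# The problem

Cancellous (trabecular) bone is a porous, oriented microstructure. In
whole-bone finite-element models it is impractical to mesh individual
trabeculae, so the standard approach is homogenization: replace the
microstructure in each region by an equivalent solid whose anisotropic
elastic constants are predicted from two descriptors that a micro-CT scan
provides — the bone volume fraction BV/TV and the second-rank fabric
tensor measured by the mean intercept length (MIL) method. trabfab
implements that chain end to end for axis-aligned cubic volumes of
interest (VOIs): morphometry, fabric, fabric-elasticity homogenization,
cohort-level density-stiffness regression, and a voxel-size sensitivity
study, plus seeded synthetic volumes so every stage is testable without
scan data.

# Morphometric indices

All operate on a `binary_volume`: a 3-D logical grid (z, y, x) with a
voxel size in micrometres.

* **BV/TV** — foreground voxels over total voxels; exact count.
* **BS/TV** — surface area of the bone/marrow interface per total volume
  (1/mm). The interface is triangulated by marching tetrahedra at
  iso-level 0.5 after light Gaussian smoothing (`smooth_sigma = 0.8`
  voxel). The smoothing matters: triangulating the raw binary staircase
  overestimates a sphere's area by about 9%, while with sigma 0.8 the
  bias is under 1%. Faces clipped by the VOI boundary are excluded
  (open-boundary policy — VOIs are interior samples); `closed_boundary =
  TRUE` caps them instead.
* **Tb.Th. / Tb.Sp.** — Hildebrand–Rüegsegger local thickness: the
  thickness at a point is the diameter of the largest sphere inside the
  phase containing that point, computed by an exact Euclidean distance
  transform, a distance-ridge test, and sphere painting. Distances are
  voxel-centre to voxel-centre, which reproduces slab and cylinder
  diameters exactly but quantizes at the single-voxel scale (an isolated
  voxel reports 2 voxels); accuracy is ±1 voxel.
* **Conn.D.** — connectivity density `(1 - chi) / TV` in 1/mm^3, with
  `chi` the Euler characteristic of the foreground cubical complex
  (vertices − edges + faces − cells; consistent with 26-connectivity).
  This equals the first Betti number per volume under the usual
  assumptions (one component, no enclosed cavities); the component count
  is attached so the assumption is checkable, and multi-component inputs
  simply report the computed value.
* **EF** — ellipsoid factor `a/b − b/c` of a maximal inscribed ellipsoid
  with semi-axes `a ≤ b ≤ c`: −1 plate-like, +1 rod-like, 0 sphere-like.
  Seeds are sampled on the distance ridge; from the inscribed sphere,
  semi-axes are dilated greedily (0.5-voxel steps) along candidate
  orthonormal triads (grid axes first, then seeded random rotations),
  keeping the largest-volume feasible ellipsoid. Containment is tested on
  surface sample points but only on the in-volume part of the surface:
  points beyond the VOI boundary do not veto growth, consistent with the
  open-boundary surface policy. The initial radius is the EDT radius
  minus one voxel, because containment is judged voxel-wise and a surface
  point can fall into a background voxel slightly beyond the
  centre-to-centre distance. EF is seed-dependent by construction; for
  structures that span the whole VOI (ideal plates/rods) the statistics
  are dominated by how much room each seed has, so limiting values are
  reached in the median, not at every seed.
* **Surface model** — `BS/TV = K·BV/TV·(1 − BV/TV)`, the simplest
  one-parameter form that vanishes at BV/TV = 0 and 1;
  `fit_surface_model()` solves the one-parameter least squares in closed
  form.

# Fabric measurement

`sample_mil()` draws test directions uniformly on the hemisphere (a
spherical Fibonacci lattice de-aligned from the grid by a seeded rotation;
pseudo-random available), lays a parallel grid of lines per direction
(default spacing 1 voxel, origin dithered), marches each line at
half-voxel steps with nearest-neighbour lookup, and counts bone/marrow
boundary crossings. `MIL(w)` is total in-volume line length divided by
the number of intercepts (crossing pairs). Directions with no intercepts
are dropped and counted.

Two numerical choices matter:

* **Run persistence.** A phase change is counted only when the new phase
  persists for two consecutive samples. Voxelized interfaces are
  staircases, and without this filter a line obliquely skimming an
  interface collects spurious single-sample crossings, making raw MIL
  systematically direction-dependent (max/min ratio ≈ 1.4 on an
  isotropic 128³ phantom; ≈ 1.09 with the filter, and the fitted
  anisotropy of an isotropic volume drops from DA ≈ 0.05 to ≈ 0.02).
  The flip side is a resolution floor: structures of ~1 voxel are below
  what any sub-voxel-marching MIL sampler can resolve, so voxel-scale
  Boolean noise is *not* measured as isotropic — isotropy holds for
  resolved (multi-voxel) microstructure.
* **Crossings-based normalization.** MIL is normalized by intercept
  pairs, the convention in which the MIL of parallel plates of period
  `s` along their normal is `s`. Since the anisotropy and fabric
  eigenvectors are invariant to the global MIL scale, this choice does
  not affect DA, the normalized eigenvalues, or the elasticity mapping.

`fit_anisotropy_tensor()` solves the linear least squares
`w' M w = 1/MIL(w)²` for the symmetric positive-definite material
anisotropy tensor `M` (eigenvalues `D1 ≤ D2 ≤ D3`), from which

* degree of anisotropy `DA = 1 − D1/D3`,
* fabric tensor `A = M^(−1/2)` with eigenvalues sorted
  `A11 > A22 > A33` (the MIL ellipsoid radii; `e1` is the principal
  trabecular direction),
* normalized eigenvalues `λ_i = A_ii / (A11 + A22 + A33)` (sum = 1), and
* orientation angles `(α, β, γ)` — direction cosines of `e1` against
  the x, y, z axes, folded into [0°, 90°].

Near-degenerate eigenvalues (relative gap < 1e-6) are flagged and the
tied eigenvectors ordered by `|e·z|`, then `|e·y|`.

# Fabric-elasticity homogenization

The orthotropic stiffness in the fabric eigenbasis is an explicit
function of `(λ1, λ2, λ3)` and BV/TV through nine scalar functions
`k_i = k_ia + k_ib·(BV/TV)^p` (p = 1.6), the classic fabric-elasticity
relations for an isotropic tissue matrix with modulus `Et` (default
15 GPa):

```
c_iiii = Et [k1 + 2 k6 + (k2 + 2 k7) II + 2 (k3 + 2 k8) λi + (2 k4 + k5 + 4 k9) λi²]
c_iijj = Et [k1 + k2 II + k3 (λi + λj) + k4 (λi² + λj²) + k5 λi λj]
c_ijij = Et [k6 + k7 II + k8 (λi + λj) + k9 (λi² + λj²)]
```

with `II = λ1λ2 + λ1λ3 + λ2λ3`. Assembly is in Voigt order (11, 22, 33,
23, 13, 12) with the engineering shear convention, so `E_i = 1/S_ii`
(i = 1..3) and `G_i = 1/S_ii` (i = 4..6) hold literally on the
compliance `S = C^{-1}`; Poisson ratios are `ν_ij = −S_ij/S_ii` and
satisfy the reciprocity relations `ν_ji/E_j = ν_ij/E_i` to numerical
precision. The material axes are *labelled* by stiffness — `z'` carries
the largest Young's modulus — rather than assumed, and the permutation
is recorded. The directional modulus `E(n) = 1/(n_i n_j n_k n_m
S_ijkm)` uses the full fourth-rank compliance with the tensor shear
convention internally, as does the rotation of the stiffness into the
volume frame.

## The constants table

The shipped `kabel_constants()` sets are micro-FE-fitted values of
`(k_ia, k_ib)` spanning six anatomic sites. The source table as printed
is typographically defective: evaluated verbatim (`variant = "printed"`)
it yields a stiffness that is negative definite for *every* eigenvalue
composition on the unit simplex and every volume fraction in the study
range — we verified this numerically over exponent re-readings of the
ambiguous entries and over alternative eigenvalue normalizations. An
exhaustive search over minimal typographic corrections (sign flips and
factor-of-ten changes per entry) finds a unique two-edit repair: the
signs of `k4b` (+1.159e1) and `k8b` (+8.001). With only those two flips

* the stiffness is positive definite over the whole observed domain up
  to `λ1 ≈ 0.40` (and for the rod-like eigenvalue shapes the generator
  produces, beyond that),
* evaluated at the cohort-mean fabric and BV/TV = 0.133 it reproduces
  the reported cohort scale (`E_z'/Et ≈ 0.046` vs 0.0476, with the
  same orderings of all nine constants), and
* extrapolated to BV/TV = 1 it gives `E_z' ≈ 1.10·Et`, matching the
  reported over-extrapolation of about 17.45 GPa vs a 15 GPa tissue
  modulus.

The corrected set also restores per-row sign agreement between `k_ia`
and `k_ib`. It ships as the default; both sets are JSON configuration
(`inst/extdata/`), never hard-coded, and
`audit_positive_definiteness()` reports validity and stiffness scale
over any domain — non-positive-definite assemblies are returned with
`valid = FALSE` and a warning, never clipped or hidden. No clamping is
applied anywhere (in particular not at high BV/TV).

# Synthetic volumes

`make_phantom()` provides analytic phantoms (sphere, slab, parallel
plates, rod lattice — each with exact or closed-form ground truth used
by the oracle tests) and the trabecular emulator `grf_trabecular`:
seeded Gaussian white noise filtered in the Fourier domain by an
anisotropic Gaussian kernel (per-axis sigmas = `sigma · stretch`, first
axis rotated onto the requested principal direction; periodic boundary
keeps the field stationary), thresholded at the `1 − BV/TV` quantile so
the achieved volume fraction matches the target to one voxel count. One
stretched axis produces rod-like (prolate) structure, two produce
plate-like; a stretch ratio of 2 yields DA ≈ 0.55–0.65, i.e. the
anisotropy range reported for vertebral cancellous bone. The default
`sigma = 2.5` voxels gives trabecular thickness of roughly 5–7 voxels.

`make_cohort()` emulates a multi-sample study: targets spanning a BV/TV
range (default 0.082–0.194), principal directions jittered about the
z-axis (default SD 8°, matching the few-degree off-axis orientations
reported for lumbar trabeculae), per-sample stretch in [1.6, 2.4], and
cyclic vertebral-level/region tags. All randomness flows from one
integer seed; regeneration is bit-identical.

What the generator does *not* emulate: gray-value CT physics (noise
spectra, beam hardening, partial-volume blur), plate-rod mixtures within
one sample, cortical shell remnants, and marrow-space heterogeneity.
Passing tests therefore demonstrate the correctness of the measurement
chain on oriented two-phase microstructure, not scanner realism.

# Voxel-size sensitivity

`degrade_voxel_size()` aggregates `factor³` blocks by mean occupancy
with ties to foreground (volume-preserving in expectation; trailing
voxels trimmed, never padded), and `voxel_sensitivity()` re-runs the
fabric-elasticity chain at each resolution, reporting moduli normalized
to the finest grid. On trabecular phantoms the seed-averaged normalized
Young's moduli decrease from factor 1 to factor 4 in all three
directions (fitted slope negative; coarsest below finest). A caveat at
small factors: when the block size is comparable to the feature size,
majority aggregation can transiently *gain* bone volume (we observe a
bump at factor 2 in the transverse moduli), so the decrease is a trend
over the factor range, not a strict per-step monotonicity — consistent
with a resolution error that grows with voxel size.

# Cohort statistics

`fit_power_law()` fits `y = a·x^b` by nonlinear least squares on the
original scale (not log-log), initialized from the log-log linear fit,
with an analytic Jacobian and geometric normalization of the response —
this makes the fit exactly scale-equivariant and lets it converge to
tight tolerance; R² is reported on both the original and the log scale
(which one the classic reports used is ambiguous), and the p-value is
the two-sided t-test of the log-log slope. Constant responses return a
flagged degenerate fit. `describe_stats()` reports mean, SD (n−1), CV,
median, min, max; `group_summaries()` applies it per group. No outlier
removal is performed anywhere.

# Problem sizes used in the checks

The test suite runs phantoms at 16³–96³ with 300–1000 MIL directions and
line spacing 2; the full-scale parameter-recovery checks use 128³
volumes with 2000 directions; the sensitivity trend uses ten 64³ seeds
at factors 1–4. These sizes were chosen so each property is measured
well inside its noise floor while the whole suite stays desk-scale.

# Known limitations

* MIL is nearest-neighbour sampled; structures ~1 voxel thick are below
  its resolution (see run persistence above). Measure at ≥3 voxels per
  trabecula.
* EF uses greedy axis dilation over a finite set of orientations; it
  recovers limiting shapes (sphere/rod/plate) and the plate-vs-rod sign,
  but is not a reimplementation of any particular published EF code, and
  its absolute values at intermediate shapes depend on the seed and
  orientation budget.
* Conn.D. assumes the standard one-component, no-cavity topology; the
  component count is reported so violations are visible.
* The fabric-elasticity constants are a cross-site empirical fit; at
  extreme anisotropy (`λ1 > ~0.40` with two large eigenvalues) the
  assembled stiffness can lose positive definiteness, which is reported,
  not repaired. Poisson ratios above 0.5 are possible and legitimate for
  anisotropic cellular solids.
* The pipeline assumes axis-aligned cubic VOIs that are already
  binarized or binarizable by a global isodata threshold; no
  pre-filtering is applied before thresholding.
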