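---
title: "Landmark-oriented reference planes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Landmark-oriented reference planes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cephaloplane)
```

# The measurement model

All analysis operates on named 3D landmark coordinates in millimetres, in a
right-handed subject frame: X lateral (positive toward the subject's
right), Y vertical (positive superior), Z transverse (positive anterior).
Coordinates are stored exactly as read; every reported quantity is either
invariant under rigid motion of the whole landmark set (unsigned distances,
bilateral differences, correlations, Friedman ranks) or pinned by an
explicit orientation convention (signed midline offsets), so no
recentering or pre-alignment of the input is performed or required.

## Horizontal reference planes

Four orbitale/porion landmarks over-determine the Frankfort horizontal, so
five landmark-oriented horizontal planes are constructed, each from exactly
three points:

| plane | defining points |
|-------|-----------------|
| FHP-P | porion midpoint PoA, OrR, OrL |
| FHP-O | orbitale midpoint OrA, PoR, PoL |
| FHP-L | PoL, OrR, OrL |
| FHP-R | PoR, OrR, OrL |
| LSP   | LsR, LsL, N |

A plane is stored as a unit normal $\mathbf n$ and offset $d$ with the
plane $\{\,p : \mathbf n\cdot p = d\,\}$; the signed point distance is
$\mathbf n\cdot p - d$. Horizontal-plane normals are flipped, when needed,
to have a positive Y component (pointing superiorly). This assumes the
subject frame is not upside down — a weaker assumption than any head
positioning, since only the sign, not the value, of distances depends on
it.

## The midsagittal plane

For a chosen horizontal plane $H$ the midsagittal plane is the unique
plane containing nasion and basion and perpendicular to $H$: its normal is
$\mathbf n_H \times (Ba - N)$, normalised, and sign-fixed to point toward
the subject's right (positive X). Signed offsets of the midline landmarks
(ANS, UI, LI, Pog, Me) to this plane are therefore positive when the
landmark lies right of the facial midline. The construction degenerates
when $Ba - N$ is parallel to $\mathbf n_H$ (anatomically impossible); this
is rejected at an angular tolerance of $10^{-6}$ rad rather than silently
producing an arbitrary plane. Published symmetry tables list distances
with explicit $+$ signs without defining the convention; this package
adopts *signed offsets, positive = right*, and documents it, rather than
reporting unsigned distances with a side label.

## Asymmetry metrics

For each horizontal plane the bilateral dental metrics are absolute
differences of unsigned point–plane distances,
$U3 = \lvert\,d(UL3) - d(UR3)\,\rvert$ and likewise U6, L3, L6 for the
first molars and their mandibular counterparts. Signed variants (left
minus right) are available behind a flag but excluded from the
cohort-table output, which follows the absolute-difference definition.
Cohort summaries report the sample mean and SD (the $n-1$ estimator). A
subject is classified asymmetric when the menton offset exceeds 4 mm in
magnitude, the usual physical-examination cut-off; the threshold is a
parameter.

# Statistical machinery

**Pearson correlation.** Observer reliability is summarised per landmark
and axis by the mean absolute coordinate difference between paired
digitisations and the Pearson correlation of the paired coordinate
vectors, computed from the sum formula with a two-sided p-value from
$t = r\sqrt{(n-2)/(1-r^2)}$. Both are implemented from the formulas;
`stats::cor.test` serves only as an independent cross-check in the test
suite. When a coordinate vector has zero variance the correlation is
undefined and reported as `NA` with a warning — never coerced to 1. No
multiple-testing correction is applied to the per-landmark p-values by
default (matching how reliability tables are conventionally reported); a
Bonferroni option exists.

**Pairing.** How two observers × two trials collapse into pairs is a
design choice: this package pairs trial 1 against trial 2 within each
observer for intraobserver reproducibility, and observer against observer
within each trial for interobserver reliability. Both modes are explicit
parameters, not heuristics.

**Friedman test.** Cross-plane comparisons use the Friedman rank test:
values are ranked within each block (subject, or midline landmark for a
single-subject symmetry table) using midranks for ties, and
$$Q = \frac{12}{nk(k+1)}\sum_j \Bigl(R_j - \tfrac{n(k+1)}{2}\Bigr)^2 \Big/
\Bigl(1 - \tfrac{\sum (t^3 - t)}{nk(k^2-1)}\Bigr)$$
is referred to $\chi^2_{k-1}$. The fully tied case (every block constant)
is reported as $Q = 0$, $p = 1$. The implementation is from the formula;
the tests verify it against both an independently coded brute-force
ranking and `stats::friedman.test` on random matrices with and without
ties, and check the empirical null rejection rate at $\alpha = 0.05$
(0.05 ± 0.02 over 2000 simulations at $n = 10$, $k = 5$).

# Rigid superimposition

Cranial-base superimposition uses the Kabsch algorithm: the rotation is
recovered from the SVD of the cross-covariance of the centered landmark
correspondences, with the smallest singular direction negated if the
determinant would be $-1$, so the result is always a proper rotation
(never a reflection). The default basis is the cranial-base set {N, Ba,
PoR, PoL, LsR, LsL}, which orthognathic surgery does not move. Fewer than
three or (near-)collinear basis points raise a degeneracy error; the
collinearity test is a second-singular-value ratio below $10^{-8}$.

# Volumetric analysis

Surface models are closed, consistently oriented triangle meshes
(counter-clockwise from outside; closedness is checked edge-by-edge and
open meshes are rejected for volume operations). ASCII STL and PLY are
read and written natively; STL's independent facets are re-indexed by
merging coincident vertices at $10^{-6}$ mm.

**Regions.** A facial region is an intersection of half-spaces, each a
plane plus a side. The printed literature does not state exact borders
for the chin / right mandible / left mandible / lower lip regions, so the
defaults built by `default_regions()` are package conventions (documented
as such): horizontal borders are planes parallel to the chosen reference
plane through LI, Me or the molar midpoint, and the lateral split is the
derived midsagittal plane. Regions are fully config-driven (YAML I/O), so
any other convention can be supplied.

**Clipping.** Meshes are clipped per half-space by polygon splitting; each
cut leaves a planar boundary loop that is filled by a centroid fan,
keeping the result closed. Cap faces are marked and excluded from
anatomical surface area, as are faces lying on a region's bounding planes
— both are artifacts of region cutting, not anatomy. The centroid-fan cap
assumes star-shaped cut cross-sections, which holds for the convex
phantoms and anatomically plausible region cuts; strongly non-convex cuts
are a known limitation.

**Volume difference.** Both clipped models are voxelized on one common
grid by ray parity: per (x, y) voxel column the surface-crossing heights
are collected, duplicates from shared coplanar edges merged, and voxel
centers with an odd crossing count below them are inside. The grid covers
the union of the two clipped bounding boxes padded by two voxels — the
grid must contain material present in only one model, which is exactly
what the difference measures — and is jittered off exact edge hits. The
default voxel is 0.4 mm, matching typical CBCT resolution; a cell budget
aborts with advice rather than exhausting memory. Reported per region:
the unsigned (symmetric) voxel difference — voxels covered by exactly one
model, a movement magnitude — alongside the signed net change; the
preoperative anatomical surface area in the region; and the average
movement ΔV/A. The soft-to-hard movement ratio divides the soft-tissue
average movement by the hard-tissue one and is undefined (an error, not
`NaN`) below a $10^{-6}$ mm hard movement. Dividing by the *pre*-surface
area is itself a choice (post- or mean-area are defensible); it is the
package's convention and a parameterisable one at region level. On the
20 × 20 × 20 mm slab phantom with a 2 mm face offset the pipeline recovers
an average movement of 2.0 mm within 5 % at 0.4 mm voxels, converging
monotonically as the voxel shrinks, and a 1.6 mm/2.0 mm soft/hard phantom
pair gives a ratio of 0.80.

# The synthetic generator

Clinical CBCT landmark data cannot be redistributed, so validation is
anchored to a generator whose outputs carry closed-form ground truth.

**Template.** `skull_template()` is a bilaterally symmetric adult-scale
landmark configuration (inter-porion 110 mm, maxillary molar half-width
30 mm, mirror plane X = 0). It is deliberately idealized: all
horizontal-plane landmarks — orbitale, porion, the lateral semicircular
canals *and nasion* — lie in the single plane Y = 0, so all five
horizontal planes coincide exactly and every asymmetry metric is an exact
null at zero deformation. Real anatomy has the canals and nasion off the
Frankfort plane, making LSP a distinct, roughly parallel plane; the
idealization is what turns "the five planes agree" into a machine-checkable
zero rather than a clinical observation, and it is the main respect in
which passing tests do not certify behaviour on real data (the others:
real landmark noise is not isotropic Gaussian, and real anatomy is not a
deformed copy of one template).

**Deformations** are applied in a fixed, documented order, since they do
not commute: occlusal cant (rotation of the dental landmarks about the
anterior axis through the arch midline), then chin deviation (lateral
translation of Me, Pog, LI; positive = right, magnitudes 4–11.5 mm span
the clinical asymmetry range), then per-side mandibular setback along −Z
(midline mandibular landmarks move by the side average). Cranial
landmarks never move, so the true midplane stays X = 0 and e.g. an
injected 6.6 mm deviation must be recovered as a +6.6 mm menton offset on
every derived midsagittal plane, exactly.

**Observer noise** is isotropic zero-mean Gaussian, default σ = 0.2 mm per
axis — the scale of published repeated-digitisation differences (0–0.47 mm
mean absolute differences). Noise is deterministic per (seed, observer,
trial, landmark): each landmark draws from its own derived stream, so
subsetting a landmark set never changes another landmark's perturbation,
and identical seeds reproduce cohort files byte for byte. For reliability
simulations, subjects additionally receive per-landmark anatomical offsets
(default SD 5 mm) around the template: between-subject spread is what
makes paired-coordinate correlations informative (with identical subjects
r would estimate 0 regardless of observer quality), and 5 mm is a
conservative stand-in for the centimetre-scale variation of real anatomy,
giving an expected $r \approx 25/(25 + 2\sigma^2) > 0.99$.

**Mesh phantoms.** The slab phantom offsets one box face by a known
amount, so ΔV, the moved-face area, and the average movement are exact;
the ellipsoid phantom scales semi-axes with the analytic volume
difference. These exercise clipping, voxelization and the ratio, not
anatomical shape.

# Problem sizes and tolerances

The validation suite uses: 1000 random subjects for plane containment
(tolerance $10^{-9}$ mm — far below the 0.4 mm voxel data precision, far
above double-precision noise); exact ($10^{-9}$ mm) recovery of injected
deviations; 10-subject, two-observer, two-trial reliability studies at
σ = 0.2 mm checked against the folded-normal mean $2\sigma/\sqrt\pi
\approx 0.226$ mm; 100 random matrices for Friedman brute-force agreement
($10^{-12}$) and 2000 null simulations for the rejection rate; 50 seeded
rigid motions for registration recovery; and the slab/ratio phantoms at
voxels 0.4/0.2/0.1 mm. These sizes make every check sharp at interactive
runtimes; all are parameters, not constants.

# Known limitations

- Landmarks arrive as coordinates; image reconstruction and landmark
  detection are out of scope, as are natural-head-position or
  gravity-referenced planes and occlusal-plane constructions.
- Signed-offset conventions presume an approximately anatomically
  oriented input frame (superior ≈ +Y, right ≈ +X); arbitrary frames
  preserve all unsigned quantities only.
- Cap filling assumes star-shaped cut cross-sections; pathological region
  geometry can produce invalid caps (the closedness check will catch the
  consequences).
- Registration is landmark-based (point correspondences); surface-based
  ICP is out of scope.
- The generator emulates landmark geometry and simple phantom meshes, not
  population shape statistics; cohort-level means from it are not
  clinical predictions.
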