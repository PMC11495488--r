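---
title: "Trabecular morphometry and cohort analysis: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Trabecular morphometry and cohort analysis: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trabkit)
```

trabkit quantifies the architecture of trabecular (cancellous) bone in the
articular heads of long-limb elements from micro-CT image stacks, and runs
the cohort-level statistics needed to describe how that architecture changes
across an ontogenetic series. The pipeline has four stages — standardized
orientation, spherical ROI extraction with segmentation, voxel-level
morphometry, and cohort statistics — plus a synthetic generator that makes
every stage testable without any scan data. This vignette explains the
models and procedures, the parameters that matter, the numerical choices,
and the limits of what the synthetic tests demonstrate.

## Standardized orientation

Comparing trabecular orientations across individuals and elements requires a
common anatomical frame. Five landmarks define it: the midpoints of the
proximal and distal metaphyses, the two lateralmost points where the
articular head contacts the anatomical neck, and one point on the articular
surface. `orientation_transform()` builds the proper rotation that maps the
metaphysis axis to +Z (proximal up), the lateral-contact chord
(orthogonalized against Z) to the Y axis, and picks the X sign so the
articular surface faces −X. Landmarks are *supplied*, not detected: in
practice they are placed interactively in an image-processing program, and
automated anatomical landmarking is out of scope. Two conventions are ours
to fix and are therefore documented rather than derived: the +Y direction is
`lateral_a − lateral_b` (the anatomy does not disambiguate which lateral
point comes "first"), and rotation is taken about the landmark centroid so
that an already-oriented bone maps to itself.

Resampling (`apply_transform()`) offers nearest-neighbour and trilinear
interpolation; binary volumes must use nearest (trilinear would manufacture
intermediate "densities" that have no meaning for a mask). The reference
tooling used for reorientation in practice does not state its interpolator,
so both are exposed. The output grid is the bounding box of the transformed
input corners plus a 2-voxel pad; `output_grid = "same"` keeps the input
grid instead, which is the natural choice for symmetry operations. Left
elements substitute for damaged right ones after `mirror_element()`, an X
reflection; mirroring is an improper isometry, so a mirrored element is
deliberately *not* superposable on its original by any proper rotation —
that is the point of using it.

## ROI extraction and segmentation

The analysis region is the largest sphere of trabecular bone in the
articular head that excludes all cortical bone. "A box whose sides contact
the innermost edges of the cortical bone" is operationalized
deterministically: from the head center, march a ray along each of the six
axis directions until the first cortical voxel; the box face sits just
inside it. The sphere is centered on the box center with radius one voxel
less than the Euclidean distance to the nearest cortical voxel (the 1-voxel
margin keeps the "no cortical bone" guarantee under discrete sampling),
capped to stay inside the grid, and refused below 3 voxels — a sphere that
small cannot contain trabeculae and indicates a degenerate input.

Binarization is Otsu's method on the histogram of the ROI interior only
(thresholding the whole volume would let the cortical shell and background
skew the histogram). The threshold maximizes between-class variance; because
any real-valued cut between two adjacent occupied intensity levels induces
the same partition, ties are resolved to the midpoint of the full maximizing
range, so a two-valued image {40, 200} thresholds at 120 rather than at an
endpoint. Constant images are an error, not a silent all-background result.

`purify()` mirrors the standard pre-morphometry cleanup: keep the largest
foreground component under 26-connectivity and fill background cavities
(6-connectivity) that never reach the array boundary. The 26/6 duality is
the standard choice that avoids the topological paradox of foreground and
background both being connected through a checkerboard junction. Purify is
idempotent, which the suite asserts directly.

## Morphometry

**BV/TV** is foreground voxels over total voxels inside the sphere —
deliberately the same counting used for the generator's ground truth, so
the two agree to numerical identity on phantoms.

**Fabric tensor.** The mean intercept length in direction $\omega$ is
estimated as

$$\mathrm{MIL}(\omega) = \frac{L(\omega)\cdot \mathrm{BV/TV}}{C(\omega)},$$

where $L$ is the total length of a grid of parallel test lines clipped to
the ROI sphere and $C$ the number of marrow-to-bone crossings along them.
The quadratic form $1/\mathrm{MIL}(\mathbf n)^2 = \mathbf n^\top M\,
\mathbf n$ is fitted by least squares over the test directions; the fabric
ellipsoid radii $r_1 \ge r_2 \ge r_3$ are the reciprocal square roots of the
eigenvalues of $M$, and the principal axis $\mathbf e_1$ (the largest-MIL
direction) is the primary trabecular orientation. The estimator is stated
explicitly because the underlying literature names the tensor but not the
normalization. Directions are a golden-spiral lattice on the hemisphere —
quasi-uniform coverage at any count — given a random rotation derived from
the seed so that lattice orientation is not a hidden systematic. Defaults:
`n_directions = 512`, `line_spacing = 2` voxels, sampling step 0.5 voxels.
Fewer than 64 directions is refused (the 6-parameter fit becomes
direction-lattice-limited), and a direction with zero crossings aborts with
advice to enlarge the ROI or coarsen the spacing rather than dividing by
zero.

**DA** is $1 - r_3/r_1$, the convention bounded at 1, consistent with the
observed raccoon range (up to ~0.43) and with 0 meaning isotropy. Eigenvalue
ratio alternatives from other toolchains are not provided.

**TbTh / TbSp** use the model-independent local thickness: Euclidean
distance transform (exact, separable), reduction to the distance ridge
(spheres not contained in a neighbour's sphere), then sphere painting; the
thickness at a voxel is the diameter of the largest inscribed sphere
containing it. TbSp is the same operation on the marrow phase restricted to
the ROI sphere. Values carry a discretization error of about one voxel —
axis-aligned slab boundaries, in particular, quantize a full voxel outward —
which is the accepted cost of the model-independent estimator.

**TbN** defaults to the plate-model identity $\mathrm{BV/TV}/\mathrm{TbTh}$,
with a direct intercept estimator (mean crossings per unit line length over
the MIL directions) available. The published raccoon TbN values cannot be
reconciled exactly with either formula from the printed group means alone,
so the choice is stamped into every output row as provenance rather than
hidden.

**Azimuth and plunge.** Trabecular orientation is axial: $\mathbf e_1$ and
$-\mathbf e_1$ are the same fabric. We canonicalize to the representative
with a non-negative Z component and report plunge as the angle to the X–Y
plane and azimuth from +X towards +Y. (A lower-hemisphere canonicalization
would flip the azimuth label by 180 degrees and nothing else; the folded
azimuth and the plunge are identical either way, and the convention chosen
here is the one consistent with the worked conversions in the test suite.)
The fold transform $||x - 180| - 90|$ collapses azimuth to $[0, 90]$ so that
antipodal and mirror-symmetric compass angles — 359 and 1 degrees — pair up
before PCA and group testing. `stereographic_projection()` is the Lambert
equal-area lower-hemisphere mapping, normalized so horizontal orientations
plot on the unit circle and vertical ones at the center.

## Cohort statistics

The statistics stage consumes a tidy table, one row per specimen-element,
and is deliberately thin over well-trodden machinery: per-group means and
coefficients of variation ($100\,s/\bar x$), Pearson correlations (partial
correlations via the inverse covariance matrix are available, because the
routine named in the source literature computes partial correlations —
which quantity its published table actually holds is ambiguous, so both
modes exist and the mode is recorded), PCA via `prcomp` with a
deterministic sign convention, Kruskal–Wallis omnibus tests per metric
(tie-corrected, via `kruskal.test`; the all-tied degenerate case returns
$H = 0, p = 1$), and Dunn post-hoc z tests with the tie term
$\sum(t^3 - t)/(12(N-1))$. Dunn tests are *gated*: inside the pipeline they
run only when the omnibus p-value clears $\alpha$ (default 0.05); a
standalone call is allowed but flagged and warned. The adjustment default is
"none", matching the cited post-hoc tool's default; Bonferroni and Holm are
flags.

**Allometry.** Each metric is regressed on log10 body mass. Slope and
isometry work uses log10-transformed metrics (isometric references are
log-log exponents: 0 for the unitless BV/TV and DA, +1/3 for the linear
TbTh and TbSp, −1/3 for TbN, struts per mm); descriptive polynomial curves
are fitted on whichever scale the caller plots. Polynomial degree is chosen
by k-fold cross-validation (default k = 10, a conventional choice since the
source only says "K-fold"; fold shuffling is seeded), taking the lowest
mean held-out MSE with numerical ties resolved to the smallest degree. The
isometry comparison is operationalized as a 95% CI containment test on the
linear slope — the source describes the comparison without naming a
statistic, and CI containment has exact 5% type-I error by construction.
Body-mass estimation from bone circumference, $\log_{10} BM = a \log_{10} C
+ b$, requires the coefficients as configuration: the underlying scaling
equation is external and not reprinted, so defaulting them silently would
fabricate a provenance.

## The synthetic generator

The generator exists so that every claim above is testable against known
ground truth. It emulates three things:

* **Rod phantoms** (`generate_rod_phantom()`): cylindrical struts of fixed
  radius whose axes follow a von Mises–Fisher law — the standard
  concentration family on the sphere, chosen because no dispersion model is
  given in the source material ($\kappa = 0$ isotropic, large $\kappa$
  parallel). Anchor points are drawn as a uniform line process (uniform on
  the perpendicular disk circumscribing the grid): anchoring uniformly
  *inside* the grid would concentrate line density at the center and bias a
  centered ROI's BV/TV upward by several points relative to the grid-wide
  truth. Struts are added until the foreground fraction is within ±0.02 of
  the target; exact targeting is ill-posed on a discrete grid, and a target
  that a single strut overshoots is an explicit error. Ground truth
  (achieved fraction by direct recount, strut radius, every drawn axis) is
  returned with the volume.
* **Whole-bone mocks** (`generate_whole_bone()`): a sphere-capped shaft with
  a solid cortical shell of configurable thickness, rod-lattice interior,
  optional growth-plate slab, grayscale rendering (bone 200, background 40)
  with additive Gaussian noise parameterized as a fraction of that class
  separation — enough to exercise Otsu, orientation and the ROI chain end
  to end.
* **Cohorts** (`simulate_cohort()`): per-group, per-element metric vectors
  drawn log-normally with the published group means and coefficients of
  variation for the five raccoon age groups (n = 13/11/10/7/14) as defaults;
  all metrics are strictly positive, which is why log-normal is the default
  noise law (normal is a switch). Group log-body-mass means are not
  published per group; the defaults (0.12, 0.75, 0.85, 0.90, 0.95 log10 kg)
  are anchored to the narrative (a typical 4–12-month animal near logBM
  0.75, adults of 6–9 kg) and are stated here as this package's choice, as
  are the orientation defaults (2-month animals horizontal along the
  anterior/posterior axis with wide spread; adults near-vertical; the femur
  lagging the humerus in the 4–12-month group). Orientation dispersion by
  age is a free parameter of the generator, not a published claim.

What the phantoms do **not** emulate: plate-like architecture, anatomically
realistic strut networks, partial-volume blur, beam hardening, or
resolution variation across specimens. Passing the recovery tests therefore
shows the estimators are correct on rod lattices and spheres/slabs with
known answers — it does not certify accuracy on real scans, where
segmentation quality and resolution dominate the error budget.

## Numerical choices and degenerate inputs

* Unreachable BV/TV targets, empty masks, constant images, all-foreground
  ROIs, zero-variance predictors, absent mass coefficients, and open
  cortices all raise errors naming the problem; nothing degrades silently.
* Identical seeds give bit-identical outputs everywhere (phantoms, cohorts,
  MIL direction lattices, CV folds); pipeline stages derive their seeds
  deterministically from the global seed and the stage name.
* The test suite and the acceptance checks run at deliberately desk-scale
  sizes chosen as this package's own verification conditions: 128-cube
  phantom grids for parameter recovery, 10,000 replicates for the
  Kruskal–Wallis size check, 500 replicate cohorts for group-mean recovery,
  and 100-instance oracle sweeps for Otsu, purify and the rank tests.
* Rigid-motion resampling conserves binary foreground to within 5%;
  quarter-turn compositions on the same grid are exact.

## Known limitations

* The TbN estimator used to produce the published raccoon values is
  unidentifiable from the printed means; both provided estimators are
  internally consistent but neither is guaranteed to match that table.
* MIL at very coarse ROIs (radius under ~10 voxels) is crossing-starved and
  will abort; this is intentional but means tiny specimens need coarser
  line spacing or larger ROIs.
* Local thickness inherits the ±1 voxel quantization of the distance
  transform; thickness contrasts smaller than the voxel size are not
  resolvable.
* The cohort generator draws metrics independently within a specimen; real
  trabecular metrics co-vary (BV/TV with TbTh especially), so correlation-
  and PCA-structure tests use purpose-built co-trending simulations rather
  than the default cohort.
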