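# trabkit

Trabecular (cancellous) bone remodels within weeks in response to loading,
which makes its lattice of struts a sensitive record of how an animal uses
its limbs across life. trabkit is an R toolkit for quantifying that
architecture in the proximal articular heads of long-limb bones from
micro-CT image stacks, and for analysing the resulting metrics across an
ontogenetic cohort — the kind of study that follows bone development in a
quadruped (an ontogenetic raccoon series is the motivating design, with
five age groups of n = 13/11/10/7/14) from first walking through old age.
It is written for comparative morphologists and bone-biology researchers
who have oriented or raw TIFF stacks plus per-specimen metadata and want a
scripted, seeded, end-to-end replacement for an interactive
Dragonfly/ImageJ/Quant3D toolchain.

## What it computes

Given a bone volume and five anatomical landmarks, the pipeline:

1. **orients** the element into a uniform frame (metaphysis axis to +Z,
   lateral head–neck contacts on Y, articular surface facing −X), mirroring
   left elements onto the right-side convention where needed;
2. **extracts the ROI**: an interior box contacting the innermost cortical
   edges, then the maximal sphere that excludes all cortical bone;
   binarizes it with Otsu's threshold on the ROI histogram and purifies the
   mask (largest 26-connected component, enclosed cavities filled);
3. **measures** the standard metric vector:
   - BV/TV — bone volume fraction;
   - the mean-intercept-length fabric tensor, fitted as
     1/MIL(**n**)² = **n**ᵀM**n** over a quasi-uniform hemisphere of test
     directions, with MIL(ω) = L(ω)·(BV/TV)/C(ω);
   - DA = 1 − r₃/r₁ from the fabric ellipsoid radii;
   - TbTh and TbSp by Hildebrand–Rüegsegger local thickness
     (distance transform → distance ridge → sphere painting), in mm;
   - TbN (struts per mm), plate-model or direct-intercept;
   - the primary fabric axis as azimuth/plunge, with the fold transform
     ||x − 180| − 90| for analysis of axial compass angles;
4. **analyses the cohort**: per-group means and coefficients of variation,
   Pearson (or partial) correlation matrices, PCA, Kruskal–Wallis tests
   with α-gated Dunn post-hocs, allometric log–log regressions against
   estimated body mass with k-fold cross-validated polynomial degree
   selection and isometry tests (reference slopes 0 for BV/TV and DA, +1/3
   for TbTh/TbSp, −1/3 for TbN), and Lambert equal-area stereonet
   coordinates.

A synthetic module generates rod-lattice phantoms with von Mises–Fisher
orientation concentration and known ground truth, whole-bone mocks
(cortical shell, trabecular interior, optional growth plate, landmarks),
and cohort tables with the published group means/CVs as defaults — so the
entire pipeline is testable with no scan data.

## Worked example

```r
library(trabkit)

# 1. a synthetic bone: cortical shell + oriented trabecular rods
mock <- generate_whole_bone(whole_bone_spec(
  shape = c(96, 96, 96), outer_radius = 40, cortical_thickness = 5,
  head_center = c(47, 47, 52), noise_sd = 0.1,
  interior = phantom_spec(target_bvtv = 0.3, strut_radius = 2.5, kappa = 5),
  seed = 1
))

# 2. box the head, grow the maximal cortex-free sphere, segment, purify
cortical <- mock$labels == 2
box <- interior_box(cortical, mock$landmarks$proximal)
roi <- expand_sphere(box, cortical)
seg <- segment_roi(mock$grayscale, roi)
seg$foreground <- purify(seg$foreground) & (seg$foreground | seg$background)
seg$background <- (seg$foreground | seg$background) & !seg$foreground

# 3. the full metric vector
metrics <- compute_all_metrics(seg, n_directions = 256, seed = 1)
round(metrics[, 1:7], 3)
#>   bvtv    da  tbth  tbsp   tbn azimuth plunge
#> 1 0.28 0.286 0.146 0.285 1.913    61.7 87.007
```

BV/TV lands on the phantom's 0.3 target, TbTh ≈ 0.146 mm matches the
2 × 2.5-voxel strut diameter at 30 µm voxels, and the near-vertical plunge
(87°) recovers the κ = 5 concentration around +Z that the generator used.

```r
# 4. cohort statistics on a simulated ontogenetic series
cohort <- simulate_cohort(cohort_spec(seed = 1))
report <- run_cohort_analysis(cohort, seed = 1)
report
#> <trab_report> 110 specimen-element rows, 5 age groups
#>   15 Kruskal-Wallis tests (14 significant at alpha = 0.05), 130 Dunn pair rows

dplyr::filter(report$group_means, element == "humerus")
#>   age_group element  n    da  bvtv  tbth  tbsp  tbn
#> 1       2mo humerus 13 0.195 0.268 0.137 0.325 1.72
#> 2    4-12mo humerus 11 0.352 0.411 0.177 0.316 1.89
#> 3   14-24mo humerus 10 0.350 0.354 0.182 0.359 1.72
#> 4   26-38mo humerus  7 0.348 0.301 0.185 0.397 1.47
#> 5     46+mo humerus 14 0.362 0.287 0.172 0.406 1.43

glance(report$regressions$humerus$tbsp)
#>       n chosen_degree  cv_mse  slope conf_low conf_high isometric_reference isometry_rejected r_squared
#> 1    55             4 0.00313 0.0946   0.0459     0.143               0.333 TRUE                  0.223
```

The simulated humeral table shows the ontogenetic signature the generator
encodes: BV/TV peaking in the 4–12-month group, DA rising from 0.195 to a
mid-0.3s plateau, TbSp widening monotonically while TbN declines. The TbSp
regression illustrates the isometry test: a fitted log–log slope of 0.095
[0.046, 0.143] excludes the +1/3 isometric reference, so spacing grows with
negative allometry in this simulated cohort. `plot_violin()`,
`plot_scaling()`, `plot_stereonet()` and `autoplot()` on a PCA give the
matching figures; `tidy()`/`glance()` methods return the fitted objects in
tabular form.

A config-driven orchestration layer (`pipeline_simulate()`,
`pipeline_measure()`, `pipeline_analyze()`, with a thin Rscript front-end
in `inst/cli/trabkit.R`) runs the same stages over directories of TIFF
stacks with manifests, per-specimen error capture and derived seeds.

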