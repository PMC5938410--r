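---
title: "Multiple-lesion symptom mapping: models, inference and validation design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiple-lesion symptom mapping: models, inference and validation design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the models

Lesion–symptom mapping asks which brain locations, when damaged, drive a
behavioral deficit. `mlsmap` targets cohorts in which two lesion types
co-occur — prototypically an acute ischemic lesion (AIL) and chronic
white matter hyperintensities (WMH) in stroke — and implements three
models over subjects-by-voxels binary lesion matrices on a common grid:

1. **Mass-univariate VLSM.** Per voxel, a pooled-variance two-sample
   t-test comparing the (norm-corrected) scores of lesioned vs intact
   subjects; negative t means lesioned subjects score lower. Voxels
   where either group has fewer than two subjects, or with zero pooled
   variance but unequal means, are flagged untestable rather than given
   infinite statistics.
2. **SVR-LSM.** A single ε-insensitive support vector regression from
   all voxel columns of one lesion type to the deficit score. The linear
   kernel's primal weight vector `β = X'λ` is the voxel map.
3. **SVR-MLSM.** The multiple-lesion extension: each voxel contributes
   one indicator column per lesion type, concatenated as `[X_AIL | X_WMH]`.
   Because a voxel has exactly one of three statuses (normal / AIL /
   WMH), the two columns of one voxel are never simultaneously 1. Both
   weight blocks are estimated in one model, so the map for each lesion
   type is conditional on the other's columns. Only the linear kernel is
   admitted for the multi-lesion model (the Taylor linearization that
   justifies rbf weight maps in the single-lesion case does not carry
   over to two normalization groups); requesting rbf is an error.

## Score preparation

Composition is fixed: ordinary-least-squares norm-correction of the raw
score on an intercept plus covariates (age, sex as 0/1, education
years); optionally OLS residualization on total lesion volume(s)
(volume-control strategy "regress_out"); then the deficit transform,
which is plain negation when the score is declared higher-is-better.
Negation is the minimal "linear transformation to a deficit index":
any other affine map changes neither weight ranks nor permutation p
beyond sign. Norm-correction is within-sample regression; normative
look-up tables are out of scope. Downstream permutation inference
shuffles the final deficit vector only.

## Volume control

Three strategies, as in the comparison the package is built around:

* `none`;
* `voxelwise`: each subject's entries in a lesion-type block are scaled
  by `1/sqrt(total lesion volume of that type)`; a subject with zero
  volume of one type gets an all-zero row (warned, not fatal);
* `regress_out`: binary design, volumes regressed out of the score
  instead. Only this strategy leaves `β_AIL` and `β_WMH` on directly
  comparable scales.

**Units for `1/sqrt(volume)`.** Volume is counted in voxels of the full
(unfiltered) mask. Any consistent unit changes the design only by a
per-block constant that the box constraint C absorbs, so the choice is
statistically irrelevant — but numerically it matters: voxel units keep
the linear-kernel diagonal near 1, so the C grid `2^-20…2^20` is
searched on a well-conditioned problem. With mm³ of 2 mm voxels the
kernel shrinks by ~10^3 and the useful C range migrates to the extreme
top of the grid, where the SVR dual is expensive to solve for any SMO
implementation.

## The SVR engine

No SVM library is available in the deployment environment, so the
solver is part of the package: sequential minimal optimization for the
ε-SVR dual with an equality-constrained (unregularized) intercept and
second-order working-set selection — the LIBSVM algorithm. The test
suite pins it, coefficient for coefficient, to frozen reference
solutions produced by an independent LIBSVM front end on fixed
fixtures, and additionally checks on each run that its primal objective
is never worse than a quadratic-programming route (`quadprog`).

Numerical choices:

* ε (tube half-width) defaults to 0.1 **on the fold-standardized
  deficit**; the deficit is z-scored inside each training set and
  predictions mapped back. β maps are reported on the standardized
  scale.
* KKT stopping tolerance 1e-8 for single fits; 1e-6 inside grid sweeps.
* LOOCV grid sweeps run each fold as an ascending-C path with warm
  starts and a per-solve iteration cap (3000; 5000 in the prediction
  ladder). The cap only bites in the huge-C tail, where the model is a
  heavy overfit whose held-out accuracy is poor and never selected —
  there even LIBSVM needs 10^8 iterations on low-rank kernels (verified
  against a reference implementation). Capped solves are deterministic,
  so results are exactly reproducible.
* Ties in grid selection go to the smaller C, then smaller γ.
* **Degenerate-accuracy guard.** Held-out LOOCV predictions whose spread
  falls below the fold-statistic noise floor (`sd(y)/M`) are treated as
  constant and their accuracy as undefined. Without this, the Pearson
  correlation of essentially-constant predictions is an artifact of each
  training fold's mean/median depending on the excluded label, and can
  reach |r| ≈ 0.7 on pure noise at the tiny-C end of the grid —
  potentially hijacking model selection.

## Permutation inference

Hyperparameters are selected once on the unshuffled data and held fixed
across permutations; the deficit vector is shuffled `P` times (1000 by
convention), the SVR is refit, and pseudo weight maps `X'λ` are
extracted. The per-voxel p is `(1 + #{pseudo ≥ real}) / (P + 1)` —
one-sided toward positive weights, because under the deficit convention
damage that worsens behavior earns positive weight; ties count against
significance, and the +1 smoothing keeps p away from zero. In the
two-lesion model both blocks share each shuffle, so AIL and WMH maps
are tested at the same significance level. For VLSM the correction is
maxT (Westfall–Young): each permutation contributes its maximum |t|
across voxels, which controls familywise error; a voxelwise-uncorrected
mode and an exhaustive-enumeration mode (all M! shuffles, tiny cohorts)
exist for comparison and testing.

Clusters are maximal connected components of the thresholded map
(p < 0.05, 26-connectivity by default, no minimum size). Atlas overlap
reports count region size, tested voxels, significant voxels (n, % of
region) and subjects whose lesion touches the region; significant
voxels outside every label land in an "unlabeled" row so the counts
always partition.

## SVOI prediction ladders

The significant clusters of one model and lesion type, merged into one
region, define each subject's SVOI: the volume of their full
(unfiltered) lesion mask inside the region. Nested linear-SVR models
from predictor sets (demographics; + AIL volume; + WMH volume; + SVOIs)
to the **raw** score are compared by LOOCV Pearson accuracy, with
predictors z-scored inside each training fold. Nothing from the
held-out subject reaches training — the suite probes this by perturbing
a held-out subject's score and asserting its own held-out prediction is
unchanged. When SVOIs come from clusters estimated on the same cohort,
the ladder is an internal comparison, not external validation; the
package says so at run time.

# The synthetic cohort generator

The generator exists so that every stage has a parameter-recovery test
surface; no patient data ship with the package.

* **Brain**: an ellipsoid (90% of each half-extent) on a configurable
  grid; default worlds use 20×20×20 voxels of 2 mm.
* **Lesions**: unions of spheres. Every voxel of a lesion type's
  spatial-prior support independently becomes a sphere center with a
  small probability, calibrated by root-finding on the exact coverage
  identity so that the mean per-voxel prevalence over the support equals
  the configured target; radii are uniform in a range (default 2–3
  voxels). Spatial priors distinguish the types (e.g. a deep AIL focus
  vs a periventricular-like WMH distribution).
* **Exclusivity**: where a subject's AIL and WMH overlap, AIL wins —
  the acute event masks the chronic one on imaging.
* **Scores**: `base − Σ truth_AIL·x − Σ truth_WMH·x + covariate effects
  + N(0, noise_sd)`, clipped to a 0–30 range. Defaults are MoCA-like:
  base 27, noise sd 2, age in U(50, 82) at −0.12 points/year, education
  in U(0, 14) at +0.30 points/year, sex Bernoulli(0.42) with no effect.
  All randomness flows from one seed through named substreams, so
  cohorts are bit-reproducible and changing, say, the permutation count
  never perturbs the masks.

## The reference planted world

`planted_cohort_config()` freezes the validation world used by the
acceptance suite: 60 subjects; Gaussian spatial priors (σ = 4 voxels)
centered on two disjoint strategic spheres of radius 2 voxels (33
voxels ≈ 0.26 ml); mean prior prevalence 0.15, which puts region
prevalence around 15–20 of 60 subjects; planted per-voxel weights decay
from the region center (Gaussian, σ = 1.25 voxels) and are rescaled so
that the mean score penalty among subjects lesioned in the region
equals 1.5 × noise sd. The rescaling is computed from the cohort the
seed itself generates — masks are independent of the weights, so the
calibration is exact and reproducible.

Two design points deserve emphasis because they were learned from
pilots, not assumed:

* **The strategic region must be at least as large as the lesion
  blur.** With spheres of radius 2–3 voxels as lesions, any voxel
  within one blob radius of a strategic focus carries nearly the same
  information as the focus itself. If the planted region is smaller
  than that blur, asking the global |β| maximum to land inside it is a
  coin flip *for any method* — not a defect of the estimator. The
  frozen region (radius 2, with center-weighted effects and the lesion
  prior centered on it) makes the confusion zone part of the region.
* **Recovery metrics need the prevalence peak to coincide with the
  effect peak.** Raw SVR weights are not prevalence-normalized, so in a
  uniform-prior world high-prevalence nuisance voxels can out-weigh the
  planted focus even when the permutation p map ranks correctly.
  Centering each lesion type's prior on its strategic region is both
  anatomically sensible (strategic damage sits where that lesion type
  concentrates) and what makes the peak criterion informative.

What a green planted-recovery test establishes: on blob-shaped,
moderately prevalent, additively acting lesions with Gaussian noise and
linear covariate effects, the full pipeline (filter → voxelwise volume
control → LOOCV-trained linear SVR → permutation p) ranks truly
strategic voxels far above noise voxels (ROC AUC ≥ 0.8) and peaks
inside the planted regions. What it does not establish: performance on
real vascular-territory lesion shapes, registration error, non-additive
or threshold effects, longitudinal WMH progression, or cohorts whose
lesion coverage is too sparse to test.

## Null-calibration world

False-positive calibration uses independent Bernoulli lesion tensors
(exactly 500 voxels per lesion type, per-voxel prevalence uniform in
0.1–0.4, 60 subjects) with scores drawn independently of the lesions.
Geometry is irrelevant under the global null, and this construction
hits the stated matrix sizes exactly. Expected behavior, verified by
the acceptance suite over 20 replicates: the mean fraction of voxels
with permutation p < 0.05 stays near the nominal rate (0.02–0.09 band,
reflecting the conservative tie rule and Monte-Carlo noise at P = 200),
and maxT VLSM's familywise error rate stays at or below ~5–10%.

## LOOCV sanity fixtures

The noiseless-recovery premise ("best-grid LOOCV accuracy ≥ 0.99 when
the deficit is an exact linear function of the design") holds only for
determined systems: with more voxels than subjects the minimum-norm SVR
spreads weight across correlated columns and held-out accuracy
plateaus below 0.99 for any solver. The fixture therefore uses 60
subjects × 30 voxels. The shuffled-label check (|accuracy| < 0.4 in ≥
95% of runs at M = 60) uses the same design; its threshold reflects the
max-over-41-grid-points selection bias on a null Pearson r with sd
≈ 1/√60.

# Known limitations

* The simulator's lesions are unions of spheres; real lesion shape,
  spatial covariance and registration artifacts are not emulated.
* Permutation inference assumes exchangeability of subjects after
  norm-correction; strong residual confounding violates it.
* LOOCV accuracy at M ≈ 60 is itself noisy (sd ≈ 0.13 under the null);
  small accuracy differences between models should not be
  over-interpreted — the ladder reports deltas, not tests of deltas.
* Solver solutions in the extreme-C overfit regime are iteration-capped
  approximations (deterministic, documented above).
* SVOI ladders on the discovery cohort are internal comparisons; no
  external validation machinery is provided.
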