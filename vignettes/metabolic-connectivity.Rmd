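---
title: "Metabolic connectivity and multimodal group analysis: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic connectivity and multimodal group analysis: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaconn)
```

`metaconn` analyses cohorts of spatially normalized brain volumes — FDG-PET
standardized uptake value ratio (SUVr) maps and gray-matter density maps —
together with tabular volumetric measures, to characterize and discriminate
dementia variants (behavioral-variant AD, typical amnestic AD,
behavioral-variant FTD, controls). This vignette explains the statistical
models, the tunable parameters and their defaults, the synthetic cohort the
tests run on, and the numerical choices made where conventions diverge.

## Spatial data model

All volumes in one analysis live on a single `vol_grid`: shape, voxel
spacing (mm) and a 4x4 affine mapping zero-based voxel indices to world
RAS mm (MNI convention). Two grids are equal iff shape matches and spacing
and affine agree within 1e-6 mm; every analysis function checks this and
refuses mismatched grids. A nearest-neighbour/trilinear `resample_volume()`
exists but is never applied implicitly — silent misregistration is the
classic failure mode this guards against.

Seed regions are spheres in world coordinates; a voxel belongs to the
sphere iff its *centre* is within the radius (no partial-volume weighting,
matching common sphere-ROI toolkit behaviour). The canonical registry pins
four 4-mm seeds at their published MNI coordinates: PCC (−8, −56, 26),
amPFC (6, 52, −2), right frontoinsula (36, 18, 4), right DLPFC
(44, 36, 20). The amPFC coordinate has positive x although it is
conventionally described as left-sided; the coordinate, not the label, is
authoritative here. Continuous template maps are binarized with a *strict*
`value > threshold` rule (default r = 0.2), so voxels exactly at the
threshold are excluded — the reproducible reading of "thresholded at".

Gaussian smoothing (default 12 mm FWHM for PET) is separable with
`sigma = fwhm / (spacing * sqrt(8 log 2))` per axis and symmetric-reflection
boundaries. Reflection with a symmetric kernel yields a symmetric smoothing
operator, so constants are exactly invariant and the global mean is
preserved to machine precision — a property the tests assert at 1e-10.

## Voxelwise group contrasts

Group comparisons fit, independently at every in-mask voxel, the linear
model `y = X b + e` with a cell-means design: one indicator column per
diagnostic group plus mean-centred covariates (age and sex for PET; plus
scanner field strength and intracranial volume for gray-matter analyses).
Cell-means coding is a full-rank reparameterization of
intercept-plus-indicators; pairwise contrasts are `+1/−1` on two group
columns, and contrast t-values are unaffected by the centring. Covariates
that are constant within the analyzed subjects are dropped (there is
nothing to adjust for, and a centred constant would be identically zero).

The contrast map stores `t = c'b / sqrt(s^2 c'(X'X)^{-1} c)` with
`df = n − rank(X)`. Thresholding follows the two regimes used for
patient-vs-control and patient-vs-patient maps:

- **uncorrected**: voxel passes iff its Student-t p-value (one- or
  two-sided) is below alpha (default 0.001 between patient groups);
- **permutation FWE**: a max-statistic null is built by the Freedman–Lane
  scheme — the outcome is residualized against the nuisance design (the
  full design projected onto the null space of the contrast), residual rows
  are permuted, the nuisance fit is added back, the full model refit, and
  the maximum statistic recorded. A voxel passes iff
  `(1 + #{null >= t}) / (n_perm + 1) <= alpha`. This is a deliberate design
  choice: the classical toolchain uses parametric random-field FWE, but
  permutation is distribution-free and exactly specifiable, at the cost of
  slightly different thresholds. At least `1/alpha` permutations are
  required (200 is the default for alpha = 0.05).

Surviving voxels are grouped into connected components with
18-neighbourhood connectivity (faces + edges, the dominant convention of
the source toolchain); clusters smaller than the extent threshold
(k = 50 voxels by default) are discarded. Patient-vs-control contrasts are
run one-sided in the hypometabolism/atrophy direction; patient-vs-patient
contrasts two-sided. Binary significance maps can be combined into an
integer-coded overlay volume (each mask contributes one bit) to read off
regional overlap between contrasts.

## Interregional covariance analysis and goodness-of-fit

Metabolic connectivity is estimated *across subjects* within one group:
for seed ROI s (4-mm sphere intersected with the gray-matter mask), each
voxel v is regressed on the per-subject seed mean with age and sex
adjustment,

    y_v,i = b0 + b1 seed_i + b2 age_i + b3 sex_i + e ,

and the map stores the t-statistic of `b1`. One covariance map exists per
(group, seed); its sampling unit is the subject, so group size must exceed
the covariate count by at least 3.

The goodness-of-fit of a covariance map to a binary network template is

    GOF = T_inside − T_outside ,

the difference between the mean t over template voxels and the mean t over
the remaining analysis-mask voxels, computed on the *unthresholded* map
(display thresholds govern figures, not the score; a thresholded variant is
a caller option). "Outside" means analysis mask minus template, not the
whole grid — including out-of-brain voxels would dilute T_outside
arbitrarily. GOF is exactly invariant to adding a constant to the map and
linear in the map, both asserted in the tests. The canonical pairing scores
the PCC seed against the posterior DMN template, amPFC against anterior
DMN, frontoinsula against the salience network, and DLPFC against the
executive control network. No inferential statistics are attached to GOF
scores: the covariance maps are group-level objects with no subject-level
replication.

Between-group connectivity differences use the interaction model on the
pooled pair of groups,

    y_v = a_A 1[A] + a_B 1[B] + c_A seed 1[A] + c_B seed 1[B]
          + b_age age + b_sex sex + e ,

whose contrast `c_A − c_B` tests equality of the seed slopes. Age and sex
effects are shared between groups (the group-specific-slope convention is
ambiguous in the field; shared effects use the available degrees of freedom
more efficiently at these group sizes). Results are reported at
uncorrected p < 0.001 and p < 0.05, two-sided, without extent threshold.

## Features and discrimination

Subject-level scalar features feed single-feature ROC analyses:

- **network ratios** — mean of the subject's map inside a template divided
  by the mean outside (within the analysis mask), an index of relative
  hypometabolism/atrophy that is invariant to global scaling;
- **signature-ROI means** — means over AD-signature (temporoparietal,
  parietal) and FTD-signature composite masks;
- **tabular features** — bilateral amygdala volume (left and right summed;
  laterality carries no signal here) and per-lobe WMH burdens, the
  weighted sum over the four concentric layers (weights default to
  uniform; the weighting in the source convention is unspecified, so it is
  exposed as a parameter).

AUC uses the Mann–Whitney formulation with midrank ties, always reported
for the fixed orientation positive-group-over-negative-group (values below
0.5 mean the negative group scores higher). The 95% CI and the two-sided
p-value against 0.5 use the DeLong variance estimator (deterministic,
standard; the source's CI method is unstated), clipped to [0, 1]. Features
are ranked by the orientation-free score `max(AUC, 1 − AUC)`; no
multiple-comparison adjustment is applied across features, matching the
per-feature reporting convention.

## Volumetric statistics

Subcortical volumes (cm^3, bilateral sums) are compared by OLS per
structure on group indicators plus age, sex, field strength and
intracranial volume, with Wald t contrasts for every group pair.
Bonferroni correction runs over the full family — structures times pairwise
contrasts — and the family size is printed in the output so the correction
is auditable.

Regional WMH volumes are strictly positive and right-skewed, hence gamma
GLMs with log link, the same covariates, and dispersion estimated by
Pearson chi-square over residual df; pairwise Wald contrasts use a t
reference distribution on the residual df. The group contrast estimate is
a log multiplicative factor. Exact zeros (possible in low-burden regions)
are shifted by half the smallest positive observed value in that region,
and the offset is recorded in the output. No multiplicity correction is
applied, reflecting the strong correlation among regional volumes.
Control-normalization divides each region by the control-group mean so
values read as multiplicative factors; because the log link absorbs a
per-region constant into the intercept, normalization leaves group
contrasts and p-values unchanged (asserted in the tests).

## The synthetic cohort

Real imaging of this kind is shared on request only, so the package ships
a generator that produces cohorts with exactly the statistical structure
the pipeline assumes. Subject i of group g receives

    v_i = 1 − depth_g(pattern) + sum_k lambda_{g,k} z_{ik} 1[network_k]
          + beta_age (age_i − mean age) + beta_sex sex_i + eps ,

with `z_ik ~ N(0,1)` latent loadings and iid `N(0, 0.05^2)` voxel noise,
multiplied by a per-subject global uptake scale `exp(N(0, 0.1^2))` that
SUVr normalization (against a reference-region box untouched by the
patterns) removes again. Rank-1 latent-network covariance was chosen over
explicit voxel covariance matrices because it is scalable and is precisely
the structure seed-based covariance analysis is designed to detect. The
four network templates are disjoint axis-aligned boxes, each containing
its canonical seed sphere — geometric stand-ins, not anatomy.

Defaults are fixed once and mirror the study conditions: group sizes
29/28/28/34; age and sex moments per group from the published cohort
table; hypometabolism depths bvAD pDMN 0.15 / aDMN 0.03 / SN 0.02, tAD
pDMN 0.15, bvFTD SN 0.15 / aDMN 0.10 (SUVr units); couplings lambda chosen
so that the anterior-DMN coupling is high in bvAD and bvFTD (0.06) but low
in tAD (0.03), reproducing the qualitative GOF ordering; subcortical
deficits such that the amygdala (tAD −18%, bvAD −3% of a 3.4 cm^3 control
mean, 10% CV) is the dominant bvAD-vs-tAD discriminator while hippocampal
loss (−20%) is shared — effect sizes reasoned out in standard-deviation
units before any test was run; WMH gamma shape 2 with layer-decreasing
baselines and patient bgit factors 1.4–1.8. The working grid is
32 x 38 x 32 at 4 mm (~39k voxels), small enough that the full pipeline
with hundreds of permutations runs in minutes; it is configurable up to
2-mm MNI dimensions.

What the generator does *not* emulate: PET physics and partial-volume
effects, anatomically shaped networks, spatially correlated noise, and
registration error. Passing tests therefore demonstrate the statistical
machinery — calibration, recovery, orderings — on data satisfying the
model's assumptions, not performance on real scans.

## Numerical choices and degenerate inputs

- Voxels with an exactly zero response (or an exact linear fit) would give
  t = 0/0; these are reported as 0.
- `threshold_spec` validates `0 < alpha < 1`, `extent_k >= 0`; FWE
  thresholding refuses fewer than `1/alpha` permutations.
- The permutation p-value convention `(1 + #{null >= t}) / (n_perm + 1)`
  makes the familywise error exactly the chosen alpha under
  exchangeability and never returns p = 0.
- DeLong variance is undefined when a group has a single observation; the
  CI then falls back to [0, 1] with an NA p-value. A pooled-constant
  feature warns and returns AUC 0.5.
- Ties in AUC are handled by midranks, so `AUC(a,b) + AUC(b,a) = 1`
  exactly.
- Gamma GLM fits run up to 200 IRLS iterations; non-convergence is an
  error naming the region rather than a silent result.

## Problem sizes used by the test-suite

Unit tests run on handcrafted grids of a few hundred voxels. The
statistical validation uses: 200 null simulations of 250 voxels with 199
permutations each for familywise-error calibration; 20,000 pooled null
voxels for the uncorrected rate; 300 replicates for tabular type-I error;
20–40 simulation seeds for recovery of planted network couplings, slope
differences, WMH factors and the amygdala ranking; n = 500 per group for
the Gaussian closed-form AUC limit. These sizes were chosen to give
binomial standard errors comfortably inside the asserted tolerances.

## Known limitations

- Permutation FWE will not numerically match parametric random-field
  thresholds on the same data; differences are expected to be small but
  are not bounded here.
- The cell-means + shared-covariate interaction model is one of several
  defensible parameterizations of "seed slope per group"; per-group
  covariate effects are not implemented.
- GOF has no inferential wrapper by design; comparing GOF values between
  groups is descriptive.
- The synthetic WMH tables draw regions independently; real lobar volumes
  are strongly correlated, which matters only for multiplicity behaviour
  across regions, not for the per-region GLM that is tested.
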