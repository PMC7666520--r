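# metaconn

Multimodal neuroimaging group analysis for dementia variants: voxel-wise
FDG-PET hypometabolism contrasts, seed-based metabolic covariance with
goodness-of-fit scoring against functional network templates, connectivity
interaction contrasts, network-ratio / ROI features with pairwise ROC
discrimination, and tabular comparisons of subcortical and white-matter-
hyperintensity (WMH) volumes.

## The problem

The behavioral variant of Alzheimer's disease (bvAD) presents with
frontal-type behavioral symptoms but, paradoxically, shows mostly
temporoparietal atrophy. Disentangling it from typical amnestic AD (tAD) and
behavioral-variant frontotemporal dementia (bvFTD) calls for markers beyond
structural MRI: glucose metabolism, metabolic network connectivity, and
subcortical / white-matter measures. `metaconn` implements that analysis
stack as a reusable, tested R pipeline, exercised end-to-end on a
deterministic synthetic cohort generator (real patient imaging of this kind
is typically available only on request).

## What it computes

- **SUVr preparation** — reference-region (pons) normalization
  (`compute_suvr`), gray-matter-masked ROI extraction, 12-mm Gaussian
  smoothing, NIfTI I/O on a strict shared-grid data model.
- **Voxelwise contrasts** — per-voxel ANCOVA of SUVr (or gray-matter) maps
  with age/sex covariates; for a contrast vector c the map stores
  t = c'b / sqrt(s^2 c'(X'X)^-1 c). Thresholding at p < 0.05 with
  max-statistic permutation FWE (Freedman–Lane residual scheme) or
  p < 0.001 uncorrected, extent threshold k = 50 voxels, 18-connectivity
  clusters, and multi-contrast overlay maps.
- **Metabolic connectivity** — interregional correlation analysis (IRCA):
  per group, every voxel is regressed on the mean SUVr of a 4-mm seed
  sphere (PCC, amPFC, right frontoinsula, right DLPFC), adjusted for age
  and sex; the seed-slope t-map is scored against binary network templates
  (pDMN, aDMN, salience, executive control) by
  GOF = T_inside − T_outside. Between-group differences in connectivity are
  tested by a voxelwise seed-slope interaction contrast.
- **Discrimination** — subject-level features (within/outside-network SUVr
  and gray-matter ratios, signature-ROI means, amygdala volume, lobar WMH
  burdens) ranked by pairwise ROC AUC with DeLong confidence intervals.
- **Volumetrics** — subcortical volumes via linear models with age, sex,
  field strength and intracranial volume as covariates (Bonferroni over the
  full structure-by-contrast family); regional WMH volumes via gamma GLMs
  with log link, with control-normalization to multiplicative factors.
- **Synthetic cohort** — four diagnostic groups (bvAD 29, tAD 28, bvFTD 28,
  CN 34) with group-specific regional hypometabolism, rank-1 latent-network
  covariance, age/sex effects, Gaussian voxel noise, and gamma-distributed
  regional WMH tables; fully deterministic given one seed.

## Worked example

```r
library(metaconn)

cfg <- sim_config(rng_seed = 42)
sim <- suvr_normalize_cohort(simulate_fdg_cohort(cfg))

idx <- split(seq_len(nrow(sim$cohort)), sim$cohort$group)
gof <- gof_profile(lapply(idx, function(i) sim$volumes[i]),
                   lapply(idx, function(i) sim$cohort[i, , drop = FALSE]),
                   sim$templates, sim$seeds, sim$gm_mask,
                   matched_only = TRUE)
subset(gof, network %in% c("aDMN", "pDMN"))
#>  group  seed network t_inside t_outside  gof
#>   bvAD   PCC    pDMN     4.40   0.00195 4.39
#>   bvAD amPFC    aDMN     5.77  -0.01483 5.78
#>  bvFTD   PCC    pDMN     2.21   0.04541 2.16
#>  bvFTD amPFC    aDMN     7.04   0.11784 6.92
#>     CN   PCC    pDMN     4.64  -0.08096 4.72
#>     CN amPFC    aDMN     4.09  -0.01696 4.11
#>    tAD   PCC    pDMN     4.08  -0.10773 4.19
#>    tAD amPFC    aDMN     1.95   0.02175 1.93
```

The anterior-DMN GOF is high for bvAD and bvFTD but low for tAD, while the
posterior-DMN GOF is high for bvAD, tAD and controls but low for bvFTD —
the anterior default-mode involvement that sets bvAD apart from typical AD.
Ranking single-feature discriminators for bvAD vs. tAD:

```r
tabs <- simulate_volume_tables(cfg, cohort = sim$cohort)
amyg <- setNames(tabs$subcortical[, c("subject_id", "amygdala")],
                 c("subject_id", "amygdala_cm3"))
feats <- assemble_feature_table(
  sim$cohort, list(fdg = sim$volumes), templates = sim$templates,
  rois = generate_signature_rois(sim$grid, sim$templates),
  analysis_mask = sim$gm_mask,
  volume_features = merge(amyg, wmh_lobar_burden(tabs$wmh),
                          by = "subject_id"))
rank_discriminators(feats, c("bvAD", "tAD"), top_k = 3)
#>            feature   auc ci_low ci_high direction score
#>       amygdala_cm3 0.836  0.734   0.939   pos>neg 0.836
#>       wmh_temporal 0.297  0.162   0.432   pos<neg 0.703
#>  fdg_FTD_signature 0.310  0.166   0.455   pos<neg 0.690
```

Bilateral amygdala volume (larger in bvAD) is the strongest bvAD-vs-tAD
discriminator, AUC 0.84 [0.73–0.94]. `run_pipeline(run_config(...))` runs
every stage end-to-end and writes NIfTI maps, CSV tables and a JSON run
report.

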