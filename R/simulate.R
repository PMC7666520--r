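#' Default simulation grid
#'
#' 32 x 38 x 32 voxels at 4 mm isotropic spacing, centred near the world
#' origin with MNI-like axis ranges (x -62..62, y -76..72, z -50..74 mm), so
#' the canonical network seed coordinates fall inside the volume. Desk-scale:
#' about 39k voxels, small enough that the full pipeline with hundreds of
#' permutations runs in minutes.
#'
#' @return a `vol_grid`.
#' @export
default_sim_grid <- function() {
  aff <- diag(4)
  diag(aff)[1:3] <- 4
  aff[1:3, 4] <- c(-62, -76, -50)
  vol_grid(c(32L, 38L, 32L), spacing = c(4, 4, 4), affine = aff)
}

# world-mm boxes (closed intervals) for the four synthetic network templates;
# each contains its canonical seed sphere and the boxes are pairwise disjoint
template_boxes <- function() {
  list(
    pDMN = rbind(x = c(-24, 8),  y = c(-72, -40), z = c(10, 42)),
    aDMN = rbind(x = c(-10, 22), y = c(36, 68),   z = c(-18, 14)),
    SN   = rbind(x = c(24, 48),  y = c(2, 34),    z = c(-12, 12)),
    ECN  = rbind(x = c(30, 58),  y = c(22, 50),   z = c(14, 38))
  )
}

box_mask <- function(grid, box) {
  xyz <- grid_coordinates(grid)
  m <- xyz[, 1] >= box[1, 1] & xyz[, 1] <= box[1, 2] &
       xyz[, 2] >= box[2, 1] & xyz[, 2] <= box[2, 2] &
       xyz[, 3] >= box[3, 1] & xyz[, 3] <= box[3, 2]
  binary_mask(grid, m)
}

#' Generate synthetic network templates
#'
#' Four pairwise-disjoint axis-aligned box masks standing in for canonical
#' resting-state network templates: pDMN (posterior), aDMN (anterior medial
#' prefrontal), SN (right frontoinsular) and ECN (right dorsolateral
#' prefrontal). Each box fully contains the 4-mm sphere around its paired
#' canonical seed coordinate. These are geometric stand-ins, not anatomical
#' templates.
#'
#' @param grid a `vol_grid` covering the MNI-like ranges of
#'   [default_sim_grid()].
#' @return named list of `network_template`s.
#' @export
generate_network_templates <- function(grid = default_sim_grid()) {
  boxes <- template_boxes()
  seeds <- default_seed_registry()
  pairing <- default_network_seed_pairing()
  out <- list()
  for (nm in names(boxes)) {
    m <- box_mask(grid, boxes[[nm]])
    if (mask_count(m) == 0L)
      stop(sprintf("geometry error: grid too small for template '%s'", nm),
           call. = FALSE)
    sphere <- make_sphere_mask(grid, seeds[[pairing[[nm]]]])
    if (mask_count(mask_difference(sphere, m)) > 0L)
      stop(sprintf("geometry error: seed sphere not contained in template '%s'",
                   nm), call. = FALSE)
    out[[nm]] <- network_template(nm, m, source_label = "synthetic box template")
  }
  for (a in seq_along(out)) for (b in seq_len(a - 1L))
    if (mask_count(mask_intersect(out[[a]]$mask, out[[b]]$mask)) > 0L)
      stop("geometry error: templates overlap", call. = FALSE)
  out
}

#' Generate synthetic disease-signature ROIs
#'
#' Geometric stand-ins for the AD temporoparietal, AD parietal and FTD
#' (anterior cingulate / frontoinsular / striatal / frontopolar composite)
#' signature regions, built from the synthetic template geometry:
#' AD_temporoparietal = the posterior box, AD_parietal = its superior half,
#' FTD_signature = the union of the anterior and frontoinsular boxes.
#'
#' @param grid a `vol_grid`.
#' @param templates templates from [generate_network_templates()].
#' @return named list of `signature_roi`s.
#' @export
generate_signature_rois <- function(grid = default_sim_grid(),
                                    templates = generate_network_templates(grid)) {
  pd <- template_boxes()$pDMN
  par_box <- pd
  par_box[3, 1] <- mean(pd[3, ])   # superior half in z
  list(
    AD_temporoparietal = signature_roi("AD_temporoparietal",
                                       templates$pDMN$mask),
    AD_parietal = signature_roi("AD_parietal", box_mask(grid, par_box)),
    FTD_signature = signature_roi(
      "FTD_signature", mask_union(templates$aDMN$mask, templates$SN$mask))
  )
}

#' Reference-region (pons stand-in) mask for SUVr normalization
#'
#' A small box inferior-posterior to the templates, untouched by the
#' simulated disease patterns and network loadings.
#'
#' @param grid a `vol_grid`.
#' @return a `binary_mask`.
#' @export
generate_reference_mask <- function(grid = default_sim_grid()) {
  m <- box_mask(grid, rbind(x = c(-8, 8), y = c(-40, -20), z = c(-50, -34)))
  if (mask_count(m) == 0L)
    stop("geometry error: grid too small for the reference region",
         call. = FALSE)
  m
}

#' Simulation configuration
#'
#' Holds every knob of the synthetic cohort: group sizes matching the
#' published cohort (bvAD 29, tAD 28, bvFTD 28, CN 34), per-group regional
#' hypometabolism depths (in SUVr units, subtracted inside the named
#' template's box), per-group network coupling strengths (SUVr change per
#' standard deviation of the subject's latent network loading), additive
#' age/sex effects, iid Gaussian voxel noise, a per-subject global uptake
#' scale (removed again by SUVr normalization), and the gamma model of the
#' regional WMH tables.
#'
#' @param grid a `vol_grid` (default [default_sim_grid()]).
#' @param group_sizes named integer vector (each >= 4).
#' @param ages named list group -> c(mean, sd) in years.
#' @param sex_p_male named numeric, probability male (coded 1).
#' @param p_15t named numeric, probability of 1.5 T field strength.
#' @param depths named list group -> named numeric (template -> SUVr depth).
#' @param lambda named list group -> named numeric (template -> coupling).
#' @param beta_age SUVr change per year of (centred) age.
#' @param beta_sex SUVr offset for sex = 1.
#' @param noise_sd iid voxel noise SD (SUVr units, > 0).
#' @param uptake_scale_sd SD of the per-subject log global uptake scale.
#' @param wmh_shape gamma shape of regional WMH volumes.
#' @param wmh_layer_means baseline mean WMH volume (cm^3) per concentric
#'   layer 1 (periventricular) .. 4 (juxtacortical).
#' @param wmh_bgit_mean baseline mean WMH volume of the basal
#'   ganglia/infratentorial region.
#' @param wmh_factors named list group -> named numeric of multiplicative
#'   regional factors (unnamed regions default to 1).
#' @param subcortical_means named numeric: control-mean bilateral volumes
#'   (cm^3) per structure.
#' @param subcortical_deficits named list group -> named numeric fractional
#'   deficits relative to the control mean.
#' @param subcortical_cv coefficient of variation of structure volumes.
#' @param icv_mean,icv_sd intracranial volume distribution (cm^3).
#' @param icv_slope fractional volume change per fractional ICV deviation.
#' @param rng_seed integer seed; every generator output is a pure function
#'   of the configuration including this seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(grid = default_sim_grid(),
                       group_sizes = c(bvAD = 29L, tAD = 28L, bvFTD = 28L,
                                       CN = 34L),
                       ages = list(bvAD = c(64.4, 9.4), tAD = c(63.0, 9.3),
                                   bvFTD = c(64.6, 4.4), CN = c(64.9, 9.9)),
                       sex_p_male = c(bvAD = 0.59, tAD = 0.55, bvFTD = 0.70,
                                      CN = 0.65),
                       p_15t = c(bvAD = 17 / 29, tAD = 22 / 28,
                                 bvFTD = 14 / 28, CN = 22 / 34),
                       depths = list(
                         bvAD = c(pDMN = 0.15, aDMN = 0.03, SN = 0.02),
                         tAD = c(pDMN = 0.15),
                         bvFTD = c(SN = 0.15, aDMN = 0.10),
                         CN = numeric(0)),
                       lambda = list(
                         bvAD = c(pDMN = 0.06, aDMN = 0.06, SN = 0.03,
                                  ECN = 0.04),
                         tAD = c(pDMN = 0.06, aDMN = 0.03, SN = 0.02,
                                 ECN = 0.05),
                         bvFTD = c(pDMN = 0.03, aDMN = 0.06, SN = 0.06,
                                   ECN = 0.05),
                         CN = c(pDMN = 0.06, aDMN = 0.04, SN = 0.04,
                                ECN = 0.04)),
                       beta_age = -0.002, beta_sex = 0.02,
                       noise_sd = 0.05, uptake_scale_sd = 0.1,
                       wmh_shape = 2,
                       wmh_layer_means = c(1.5, 0.8, 0.4, 0.2),
                       wmh_bgit_mean = 0.6,
                       wmh_factors = list(
                         bvAD = c(bgit = 1.8, temporal_right_l4 = 1.5),
                         tAD = c(bgit = 1.4, temporal_left_l4 = 1.5),
                         bvFTD = c(bgit = 1.8, temporal_left_l4 = 1.5,
                                   frontal_left_l4 = 1.4,
                                   frontal_right_l4 = 1.4),
                         CN = numeric(0)),
                       subcortical_means = c(amygdala = 3.4,
                                             nucleus_accumbens = 1.0,
                                             caudate = 6.8, putamen = 9.8,
                                             globus_pallidus = 3.6,
                                             hippocampus = 7.4,
                                             thalamus = 15.2),
                       subcortical_deficits = list(
                         bvAD = c(hippocampus = 0.20, putamen = 0.10,
                                  caudate = 0.10, thalamus = 0.10,
                                  amygdala = 0.03, nucleus_accumbens = 0.08),
                         tAD = c(hippocampus = 0.20, amygdala = 0.18,
                                 nucleus_accumbens = 0.15, thalamus = 0.10,
                                 putamen = 0.05, caudate = 0.05),
                         bvFTD = c(amygdala = 0.15, nucleus_accumbens = 0.15,
                                   caudate = 0.15, putamen = 0.15,
                                   globus_pallidus = 0.15,
                                   hippocampus = 0.15, thalamus = 0.15),
                         CN = numeric(0)),
                       subcortical_cv = 0.10,
                       icv_mean = 1450, icv_sd = 120, icv_slope = 0.5,
                       rng_seed = 1L) {
  if (any(group_sizes < 4L)) stop("group sizes must be >= 4", call. = FALSE)
  if (!is.finite(noise_sd) || noise_sd <= 0)
    stop("noise_sd must be > 0", call. = FALSE)
  cfg <- as.list(environment())
  structure(cfg, class = "sim_config")
}

# deterministic per-stage child seed (kept within 32-bit integer range)
child_seed <- function(seed, k) (as.numeric(seed) * 7 + k * 1009) %% 2^31

simulate_demographics <- function(config) {
  groups <- names(config$group_sizes)
  rows <- list()
  for (g in groups) {
    n <- config$group_sizes[[g]]
    age <- pmin(95, pmax(45, stats::rnorm(n, config$ages[[g]][1],
                                          config$ages[[g]][2])))
    sex <- stats::rbinom(n, 1, config$sex_p_male[[g]])
    fs <- ifelse(stats::runif(n) < config$p_15t[[g]], 1.5, 3)
    icv <- pmax(900, stats::rnorm(n, config$icv_mean, config$icv_sd))
    rows[[g]] <- data.frame(
      subject_id = sprintf("%s_%03d", g, seq_len(n)), group = g,
      age = age, sex = sex, field_strength_t = fs, icv_cm3 = icv,
      stringsAsFactors = FALSE)
  }
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Simulate an FDG-PET cohort with latent-network covariance
#'
#' Subject i of group g receives the volume
#' `baseline(1) - depth_g(pattern) + sum_k lambda_{g,k} z_{ik} 1[network_k]
#'  + beta_age (age_i - mean age) + beta_sex sex_i + eps`,
#' with `z_ik ~ N(0,1)` latent network loadings (rank-1 covariance per
#' network, exactly the structure seed-based covariance analysis assumes) and
#' iid `N(0, noise_sd^2)` voxel noise, then multiplied by a per-subject
#' global uptake scale `exp(N(0, uptake_scale_sd^2))` which SUVr
#' normalization removes again. Deterministic given `config$rng_seed`.
#'
#' @param config a `sim_config`.
#' @return list: `cohort` (data.frame), `volumes` (named list subject_id ->
#'   uptake `scalar_volume`), `templates`, `seeds`, `gm_mask` (analysis
#'   mask), `reference_mask` (pons stand-in), `grid`, `latent` (matrix of
#'   the z loadings, for diagnostics), `config`.
#' @export
simulate_fdg_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  grid <- config$grid
  templates <- generate_network_templates(grid)
  seeds <- default_seed_registry()
  set.seed(child_seed(config$rng_seed, 1L))
  cohort <- simulate_demographics(config)
  n <- nrow(cohort)
  nvox <- prod(grid$shape)
  tmpl_ind <- lapply(templates, function(t) as.vector(t$mask$membership))
  base <- rep(1, nvox)
  age_c <- cohort$age - mean(cohort$age)
  z <- matrix(stats::rnorm(n * length(templates)), nrow = n,
              dimnames = list(cohort$subject_id, names(templates)))
  scale_i <- exp(stats::rnorm(n, 0, config$uptake_scale_sd))
  volumes <- vector("list", n)
  names(volumes) <- cohort$subject_id
  for (i in seq_len(n)) {
    g <- cohort$group[i]
    v <- base
    dg <- config$depths[[g]]
    for (nm in names(dg)) v <- v - dg[[nm]] * tmpl_ind[[nm]]
    lg <- config$lambda[[g]]
    for (nm in names(lg)) v <- v + lg[[nm]] * z[i, nm] * tmpl_ind[[nm]]
    v <- v + config$beta_age * age_c[i] + config$beta_sex * cohort$sex[i]
    v <- v + stats::rnorm(nvox, 0, config$noise_sd)
    volumes[[i]] <- scalar_volume(grid, v * scale_i[i])
  }
  list(cohort = cohort, volumes = volumes, templates = templates,
       seeds = seeds, gm_mask = binary_mask(grid, rep(TRUE, nvox)),
       reference_mask = generate_reference_mask(grid), grid = grid,
       latent = z, config = config)
}

#' SUVr-normalize every subject of a simulated cohort
#'
#' Applies [compute_suvr()] with the cohort's reference mask to each uptake
#' volume, removing the per-subject global scale.
#'
#' @param sim result of [simulate_fdg_cohort()].
#' @return `sim` with `volumes` replaced by SUVr volumes.
#' @export
suvr_normalize_cohort <- function(sim) {
  sim$volumes <- lapply(sim$volumes, compute_suvr,
                        reference = sim$reference_mask)
  sim
}

wmh_region_names <- function() {
  lobes <- c("frontal", "parietal", "temporal", "occipital")
  c(as.vector(outer(as.vector(outer(lobes, c("left", "right"), paste,
                                    sep = "_")),
                    paste0("l", 1:4), paste, sep = "_")), "bgit")
}

wmh_region_base_mean <- function(region, config) {
  if (region == "bgit") return(config$wmh_bgit_mean)
  config$wmh_layer_means[as.integer(sub(".*_l", "", region))]
}

#' Simulate subcortical-volume and regional-WMH tables
#'
#' Subcortical volumes are Normal around the control mean times
#' `(1 - deficit_g)`, with an ICV-proportional component and truncation to
#' positive values. Regional WMH volumes are Gamma(shape, scale) with the
#' mean equal to the layer baseline times the group's regional multiplicative
#' factor. Deterministic given `config$rng_seed`.
#'
#' @param config a `sim_config`.
#' @param cohort optional cohort data.frame (defaults to the one
#'   [simulate_fdg_cohort()] would draw from this config).
#' @return list: `cohort`, `subcortical` (data.frame subject_id + 7
#'   structures), `wmh` (data.frame subject_id + lobe x side x layer + bgit).
#' @export
simulate_volume_tables <- function(config = sim_config(), cohort = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(cohort)) {
    set.seed(child_seed(config$rng_seed, 1L))
    cohort <- simulate_demographics(config)
  }
  set.seed(child_seed(config$rng_seed, 2L))
  n <- nrow(cohort)
  icv_dev <- cohort$icv_cm3 / config$icv_mean - 1
  sub <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  for (st in names(config$subcortical_means)) {
    mu0 <- config$subcortical_means[[st]]
    defs <- vapply(cohort$group, function(g) {
      d <- config$subcortical_deficits[[g]]
      if (st %in% names(d)) d[[st]] else 0
    }, numeric(1))
    mu <- mu0 * (1 - defs) * (1 + config$icv_slope * icv_dev)
    sub[[st]] <- pmax(0.05 * mu0,
                      stats::rnorm(n, mu, config$subcortical_cv * mu0))
  }
  regions <- wmh_region_names()
  wmh <- data.frame(subject_id = cohort$subject_id, stringsAsFactors = FALSE)
  for (rg in regions) {
    base <- wmh_region_base_mean(rg, config)
    fac <- vapply(cohort$group, function(g) {
      f <- config$wmh_factors[[g]]
      if (rg %in% names(f)) f[[rg]] else 1
    }, numeric(1))
    wmh[[rg]] <- stats::rgamma(n, shape = config$wmh_shape,
                               scale = base * fac / config$wmh_shape)
  }
  list(cohort = cohort, subcortical = sub, wmh = wmh)
}
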