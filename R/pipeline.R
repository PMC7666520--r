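#' Pipeline run configuration
#'
#' One object carrying everything [run_pipeline()] needs: the simulation
#' configuration, the output directory, stage toggles, thresholding
#' parameters and the master seed. The master `rng_seed` fans out to
#' deterministic per-stage child seeds, so a single integer fixes the whole
#' run.
#'
#' @param out_dir output directory (created if absent).
#' @param sim a `sim_config` (its `rng_seed` is overridden by `rng_seed`
#'   here).
#' @param stages character vector of stages to run, in dependency order a
#'   subset of `c("simulate", "suvr", "contrasts", "connectivity",
#'   "features", "discriminate", "volumetrics")`. `simulate` and `suvr` are
#'   always required by the imaging stages.
#' @param fwe_alpha,extent_k thresholding for patient-vs-control contrasts.
#' @param uncorrected_alpha thresholding for patient-vs-patient contrasts.
#' @param n_perm permutations for the FWE null (>= 100).
#' @param contrast_pairs list of character(2) pairs for the voxelwise
#'   contrasts; defaults to each patient group vs CN plus bvAD vs the other
#'   patient groups.
#' @param roc_pairs list of character(2) pairs for discrimination.
#' @param rng_seed master integer seed.
#' @param write_nifti write t-maps and masks as NIfTI files (default TRUE).
#' @return object of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("metaconn_run_"),
                       sim = sim_config(),
                       stages = c("simulate", "suvr", "contrasts",
                                  "connectivity", "features", "discriminate",
                                  "volumetrics"),
                       fwe_alpha = 0.05, extent_k = 50L,
                       uncorrected_alpha = 0.001,
                       n_perm = 200L,
                       contrast_pairs = NULL,
                       roc_pairs = list(c("bvAD", "tAD"), c("bvAD", "bvFTD"),
                                        c("bvAD", "CN")),
                       rng_seed = 1L,
                       write_nifti = TRUE) {
  stages <- match.arg(stages, several.ok = TRUE)
  sim$rng_seed <- rng_seed
  if (is.null(contrast_pairs)) {
    groups <- names(sim$group_sizes)
    patients <- setdiff(groups, "CN")
    contrast_pairs <- c(lapply(patients, function(g) c(g, "CN")),
                        lapply(setdiff(patients, "bvAD"),
                               function(g) c("bvAD", g)))
  }
  structure(list(out_dir = out_dir, sim = sim, stages = stages,
                 fwe_alpha = fwe_alpha, extent_k = as.integer(extent_k),
                 uncorrected_alpha = uncorrected_alpha,
                 n_perm = as.integer(n_perm),
                 contrast_pairs = contrast_pairs, roc_pairs = roc_pairs,
                 rng_seed = as.integer(rng_seed),
                 write_nifti = isTRUE(write_nifti)),
            class = "run_config")
}

stage_record <- function(report, name, t0, outputs) {
  report$stages[[name]] <- list(
    stage = name, status = "ok",
    elapsed_s = round(as.numeric(Sys.time()) - t0, 3),
    outputs = outputs)
  report
}

#' Run the full analysis pipeline on a synthetic cohort
#'
#' Executes the enabled stages in dependency order: cohort simulation, SUVr
#' normalization, voxelwise group contrasts (permutation-FWE for
#' patient-vs-control, uncorrected for patient-vs-patient, both with the
#' configured extent threshold), seed-based covariance + GOF profile,
#' interaction analyses (PCC and frontoinsula seeds, bvAD vs tAD and vs
#' bvFTD), feature assembly, ROC discrimination, and the tabular volumetric
#' comparisons. Writes CSV/NIfTI/JSON outputs under `config$out_dir` and
#' returns (and writes) a machine-readable run report.
#'
#' @param config a `run_config`.
#' @return invisibly, a list with the in-memory stage results and the
#'   report; the report is also written to `<out_dir>/report.json`.
#' @export
run_pipeline <- function(config = run_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list(rng_seed = config$rng_seed, stages = list())
  res <- list()
  needs_imaging <- any(c("suvr", "contrasts", "connectivity", "features",
                         "discriminate") %in% config$stages)

  if ("simulate" %in% config$stages || needs_imaging) {
    t0 <- as.numeric(Sys.time())
    res$sim <- simulate_fdg_cohort(config$sim)
    res$tables <- simulate_volume_tables(config$sim, cohort = res$sim$cohort)
    cohort_path <- file.path(config$out_dir, "cohort.csv")
    utils::write.csv(res$sim$cohort, cohort_path, row.names = FALSE)
    utils::write.csv(res$tables$subcortical,
                     file.path(config$out_dir, "subcortical_volumes.csv"),
                     row.names = FALSE)
    utils::write.csv(res$tables$wmh,
                     file.path(config$out_dir, "wmh_volumes.csv"),
                     row.names = FALSE)
    report <- stage_record(report, "simulate", t0,
                           c("cohort.csv", "subcortical_volumes.csv",
                             "wmh_volumes.csv"))
  }

  if ("suvr" %in% config$stages || needs_imaging) {
    t0 <- as.numeric(Sys.time())
    res$sim <- suvr_normalize_cohort(res$sim)
    report <- stage_record(report, "suvr", t0, character(0))
  }

  cohort <- res$sim$cohort
  by_group <- function() split(seq_len(nrow(cohort)), cohort$group)

  if ("contrasts" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    outs <- character(0)
    design <- build_design(cohort)
    masks <- list()
    all_clusters <- list()
    for (pr in config$contrast_pairs) {
      lab <- sprintf("%s_lt_%s", pr[1], pr[2])
      fit <- fit_voxelwise_glm(res$sim$volumes, design,
                               analysis_mask = res$sim$gm_mask)
      # hypometabolism direction: pr[2] minus pr[1] (one-sided) for
      # patient-vs-control; both directions (two-sided) between patients
      ctr <- group_contrast(design, pr[2], pr[1])
      tm <- group_contrast_tmap(fit, ctr, label = lab)
      if ("CN" %in% pr) {
        null_max <- build_permutation_null(
          res$sim$volumes, design, ctr, n_perm = config$n_perm,
          rng_seed = child_seed(config$rng_seed, 10L),
          analysis_mask = res$sim$gm_mask, sidedness = "one_sided")
        thr <- threshold_tmap(tm, threshold_spec(config$fwe_alpha,
                                                 "fwe_permutation",
                                                 config$extent_k,
                                                 "one_sided"), null_max)
      } else {
        thr <- threshold_tmap(tm, threshold_spec(config$uncorrected_alpha,
                                                 "uncorrected",
                                                 config$extent_k,
                                                 "two_sided"))
      }
      masks[[lab]] <- thr$mask
      cl <- thr$clusters
      if (nrow(cl)) cl$contrast <- lab
      all_clusters[[lab]] <- cl
      if (config$write_nifti) {
        write_volume(tm$volume, file.path(config$out_dir,
                                          paste0("tmap_", lab, ".nii.gz")))
        write_volume(thr$mask, file.path(config$out_dir,
                                         paste0("sig_", lab, ".nii.gz")))
        outs <- c(outs, paste0("tmap_", lab, ".nii.gz"),
                  paste0("sig_", lab, ".nii.gz"))
      }
    }
    cn_masks <- masks[grepl("_lt_CN$", names(masks))]
    if (length(cn_masks) > 1L) {
      ov <- overlay_significance_maps(cn_masks)
      if (config$write_nifti) {
        write_volume(ov$volume, file.path(config$out_dir,
                                          "overlay_patients_vs_CN.nii.gz"))
        outs <- c(outs, "overlay_patients_vs_CN.nii.gz")
      }
      res$overlay <- ov
    }
    cl_tab <- do.call(rbind, all_clusters)
    utils::write.csv(cl_tab, file.path(config$out_dir, "clusters.csv"),
                     row.names = FALSE)
    res$contrast_masks <- masks
    res$clusters <- cl_tab
    report <- stage_record(report, "contrasts", t0,
                           c(outs, "clusters.csv"))
  }

  if ("connectivity" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    idx <- by_group()
    vols_by_group <- lapply(idx, function(i) res$sim$volumes[i])
    coh_by_group <- lapply(idx, function(i) cohort[i, , drop = FALSE])
    res$gof <- gof_profile(vols_by_group, coh_by_group, res$sim$templates,
                           res$sim$seeds, res$sim$gm_mask)
    utils::write.csv(res$gof, file.path(config$out_dir, "gof_profile.csv"),
                     row.names = FALSE)
    res$interactions <- list()
    for (pr in list(c("bvAD", "tAD"), c("bvAD", "bvFTD"))) {
      for (sd_name in c("PCC", "riFI")) {
        key <- sprintf("%s_vs_%s_%s", pr[1], pr[2], sd_name)
        res$interactions[[key]] <- interaction_analysis(
          res$sim$volumes, cohort, pr, res$sim$seeds[[sd_name]],
          res$sim$gm_mask)
      }
    }
    report <- stage_record(report, "connectivity", t0, "gof_profile.csv")
  }

  if ("features" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    rois <- generate_signature_rois(res$sim$grid, res$sim$templates)
    amyg <- res$tables$subcortical[, c("subject_id", "amygdala")]
    names(amyg)[2] <- "amygdala_cm3"
    burdens <- wmh_lobar_burden(res$tables$wmh)
    vf <- merge(amyg, burdens, by = "subject_id")
    res$features <- assemble_feature_table(
      cohort, list(fdg = res$sim$volumes), templates = res$sim$templates,
      rois = rois, analysis_mask = res$sim$gm_mask, volume_features = vf)
    utils::write.csv(res$features, file.path(config$out_dir, "features.csv"),
                     row.names = FALSE)
    report <- stage_record(report, "features", t0, "features.csv")
  }

  if ("discriminate" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    rocs <- lapply(config$roc_pairs, function(pr)
      rank_discriminators(res$features, pr))
    res$roc <- do.call(rbind, rocs)
    utils::write.csv(res$roc, file.path(config$out_dir, "roc_summary.csv"),
                     row.names = FALSE)
    report <- stage_record(report, "discriminate", t0, "roc_summary.csv")
  }

  if ("volumetrics" %in% config$stages) {
    t0 <- as.numeric(Sys.time())
    if (is.null(res$tables))
      res$tables <- simulate_volume_tables(config$sim)
    coh <- if (is.null(res$sim)) res$tables$cohort else cohort
    res$subcortical_stats <- subcortical_group_comparison(
      res$tables$subcortical, coh)
    cn_ids <- coh$subject_id[coh$group == "CN"]
    res$wmh_normalized <- wmh_normalize_to_controls(res$tables$wmh, cn_ids)
    res$wmh_stats <- wmh_group_comparison(res$tables$wmh, coh)
    utils::write.csv(res$subcortical_stats,
                     file.path(config$out_dir, "subcortical_stats.csv"),
                     row.names = FALSE)
    utils::write.csv(res$wmh_stats,
                     file.path(config$out_dir, "wmh_stats.csv"),
                     row.names = FALSE)
    report <- stage_record(report, "volumetrics", t0,
                           c("subcortical_stats.csv", "wmh_stats.csv"))
  }

  report$inputs_hash <- pipeline_inputs_hash(config)
  jsonlite::write_json(report, file.path(config$out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  res$report <- report
  invisible(res)
}

# md5 of the serialized configuration: identical config => identical hash
pipeline_inputs_hash <- function(config) {
  cfg <- config
  cfg$out_dir <- NULL
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg, f, version = 2)
  unname(tools::md5sum(f))
}
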