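#' Within-network / outside-network ratio for a subject map
#'
#' Mean of the map over the voxels of a network template divided by the mean
#' over the analysis-mask voxels outside the template: a subject-level index
#' of relative hypometabolism (SUVr maps) or relative atrophy (gray-matter
#' maps) within the network.
#'
#' @param subject_map a `scalar_volume`.
#' @param template a `network_template` or bare `binary_mask`.
#' @param analysis_mask `binary_mask` defining the brain/gray-matter domain.
#' @return numeric ratio.
#' @export
network_ratio <- function(subject_map, template, analysis_mask) {
  tmask <- if (inherits(template, "network_template")) template$mask
           else template
  stopifnot(inherits(subject_map, "scalar_volume"),
            inherits(tmask, "binary_mask"),
            inherits(analysis_mask, "binary_mask"))
  check_same_grid(subject_map, analysis_mask)
  check_same_grid(subject_map, tmask)
  inside <- tmask$membership & analysis_mask$membership
  outside <- analysis_mask$membership & !tmask$membership
  if (!any(inside) || !any(outside))
    stop("partition error: template must split the analysis mask into two non-empty parts",
         call. = FALSE)
  denom <- mean(subject_map$values[outside])
  if (denom == 0)
    stop("ratio error: outside-template mean is zero", call. = FALSE)
  mean(subject_map$values[inside]) / denom
}

#' Signature ROI: a named disease-signature mask
#'
#' Canonical names: AD_temporoparietal, AD_parietal, FTD_signature (anterior
#' cingulate + frontoinsular + striatal + frontopolar composite); any named
#' non-empty mask is accepted.
#'
#' @param name ROI label.
#' @param mask non-empty `binary_mask`.
#' @return object of class `signature_roi`.
#' @export
signature_roi <- function(name, mask) {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_count(mask) == 0L) stop_empty_roi(sprintf("signature ROI '%s'", name))
  structure(list(name = as.character(name), mask = mask),
            class = "signature_roi")
}

#' Mean of a subject map over a signature ROI
#'
#' @param subject_map a `scalar_volume`.
#' @param roi a `signature_roi` (or bare `binary_mask`).
#' @param restrict optional `binary_mask` (e.g. gray matter).
#' @return numeric mean.
#' @export
signature_roi_mean <- function(subject_map, roi, restrict = NULL) {
  mask <- if (inherits(roi, "signature_roi")) roi$mask else roi
  extract_roi_mean(subject_map, mask, restrict)
}

#' Assemble the per-subject feature table for discrimination
#'
#' One row per subject; columns are the requested network ratios (per
#' modality), signature-ROI means (per modality), and any tabular volume
#' features (e.g. bilateral amygdala volume, lobar WMH burdens). Rows are
#' sorted by subject_id and column order is deterministic.
#'
#' @param cohort cohort data.frame (`subject_id`, `group`).
#' @param maps_by_modality named list: modality -> named list
#'   (subject_id -> `scalar_volume`). Missing subjects are an error.
#' @param templates named list of `network_template`s (ratio features, one
#'   per template per modality, named `<modality>_<network>_ratio`).
#' @param rois named list of `signature_roi`s (mean features,
#'   `<modality>_<roi>`).
#' @param analysis_mask `binary_mask` for the ratio denominator.
#' @param volume_features optional data.frame keyed by `subject_id` whose
#'   remaining numeric columns are appended as features.
#' @return data.frame feature table.
#' @export
assemble_feature_table <- function(cohort, maps_by_modality, templates = list(),
                                   rois = list(), analysis_mask = NULL,
                                   volume_features = NULL) {
  ids <- sort(as.character(cohort$subject_id))
  cohort <- cohort[match(ids, as.character(cohort$subject_id)), , drop = FALSE]
  out <- data.frame(subject_id = ids, group = as.character(cohort$group),
                    stringsAsFactors = FALSE)
  for (mod in names(maps_by_modality)) {
    maps <- maps_by_modality[[mod]]
    absent <- setdiff(ids, names(maps))
    if (length(absent))
      stop(sprintf("completeness error: no %s map for subject(s): %s",
                   mod, paste(absent, collapse = ", ")), call. = FALSE)
    for (net in names(templates)) {
      if (is.null(analysis_mask))
        stop("analysis_mask is required for ratio features", call. = FALSE)
      out[[paste(mod, net, "ratio", sep = "_")]] <-
        vapply(ids, function(s)
          network_ratio(maps[[s]], templates[[net]], analysis_mask),
          numeric(1))
    }
    for (rn in names(rois)) {
      out[[paste(mod, rn, sep = "_")]] <-
        vapply(ids, function(s)
          signature_roi_mean(maps[[s]], rois[[rn]], analysis_mask),
          numeric(1))
    }
  }
  if (!is.null(volume_features)) {
    absent <- setdiff(ids, as.character(volume_features$subject_id))
    if (length(absent))
      stop(sprintf("completeness error: no tabular features for subject(s): %s",
                   paste(absent, collapse = ", ")), call. = FALSE)
    vf <- volume_features[match(ids, as.character(volume_features$subject_id)),
                          , drop = FALSE]
    for (cn in setdiff(names(vf), "subject_id")) out[[cn]] <- vf[[cn]]
  }
  rownames(out) <- NULL
  out
}

#' Weighted lobar WMH burden features
#'
#' Collapses a regional WMH table (lobe x side x layer columns named
#' `<lobe>_<side>_l<layer>`) to one burden per lobe: the weighted sum over
#' sides and concentric layers (default uniform weights).
#'
#' @param wmh_table data.frame with `subject_id` and regional columns.
#' @param lobes lobes to collapse (default frontal, parietal, temporal,
#'   occipital).
#' @param layer_weights numeric length-4 per-layer weights, default uniform.
#' @return data.frame: subject_id plus `wmh_<lobe>` columns, and any
#'   non-layered columns (e.g. `bgit`) passed through as `wmh_<name>`.
#' @export
wmh_lobar_burden <- function(wmh_table,
                             lobes = c("frontal", "parietal", "temporal",
                                       "occipital"),
                             layer_weights = rep(1, 4)) {
  stopifnot(length(layer_weights) == 4L, all(layer_weights >= 0))
  out <- data.frame(subject_id = wmh_table$subject_id,
                    stringsAsFactors = FALSE)
  for (lb in lobes) {
    cols <- grep(sprintf("^%s_(left|right)_l[1-4]$", lb), names(wmh_table),
                 value = TRUE)
    if (!length(cols))
      stop(sprintf("no regional columns found for lobe '%s'", lb),
           call. = FALSE)
    w <- layer_weights[as.integer(sub(".*_l", "", cols))]
    out[[paste0("wmh_", lb)]] <-
      as.vector(as.matrix(wmh_table[, cols, drop = FALSE]) %*% w)
  }
  extra <- setdiff(names(wmh_table),
                   c("subject_id",
                     grep("_(left|right)_l[1-4]$", names(wmh_table),
                          value = TRUE)))
  for (cn in extra) out[[paste0("wmh_", cn)]] <- wmh_table[[cn]]
  out
}
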