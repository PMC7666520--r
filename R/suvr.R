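#' Reference-region (SUVr) normalization
#'
#' Divides every voxel of an uptake volume by the mean uptake within a
#' reference-region mask (canonically the pons, whose metabolism is preserved
#' in Alzheimer's disease), yielding a standardized uptake value ratio map
#' whose mean over the reference region is exactly 1.
#'
#' @param uptake a `scalar_volume` of tracer uptake.
#' @param reference a non-empty `binary_mask` on the same grid.
#' @return a `scalar_volume` of SUVr.
#' @export
compute_suvr <- function(uptake, reference) {
  stopifnot(inherits(uptake, "scalar_volume"), inherits(reference, "binary_mask"))
  check_same_grid(uptake, reference)
  if (mask_count(reference) == 0L) stop_empty_roi("reference region")
  ref_mean <- mean(uptake$values[reference$membership])
  if (!is.finite(ref_mean) || ref_mean <= 0)
    stop(sprintf("normalization error: reference-region mean is %g (must be > 0)",
                 ref_mean), call. = FALSE)
  scalar_volume(uptake$grid, uptake$values / ref_mean)
}

#' Mean of a volume over an ROI, optionally restricted by a second mask
#'
#' The arithmetic mean over the member voxels of `roi`, intersected with
#' `restrict` when given (e.g. a gray-matter mask excluding white matter and
#' CSF counts from a seed sphere).
#'
#' @param volume a `scalar_volume`.
#' @param roi a `binary_mask`.
#' @param restrict optional `binary_mask`.
#' @return numeric scalar mean.
#' @export
extract_roi_mean <- function(volume, roi, restrict = NULL) {
  stopifnot(inherits(volume, "scalar_volume"), inherits(roi, "binary_mask"))
  check_same_grid(volume, roi)
  sel <- roi$membership
  if (!is.null(restrict)) {
    stopifnot(inherits(restrict, "binary_mask"))
    check_same_grid(volume, restrict)
    sel <- sel & restrict$membership
  }
  if (!any(sel)) stop_empty_roi("ROI (after restriction)")
  mean(volume$values[sel])
}

#' Total intracranial volume from tissue compartment volumes
#'
#' TIV is the sum of the gray-matter, white-matter and CSF compartment
#' volumes (cm^3).
#'
#' @param gm_volume,wm_volume,csf_volume compartment volumes in cm^3, >= 0.
#' @return numeric TIV in cm^3.
#' @export
compute_icv <- function(gm_volume, wm_volume, csf_volume) {
  v <- c(gm_volume, wm_volume, csf_volume)
  if (any(!is.finite(v)) || any(v < 0))
    stop("compartment volumes must be finite and >= 0", call. = FALSE)
  gm_volume + wm_volume + csf_volume
}

#' Read and validate a cohort table
#'
#' Expects CSV columns `subject_id`, `group`, `age`, `sex`,
#' `field_strength_t`, `icv_cm3`. Groups are canonically bvAD, tAD, bvFTD,
#' CN but any labels are accepted; sex is coded 0/1.
#'
#' @param path CSV path, or a data.frame already in memory.
#' @return validated data.frame.
#' @export
read_cohort_table <- function(path) {
  tab <- if (is.data.frame(path)) path else
    utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "group", "age", "sex", "field_strength_t",
                "icv_cm3")
  missing <- setdiff(required, names(tab))
  if (length(missing))
    stop(sprintf("cohort table lacks columns: %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  if (anyDuplicated(tab$subject_id))
    stop("subject_ids must be unique", call. = FALSE)
  if (any(!is.finite(tab$age)) || any(tab$age <= 0))
    stop("ages must be positive", call. = FALSE)
  if (any(!is.finite(tab$icv_cm3)) || any(tab$icv_cm3 <= 0))
    stop("icv_cm3 must be positive", call. = FALSE)
  if (!all(tab$sex %in% c(0, 1)))
    stop("sex must be coded 0/1", call. = FALSE)
  tab
}

#' Read a scan manifest and load the referenced volumes
#'
#' A manifest CSV maps subjects to image files: columns `subject_id`,
#' `modality` (e.g. fdg_suvr, gm_density) and `path` (NIfTI file, relative
#' paths resolved against the manifest's directory). One volume per
#' (subject, modality) pair.
#'
#' @param path manifest CSV path.
#' @return data.frame with absolute `path`s.
#' @export
read_scan_manifest <- function(path) {
  man <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "modality", "path")
  miss <- setdiff(required, names(man))
  if (length(miss))
    stop(sprintf("manifest lacks columns: %s", paste(miss, collapse = ", ")),
         call. = FALSE)
  if (anyDuplicated(man[, c("subject_id", "modality")]))
    stop("one volume per (subject, modality) pair", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", man$path)
  man$path[rel] <- file.path(dirname(path), man$path[rel])
  absent <- man$path[!file.exists(man$path)]
  if (length(absent))
    stop(sprintf("manifest references missing file(s): %s",
                 paste(utils::head(absent, 3), collapse = ", ")),
         call. = FALSE)
  man
}

#' @rdname read_scan_manifest
#' @param manifest data.frame from [read_scan_manifest()].
#' @param modality modality to load.
#' @return named list (subject_id -> `scalar_volume`), all on one grid.
#' @export
load_scans <- function(manifest, modality = "fdg_suvr") {
  rows <- manifest[manifest$modality == modality, , drop = FALSE]
  if (!nrow(rows))
    stop(sprintf("no manifest rows with modality '%s'", modality),
         call. = FALSE)
  vols <- lapply(rows$path, read_volume)
  names(vols) <- rows$subject_id
  for (v in vols) check_same_grid(vols[[1]], v)
  vols
}
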