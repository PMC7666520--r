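#' Spherical seed region
#'
#' A named sphere in world (MNI mm) coordinates, used as a seed for
#' interregional covariance analysis. The default radius of 4 mm follows the
#' seed definition used throughout the connectivity analyses.
#'
#' @param name label for the seed.
#' @param center_mni numeric length-3 world coordinate in mm.
#' @param radius_mm sphere radius in mm (> 0).
#' @return an object of class `sphere_seed`.
#' @export
sphere_seed <- function(name, center_mni, radius_mm = 4) {
  center_mni <- as.numeric(center_mni)
  if (length(center_mni) != 3L || any(!is.finite(center_mni)))
    stop("`center_mni` must be 3 finite numbers", call. = FALSE)
  radius_mm <- as.numeric(radius_mm)
  if (!is.finite(radius_mm) || radius_mm <= 0)
    stop("`radius_mm` must be positive", call. = FALSE)
  structure(list(name = as.character(name), center_mni = center_mni,
                 radius_mm = radius_mm),
            class = "sphere_seed")
}

#' Canonical network seed registry
#'
#' The four seeds anchoring the posterior DMN (posterior cingulate cortex),
#' anterior DMN (anterior medial prefrontal cortex), salience network (right
#' frontoinsula) and executive control network (right dorsolateral prefrontal
#' cortex), at their published MNI coordinates, with 4 mm radius. The amPFC
#' coordinate has positive x; the coordinate, not a side label, is used.
#'
#' @return a named list of `sphere_seed` objects: PCC, amPFC, riFI, riDLPFC.
#' @export
default_seed_registry <- function() {
  list(
    PCC     = sphere_seed("PCC",     c(-8, -56, 26)),
    amPFC   = sphere_seed("amPFC",   c(6, 52, -2)),
    riFI    = sphere_seed("riFI",    c(36, 18, 4)),
    riDLPFC = sphere_seed("riDLPFC", c(44, 36, 20))
  )
}

#' Pairing of network templates to their anchoring seeds
#'
#' @return named character vector mapping network name to seed name.
#' @export
default_network_seed_pairing <- function() {
  c(pDMN = "PCC", aDMN = "amPFC", SN = "riFI", ECN = "riDLPFC")
}

#' Rasterize a spherical seed onto a grid
#'
#' A voxel is a member iff the Euclidean distance from its world-space centre
#' to the seed centre is at most the radius (voxel-centre membership, no
#' partial-volume weighting).
#'
#' @param grid a `vol_grid`.
#' @param seed a `sphere_seed`.
#' @return a `binary_mask`.
#' @export
make_sphere_mask <- function(grid, seed) {
  stopifnot(inherits(grid, "vol_grid"), inherits(seed, "sphere_seed"))
  ctr <- world_to_voxel(grid, matrix(seed$center_mni, 1))
  if (any(ctr < 0.5) || any(ctr > grid$shape + 0.5))
    stop_empty_roi(sprintf("seed '%s' lies outside the grid bounding box",
                           seed$name))
  # only scan a bounding box around the centre
  rad_vox <- ceiling(seed$radius_mm / grid$spacing) + 1
  lo <- pmax(1, floor(ctr - rad_vox))
  hi <- pmin(grid$shape, ceiling(ctr + rad_vox))
  idx <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  xyz <- voxel_to_world(grid, idx)
  d2 <- rowSums(sweep(xyz, 2, seed$center_mni)^2)
  member <- idx[d2 <= seed$radius_mm^2, , drop = FALSE]
  if (nrow(member) == 0L)
    stop_empty_roi(sprintf("seed '%s' rasterizes to zero voxels", seed$name))
  arr <- array(FALSE, dim = grid$shape)
  arr[member] <- TRUE
  binary_mask(grid, arr)
}

#' Binarize a continuous map at a threshold
#'
#' Membership uses a strict inequality (`value > threshold`), so a network
#' template thresholded at r = 0.2 excludes voxels exactly at 0.2.
#'
#' @param continuous_map a `scalar_volume`.
#' @param threshold finite numeric threshold.
#' @return a `binary_mask`; errors if no voxel passes.
#' @export
binarize_template <- function(continuous_map, threshold) {
  stopifnot(inherits(continuous_map, "scalar_volume"))
  if (!is.numeric(threshold) || length(threshold) != 1L || is.na(threshold))
    stop("`threshold` must be a single non-missing number", call. = FALSE)
  m <- continuous_map$values > threshold
  if (!any(m))
    stop_empty_roi(sprintf("no voxel exceeds threshold %g", threshold))
  binary_mask(continuous_map$grid, m)
}

#' Network template: a named binary mask
#'
#' @param name network label (canonically one of pDMN, aDMN, SN, ECN).
#' @param mask a non-empty `binary_mask`.
#' @param source_label free-text provenance of the template.
#' @return an object of class `network_template`.
#' @export
network_template <- function(name, mask, source_label = "") {
  stopifnot(inherits(mask, "binary_mask"))
  if (mask_count(mask) == 0L) stop_empty_roi(sprintf("template '%s'", name))
  structure(list(name = as.character(name), mask = mask,
                 source_label = as.character(source_label)),
            class = "network_template")
}
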