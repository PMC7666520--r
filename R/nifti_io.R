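#' Read a single 3-D NIfTI volume
#'
#' Reads a NIfTI-1/2 file into a `scalar_volume`, taking shape, spacing and
#' the grid-to-world affine from the header (sform preferred, per RNifti).
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a `scalar_volume`.
#' @export
read_volume <- function(path) {
  if (!file.exists(path))
    stop(sprintf("cannot read NIfTI volume: file not found: %s", path),
         call. = FALSE)
  img <- tryCatch(RNifti::readNifti(path),
                  error = function(e)
                    stop(sprintf("not a readable NIfTI file: %s (%s)",
                                 path, conditionMessage(e)), call. = FALSE))
  arr <- as.array(img)
  d <- dim(arr)
  if (length(d) == 4L && d[4] == 1L) { arr <- arr[, , , 1]; d <- dim(arr) }
  if (length(d) != 3L)
    stop(sprintf("expected a single 3-D volume, got %d dimensions: %s",
                 length(d), path), call. = FALSE)
  aff <- unclass(RNifti::xform(img))
  attributes(aff) <- list(dim = c(4L, 4L))
  spacing <- abs(RNifti::pixdim(img)[1:3])
  grid <- vol_grid(d, spacing = spacing, affine = aff)
  scalar_volume(grid, arr)
}

#' Write a volume or mask as NIfTI
#'
#' Masks are stored as 0/1 integer volumes.
#'
#' @param x a `scalar_volume` or `binary_mask`.
#' @param path output path ending in `.nii` or `.nii.gz`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path) {
  if (inherits(x, "binary_mask")) {
    arr <- array(as.integer(x$membership), dim = x$grid$shape)
    grid <- x$grid
  } else if (inherits(x, "scalar_volume")) {
    arr <- x$values
    grid <- x$grid
  } else stop("`x` must be a scalar_volume or binary_mask", call. = FALSE)
  img <- RNifti::asNifti(arr)
  aff <- structure(grid$affine, code = 2L)
  RNifti::qform(img) <- aff
  RNifti::sform(img) <- aff
  RNifti::pixdim(img) <- grid$spacing
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' Read a binary mask from NIfTI
#'
#' @param path path to a NIfTI mask (nonzero = member).
#' @param require_nonempty error if the mask has no member voxels (default
#'   TRUE: a mask used as an ROI or template must select something).
#' @return a `binary_mask`.
#' @export
read_mask <- function(path, require_nonempty = TRUE) {
  v <- read_volume(path)
  m <- binary_mask(v$grid, v$values != 0)
  if (require_nonempty && mask_count(m) == 0L)
    stop_empty_roi(sprintf("mask read from %s", path))
  m
}
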