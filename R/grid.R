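#' Voxel grid: shape, spacing and grid-to-world affine
#'
#' A `vol_grid` describes the sampling lattice shared by all volumes of one
#' analysis: the number of voxels per axis, the voxel spacing in mm, and the
#' 4x4 affine mapping zero-based voxel indices to world (RAS mm, MNI-style)
#' coordinates.
#'
#' @param shape integer vector of length 3, voxels per axis (all >= 1).
#' @param spacing numeric vector of length 3, mm per voxel (all > 0). If
#'   missing, derived from the affine column norms.
#' @param affine 4x4 numeric matrix mapping homogeneous zero-based voxel
#'   indices to world mm. Must be invertible. Defaults to a diagonal affine
#'   with the given spacing and the grid centre at the world origin.
#' @return an object of class `vol_grid`.
#' @export
vol_grid <- function(shape, spacing = NULL, affine = NULL) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(is.na(shape)) || any(shape < 1L))
    stop("`shape` must be 3 positive integers", call. = FALSE)
  if (is.null(affine)) {
    if (is.null(spacing)) spacing <- c(1, 1, 1)
    spacing <- as.numeric(spacing)
    if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be 3 positive numbers", call. = FALSE)
    # centre the grid on the world origin
    offset <- -spacing * (shape - 1) / 2
    affine <- diag(4)
    diag(affine)[1:3] <- spacing
    affine[1:3, 4] <- offset
  } else {
    affine <- as.matrix(affine)
    if (!identical(dim(affine), c(4L, 4L)) || any(!is.finite(affine)))
      stop("`affine` must be a finite 4x4 matrix", call. = FALSE)
    if (abs(det(affine)) < 1e-12)
      stop("`affine` must be invertible", call. = FALSE)
    if (is.null(spacing))
      spacing <- sqrt(colSums(affine[1:3, 1:3]^2))
    spacing <- as.numeric(spacing)
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("`spacing` must be 3 positive numbers", call. = FALSE)
  }
  structure(list(shape = shape, spacing = spacing, affine = affine),
            class = "vol_grid")
}

#' @export
print.vol_grid <- function(x, ...) {
  cat(sprintf("<vol_grid %dx%dx%d @ %.3gx%.3gx%.3g mm>\n",
              x$shape[1], x$shape[2], x$shape[3],
              x$spacing[1], x$spacing[2], x$spacing[3]))
  invisible(x)
}

#' Compare two grids for equality
#'
#' Grids are equal iff shape matches exactly and spacing and affine agree
#' within `tol` mm.
#'
#' @param a,b `vol_grid` objects.
#' @param tol numeric tolerance in mm.
#' @return logical scalar.
#' @export
grids_equal <- function(a, b, tol = 1e-6) {
  stopifnot(inherits(a, "vol_grid"), inherits(b, "vol_grid"))
  identical(a$shape, b$shape) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(abs(a$affine - b$affine) <= tol)
}

stop_grid_mismatch <- function(what = "volumes") {
  stop(sprintf("grid mismatch: all %s entering one analysis must share a grid",
               what), call. = FALSE)
}

check_same_grid <- function(a, b, what = "volumes") {
  ga <- if (inherits(a, "vol_grid")) a else a$grid
  gb <- if (inherits(b, "vol_grid")) b else b$grid
  if (!grids_equal(ga, gb)) stop_grid_mismatch(what)
  invisible(TRUE)
}

#' Map voxel indices to world coordinates
#'
#' @param grid a `vol_grid`.
#' @param ijk n x 3 matrix of one-based voxel indices (may be fractional).
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, ijk) {
  ijk <- matrix(as.numeric(ijk), ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(grid$affine)  # affine acts on zero-based indices
  h[, 1:3, drop = FALSE]
}

#' Map world coordinates to (fractional, one-based) voxel indices
#'
#' @param grid a `vol_grid`.
#' @param xyz n x 3 matrix of world mm coordinates.
#' @return n x 3 matrix of one-based voxel indices.
#' @export
world_to_voxel <- function(grid, xyz) {
  xyz <- matrix(as.numeric(xyz), ncol = 3)
  h <- cbind(xyz, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE] + 1
}

#' World coordinates of every voxel centre
#'
#' @param grid a `vol_grid`.
#' @return (prod(shape)) x 3 matrix, rows in array (column-major) order.
#' @export
grid_coordinates <- function(grid) {
  idx <- as.matrix(expand.grid(i = seq_len(grid$shape[1]),
                               j = seq_len(grid$shape[2]),
                               k = seq_len(grid$shape[3])))
  voxel_to_world(grid, idx)
}

#' Scalar volume on a grid
#'
#' @param grid a `vol_grid`.
#' @param values numeric array (or vector) with `prod(grid$shape)` elements.
#' @return an object of class `scalar_volume` with fields `grid` and `values`
#'   (a 3-D array).
#' @export
scalar_volume <- function(grid, values) {
  stopifnot(inherits(grid, "vol_grid"))
  values <- as.numeric(values)
  if (length(values) != prod(grid$shape))
    stop("value count must equal product of grid shape", call. = FALSE)
  structure(list(grid = grid, values = array(values, dim = grid$shape)),
            class = "scalar_volume")
}

#' @export
print.scalar_volume <- function(x, ...) {
  cat(sprintf("<scalar_volume %dx%dx%d, range [%.4g, %.4g]>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Binary mask on a grid
#'
#' @param grid a `vol_grid`.
#' @param membership logical array (or vector) with `prod(grid$shape)`
#'   elements; numeric input is coerced with `!= 0`.
#' @return an object of class `binary_mask`.
#' @export
binary_mask <- function(grid, membership) {
  stopifnot(inherits(grid, "vol_grid"))
  if (!is.logical(membership)) membership <- as.numeric(membership) != 0
  if (length(membership) != prod(grid$shape))
    stop("membership count must equal product of grid shape", call. = FALSE)
  if (anyNA(membership)) stop("mask membership must not contain NA", call. = FALSE)
  structure(list(grid = grid, membership = array(membership, dim = grid$shape)),
            class = "binary_mask")
}

#' @export
print.binary_mask <- function(x, ...) {
  cat(sprintf("<binary_mask %dx%dx%d, %d member voxels>\n",
              x$grid$shape[1], x$grid$shape[2], x$grid$shape[3],
              sum(x$membership)))
  invisible(x)
}

#' Number of member voxels in a mask
#' @param mask a `binary_mask`.
#' @return integer count.
#' @export
mask_count <- function(mask) sum(mask$membership)

stop_empty_roi <- function(what = "ROI") {
  stop(sprintf("empty ROI: %s contains no voxels", what), call. = FALSE)
}

#' Mask algebra
#'
#' Intersection, union and set difference of masks on a common grid, and the
#' complement of a mask.
#'
#' @param a,b `binary_mask` objects on the same grid.
#' @return a `binary_mask`.
#' @export
mask_intersect <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$grid, a$membership & b$membership)
}

#' @rdname mask_intersect
#' @export
mask_union <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$grid, a$membership | b$membership)
}

#' @rdname mask_intersect
#' @export
mask_difference <- function(a, b) {
  check_same_grid(a, b, "masks")
  binary_mask(a$grid, a$membership & !b$membership)
}

#' @rdname mask_intersect
#' @export
mask_complement <- function(a) binary_mask(a$grid, !a$membership)

#' Resample a volume onto another grid
#'
#' Nearest-neighbour or trilinear resampling. Never applied implicitly by any
#' analysis function: all analyses require exactly matching grids, and this
#' utility is the explicit escape hatch.
#'
#' @param volume a `scalar_volume`.
#' @param target a `vol_grid`.
#' @param method "nearest" or "linear".
#' @param fill value used outside the source grid.
#' @return a `scalar_volume` on `target`.
#' @export
resample_volume <- function(volume, target, method = c("nearest", "linear"),
                            fill = 0) {
  method <- match.arg(method)
  stopifnot(inherits(volume, "scalar_volume"), inherits(target, "vol_grid"))
  src <- volume$grid
  ijk <- world_to_voxel(src, grid_coordinates(target))
  n <- nrow(ijk)
  out <- rep(as.numeric(fill), n)
  if (method == "nearest") {
    r <- round(ijk)
    ok <- r[, 1] >= 1 & r[, 1] <= src$shape[1] &
          r[, 2] >= 1 & r[, 2] <= src$shape[2] &
          r[, 3] >= 1 & r[, 3] <= src$shape[3]
    out[ok] <- volume$values[cbind(r[ok, 1], r[ok, 2], r[ok, 3])]
  } else {
    f <- floor(ijk)
    # points exactly on the upper grid face: interpolate from the cell below
    for (ax in 1:3) {
      hi <- ijk[, ax] == src$shape[ax]
      f[hi, ax] <- src$shape[ax] - 1
    }
    w <- ijk - f
    ok <- f[, 1] >= 1 & f[, 1] + 1 <= src$shape[1] &
          f[, 2] >= 1 & f[, 2] + 1 <= src$shape[2] &
          f[, 3] >= 1 & f[, 3] + 1 <= src$shape[3]
    acc <- rep(0, sum(ok))
    fo <- f[ok, , drop = FALSE]; wo <- w[ok, , drop = FALSE]
    for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
      wt <- (if (dx) wo[, 1] else 1 - wo[, 1]) *
            (if (dy) wo[, 2] else 1 - wo[, 2]) *
            (if (dz) wo[, 3] else 1 - wo[, 3])
      acc <- acc + wt * volume$values[cbind(fo[, 1] + dx, fo[, 2] + dy,
                                            fo[, 3] + dz)]
    }
    out[ok] <- acc
  }
  scalar_volume(target, out)
}
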