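#' Separable Gaussian smoothing of a volume
#'
#' Smooths with an axis-separable discrete Gaussian whose full width at half
#' maximum is given in mm per axis; per axis, sigma in voxels is
#' fwhm / (spacing * sqrt(8 * log(2))). Boundaries are handled by symmetric
#' reflection, which preserves the global mean. A FWHM of 0 on an axis leaves
#' that axis untouched.
#'
#' @param volume a `scalar_volume`.
#' @param fwhm_mm numeric: a single FWHM applied isotropically, or a length-3
#'   vector per axis. All components must be >= 0.
#' @return a smoothed `scalar_volume` on the same grid.
#' @export
gaussian_smooth <- function(volume, fwhm_mm) {
  stopifnot(inherits(volume, "scalar_volume"))
  fwhm_mm <- as.numeric(fwhm_mm)
  if (length(fwhm_mm) == 1L) fwhm_mm <- rep(fwhm_mm, 3)
  if (length(fwhm_mm) != 3L || any(!is.finite(fwhm_mm)) || any(fwhm_mm < 0))
    stop("`fwhm_mm` must be 1 or 3 non-negative numbers", call. = FALSE)
  arr <- volume$values
  for (axis in 1:3) {
    if (fwhm_mm[axis] == 0) next
    sigma <- fwhm_mm[axis] / (volume$grid$spacing[axis] * sqrt(8 * log(2)))
    M <- gaussian_line_operator(volume$grid$shape[axis], sigma)
    arr <- apply_along_axis(arr, axis, M)
  }
  scalar_volume(volume$grid, arr)
}

# n x n smoothing matrix for one axis: discrete Gaussian taps (normalized to
# unit sum), with out-of-range taps folded back by symmetric reflection.
# Symmetric kernel + involutive reflection make the matrix symmetric, so both
# row and column sums are 1: constants and the global mean are preserved.
gaussian_line_operator <- function(n, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  taps <- exp(-((-r):r)^2 / (2 * sigma^2))
  taps <- taps / sum(taps)
  M <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (o in (-r):r) {
      j <- reflect_index(i + o, n)
      M[i, j] <- M[i, j] + taps[o + r + 1]
    }
  }
  M
}

# symmetric ("whole-sample") reflection: ... 3 2 1 | 1 2 3 ... n | n n-1 ...
reflect_index <- function(j, n) {
  period <- 2L * n
  j <- ((j - 1L) %% period + period) %% period + 1L
  if (j > n) j <- period - j + 1L
  j
}

# multiply a 3-D array along one axis by matrix M (n_axis x n_axis)
apply_along_axis <- function(arr, axis, M) {
  d <- dim(arr)
  perm <- c(axis, setdiff(1:3, axis))
  a <- aperm(arr, perm)
  a <- matrix(a, nrow = d[axis])
  a <- M %*% a
  a <- array(a, dim = d[perm])
  aperm(a, order(perm))
}
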