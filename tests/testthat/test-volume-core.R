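test_that("NIfTI round trip preserves values, spacing and affine", {
  g <- tiny_grid()
  set.seed(1)
  v <- scalar_volume(g, rnorm(prod(g$shape)))
  f <- tempfile(fileext = ".nii.gz")
  write_volume(v, f)
  v2 <- read_volume(f)
  expect_equal(v2$values, v$values, tolerance = 1e-12)
  expect_equal(v2$grid$spacing, c(2, 2, 2))
  expect_true(grids_equal(v$grid, v2$grid, tol = 1e-4))

  # masks round trip as 0/1 volumes
  m <- first_k_mask(g, 10)
  fm <- tempfile(fileext = ".nii.gz")
  write_volume(m, fm)
  m2 <- read_mask(fm)
  expect_identical(m2$membership, m$membership)
})

test_that("read_volume rejects non-NIfTI and missing files", {
  txt <- tempfile(fileext = ".nii")
  writeLines("not a nifti", txt)
  expect_error(read_volume(txt), "NIfTI")
  expect_error(read_volume(tempfile(fileext = ".nii")), "not found")
})

test_that("sphere masks match brute-force voxel enumeration", {
  g <- vol_grid(c(11, 11, 11), spacing = c(2, 2, 2))
  # seed at an exact voxel centre and at an off-centre position
  centres <- list(voxel_to_world(g, matrix(c(6, 6, 6), 1)),
                  c(1.3, -2.1, 0.7))
  for (ctr in centres) {
    seed <- sphere_seed("s", as.numeric(ctr), radius_mm = 4)
    m <- make_sphere_mask(g, seed)
    xyz <- grid_coordinates(g)
    d <- sqrt(rowSums(sweep(xyz, 2, as.numeric(ctr))^2))
    expect_identical(as.vector(m$membership), d <= 4)
  }
})

test_that("sub-voxel sphere at a voxel centre selects exactly that voxel", {
  g <- vol_grid(c(7, 7, 7), spacing = c(2, 2, 2))
  ctr <- voxel_to_world(g, matrix(c(4, 4, 4), 1))
  m <- make_sphere_mask(g, sphere_seed("c", ctr, radius_mm = 0.1))
  expect_equal(mask_count(m), 1L)
  expect_true(m$membership[4, 4, 4])
})

test_that("seeds outside the grid bounding box raise an empty-ROI error", {
  g <- tiny_grid()
  expect_error(make_sphere_mask(g, sphere_seed("far", c(500, 0, 0))),
               "outside the grid")
})

test_that("sphere masks reflect with the seed through the grid centre", {
  g <- vol_grid(c(9, 9, 9), spacing = c(2, 2, 2))  # centred on the origin
  seed <- sphere_seed("s", c(3, -1, 5), radius_mm = 5)
  mirror <- sphere_seed("m", -c(3, -1, 5), radius_mm = 5)
  a <- make_sphere_mask(g, seed)$membership
  b <- make_sphere_mask(g, mirror)$membership
  expect_identical(a, b[9:1, 9:1, 9:1])
})

test_that("template binarization is strict and errors when empty", {
  v <- tiny_volume(0, shape = c(3, 1, 1))
  v$values[] <- c(0.1, 0.2, 0.3)
  m <- binarize_template(v, 0.2)
  expect_identical(as.vector(m$membership), c(FALSE, FALSE, TRUE))
  expect_equal(mask_count(binarize_template(v, -Inf)), 3L)
  z <- tiny_volume(0)
  expect_error(binarize_template(z, 0.2), "empty ROI|no voxel")
})

test_that("binarization is monotone in the threshold", {
  set.seed(2)
  v <- tiny_volume(rnorm(125))
  for (thr in c(-1, -0.2, 0.1, 0.5)) {
    lo <- binarize_template(v, thr)$membership
    hi <- tryCatch(binarize_template(v, thr + 0.4)$membership,
                   error = function(e) array(FALSE, dim = dim(lo)))
    expect_true(all(lo[hi]))  # raising the threshold never adds members
  }
})

test_that("smoothing: identity at fwhm 0 and constant invariance", {
  set.seed(3)
  v <- tiny_volume(rnorm(125))
  expect_equal(gaussian_smooth(v, c(0, 0, 0))$values, v$values)
  const <- tiny_volume(2.5)
  sm <- gaussian_smooth(const, 12)
  expect_equal(sm$values, const$values, tolerance = 1e-12)
})

test_that("impulse response matches a dense convolution oracle", {
  n <- 21
  g <- vol_grid(c(n, n, n), spacing = c(2, 2, 2))
  vals <- numeric(n^3)
  v <- scalar_volume(g, vals)
  c0 <- (n + 1) / 2
  v$values[c0, c0, c0] <- 1

  kernel_1d <- function(fwhm) {
    sigma <- fwhm / (2 * sqrt(8 * log(2)))
    r <- max(1L, ceiling(4 * sigma))
    k <- exp(-((-r):r)^2 / (2 * sigma^2))
    list(k = k / sum(k), r = r)
  }

  # kernel well inside the grid: full-array dense-convolution oracle
  kk <- kernel_1d(6)
  expected <- array(0, dim = c(n, n, n))
  for (a in (-kk$r):kk$r) for (b in (-kk$r):kk$r) for (cc in (-kk$r):kk$r)
    expected[c0 + a, c0 + b, c0 + cc] <-
      kk$k[a + kk$r + 1] * kk$k[b + kk$r + 1] * kk$k[cc + kk$r + 1]
  expect_equal(gaussian_smooth(v, 6)$values, expected, tolerance = 1e-12)

  # 12-mm kernel: centre value equals the normalized 3-D Gaussian at 0
  kk12 <- kernel_1d(12)
  sm12 <- gaussian_smooth(v, 12)
  expect_equal(sm12$values[c0, c0, c0], kk12$k[kk12$r + 1]^3,
               tolerance = 1e-12)
})

test_that("smoothing preserves the global mean under reflective boundaries", {
  set.seed(4)
  v <- tiny_volume(rnorm(125, mean = 3), shape = c(5, 5, 5))
  sm <- gaussian_smooth(v, 10)
  expect_equal(mean(sm$values), mean(v$values), tolerance = 1e-10)
})

test_that("mask algebra and resampling behave set-theoretically", {
  g <- tiny_grid()
  a <- first_k_mask(g, 20)
  b <- first_k_mask(g, 10)
  expect_equal(mask_count(mask_intersect(a, b)), 10L)
  expect_equal(mask_count(mask_union(a, b)), 20L)
  expect_equal(mask_count(mask_difference(a, b)), 10L)
  expect_equal(mask_count(mask_complement(a)), 125L - 20L)

  # identity resample returns the same values
  set.seed(5)
  v <- scalar_volume(g, rnorm(125))
  expect_equal(resample_volume(v, g, "nearest")$values, v$values)
  expect_equal(resample_volume(v, g, "linear")$values, v$values,
               tolerance = 1e-12)
})
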