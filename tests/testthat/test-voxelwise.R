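test_that("single-voxel group contrast equals the pooled two-sample t", {
  set.seed(21)
  for (rep in 1:5) {
    ya <- rnorm(5, 1, 0.5)
    yb <- rnorm(5, 0.4, 0.5)
    cohort <- data.frame(group = rep(c("A", "B"), each = 5))
    X <- build_design(cohort, covariates = character(0))
    fit <- fit_voxelwise_glm(matrix(c(ya, yb), ncol = 1), X)
    tm <- group_contrast_tmap(fit, group_contrast(X, "A", "B"))
    oracle <- stats::t.test(ya, yb, var.equal = TRUE)
    expect_equal(tm$t, unname(oracle$statistic), tolerance = 1e-10)
    expect_equal(tm$df, unname(oracle$parameter))
  }
})

test_that("identically-zero responses give zero coefficients and variance", {
  cohort <- data.frame(group = rep(c("A", "B"), each = 6))
  X <- build_design(cohort, covariates = character(0))
  fit <- fit_voxelwise_glm(matrix(0, 12, 4), X)
  expect_equal(unname(fit$beta), matrix(0, 2, 4))
  expect_equal(unname(fit$sigma2), rep(0, 4))
  tm <- group_contrast_tmap(fit, group_contrast(X, "A", "B"))
  expect_equal(tm$t, rep(0, 4))
})

test_that("rank-deficient designs are rejected naming the collinear columns", {
  cohort <- toy_cohort()
  cohort$age2 <- cohort$age
  X <- build_design(cohort, covariates = c("age", "age2"))
  set.seed(22)
  expect_error(fit_voxelwise_glm(matrix(rnorm(20), ncol = 1), X),
               "rank-deficient.*age")
})

test_that("contrast t-maps are antisymmetric in the contrast", {
  set.seed(23)
  cohort <- toy_cohort()
  X <- build_design(cohort)
  Y <- matrix(rnorm(20 * 50), 20)
  fit <- fit_voxelwise_glm(Y, X)
  ctr <- group_contrast(X, "A", "B")
  expect_equal(group_contrast_tmap(fit, ctr)$t,
               -group_contrast_tmap(fit, -ctr)$t)
  expect_error(group_contrast_tmap(fit, ctr * 0), "all zero")
})

test_that("residuals are orthogonal to every design column", {
  set.seed(24)
  cohort <- toy_cohort(n_per_group = 12)
  X <- build_design(cohort)
  Y <- matrix(rnorm(24 * 30, sd = 2), 24)
  fit <- fit_voxelwise_glm(Y, X)
  resid <- Y - X %*% fit$beta
  rel <- max(abs(crossprod(X, resid))) / max(abs(Y))
  expect_lt(rel, 1e-8)
})

test_that("uncorrected thresholding attains the nominal voxelwise rate", {
  set.seed(25)
  cohort <- data.frame(group = rep(c("A", "B"), each = 20),
                       age = rnorm(40, 65, 8), sex = rbinom(40, 1, 0.5))
  X <- build_design(cohort)
  hits <- 0; total <- 0
  for (rep in 1:10) {
    Y <- matrix(rnorm(40 * 1000), 40)   # equal group means
    fit <- fit_voxelwise_glm(Y, X)
    tm <- group_contrast_tmap(fit, group_contrast(X, "A", "B"))
    crit <- qt(1 - 0.001 / 2, df = tm$df)
    hits <- hits + sum(abs(tm$t) > crit)
    total <- total + length(tm$t)
  }
  rate <- hits / total
  expect_lt(abs(rate - 0.001), 3 * sqrt(0.001 * 0.999 / total) + 1e-9)
})

test_that("extent filtering keeps 50-voxel clusters and drops 49-voxel ones", {
  g <- vol_grid(c(60, 2, 2), spacing = c(2, 2, 2))
  for (len in c(49, 50)) {
    tv <- numeric(prod(g$shape))
    arr <- array(0, dim = g$shape)
    arr[seq_len(ceiling(len / 2)), 1, 1] <- 10
    arr[seq_len(floor(len / 2)), 2, 1] <- 10   # 18-connected slab
    tm <- tmap(as.vector(arr), df = 30, grid = g)
    out <- threshold_tmap(tm, threshold_spec(0.001, "uncorrected", 50L,
                                             "one_sided"))
    if (len == 49) {
      expect_equal(mask_count(out$mask), 0L)
      expect_equal(nrow(out$clusters), 0L)
    } else {
      expect_equal(mask_count(out$mask), 50L)
      expect_equal(out$clusters$n_voxels, 50L)
      expect_equal(out$clusters$peak_t, 10)
    }
  }
})

test_that("a null t-map yields an empty mask and no clusters", {
  g <- tiny_grid()
  tm <- tmap(numeric(125), df = 20, grid = g)
  out <- threshold_tmap(tm, threshold_spec(0.05, "uncorrected", 0L,
                                           "two_sided"))
  expect_equal(mask_count(out$mask), 0L)
  expect_equal(nrow(out$clusters), 0L)
})

test_that("hand-checked toy map splits into two singleton clusters", {
  g <- vol_grid(c(3, 1, 1), spacing = c(2, 2, 2))
  tm <- tmap(c(10, 0.1, 10), df = 10, grid = g)
  # p(t=10, df=10) ~ 7e-7 < 0.001; p(t=0.1) ~ 0.46: middle voxel fails
  out <- threshold_tmap(tm, threshold_spec(0.001, "uncorrected", 1L,
                                           "one_sided"))
  expect_equal(mask_count(out$mask), 2L)
  expect_equal(nrow(out$clusters), 2L)
  expect_equal(sort(out$clusters$n_voxels), c(1L, 1L))
})

test_that("cluster connectivity is 18-neighbourhood (edges join, corners do not)", {
  g <- vol_grid(c(4, 4, 4), spacing = c(2, 2, 2))
  arr <- array(0, dim = g$shape)
  arr[1, 1, 1] <- 5; arr[2, 2, 1] <- 5    # edge neighbours: one cluster
  arr[4, 4, 4] <- 5; arr[3, 3, 3] <- 5    # corner neighbours: two clusters
  tm <- tmap(as.vector(arr), df = 30, grid = g)
  out <- threshold_tmap(tm, threshold_spec(0.01, "uncorrected", 1L,
                                           "one_sided"))
  expect_equal(nrow(out$clusters), 3L)
  expect_equal(sort(out$clusters$n_voxels), c(1L, 1L, 2L))
})

test_that("permutation nulls are deterministic and refuse too few permutations", {
  set.seed(26)
  cohort <- data.frame(group = rep(c("A", "B"), each = 8),
                       age = rnorm(16, 65, 8), sex = rbinom(16, 1, 0.5))
  X <- build_design(cohort)
  Y <- matrix(rnorm(16 * 40), 16)
  ctr <- group_contrast(X, "A", "B")
  n1 <- build_permutation_null(Y, X, ctr, n_perm = 120, rng_seed = 99)
  n2 <- build_permutation_null(Y, X, ctr, n_perm = 120, rng_seed = 99)
  n3 <- build_permutation_null(Y, X, ctr, n_perm = 120, rng_seed = 100)
  expect_identical(n1, n2)
  expect_false(identical(n1, n3))

  expect_error(build_permutation_null(Y, X, ctr, n_perm = 50, rng_seed = 1),
               ">= 100")
  g <- vol_grid(c(40, 1, 1), spacing = c(2, 2, 2))
  tm <- tmap(rnorm(40), df = 12, grid = g)
  expect_error(threshold_tmap(tm, threshold_spec(0.005, "fwe_permutation",
                                                 0L, "one_sided"), n1),
               "insufficient permutations")
})

test_that("the permutation-FWE pass set shrinks as alpha decreases", {
  set.seed(27)
  cohort <- data.frame(group = rep(c("A", "B"), each = 8))
  X <- build_design(cohort, covariates = character(0))
  Y <- matrix(rnorm(16 * 60), 16)
  Y[1:8, 1:10] <- Y[1:8, 1:10] + 3
  ctr <- group_contrast(X, "A", "B")
  nul <- build_permutation_null(Y, X, ctr, n_perm = 199, rng_seed = 5)
  g <- vol_grid(c(60, 1, 1), spacing = c(2, 2, 2))
  fit <- fit_voxelwise_glm(Y, X)
  tm0 <- group_contrast_tmap(fit, ctr)
  tm <- tmap(tm0$t, df = tm0$df, grid = g)
  pass10 <- threshold_tmap(tm, threshold_spec(0.10, "fwe_permutation", 0L,
                                              "one_sided"), nul)$mask
  pass05 <- threshold_tmap(tm, threshold_spec(0.05, "fwe_permutation", 0L,
                                              "one_sided"), nul)$mask
  expect_true(all(pass10$membership[pass05$membership]))
  expect_gte(mask_count(pass10), mask_count(pass05))
})

test_that("overlay maps encode the exact bit-set of containing masks", {
  g <- tiny_grid()
  a <- first_k_mask(g, 20)
  b <- first_k_mask(g, 10)
  ov <- overlay_significance_maps(list(A = a, B = b))
  # A contains B: overlap (code 3) has |B| voxels, code-1 has |A| - |B|
  expect_equal(sum(ov$volume$values == 3), 10)
  expect_equal(sum(ov$volume$values == 1), 10)
  expect_equal(sum(ov$volume$values == 2), 0)

  ident <- overlay_significance_maps(list(x = a, y = a))
  expect_true(all(ident$volume$values[a$membership] == 3))

  dis <- overlay_significance_maps(
    list(p = a, q = mask_complement(a)))
  expect_true(all(dis$volume$values %in% c(1, 2)))
})
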