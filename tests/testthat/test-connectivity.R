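# small grid whose centre hosts a 4-mm seed sphere
conn_grid <- function() vol_grid(c(8, 8, 8), spacing = c(2, 2, 2))

conn_seed <- function(g) {
  ctr <- voxel_to_world(g, matrix(c(4, 4, 4), 1))
  sphere_seed("seed", as.numeric(ctr), radius_mm = 4)
}

test_that("a perfectly seed-coupled cohort drives the seed-slope t beyond 100", {
  set.seed(31)
  g <- conn_grid()
  seed <- conn_seed(g)
  sph <- make_sphere_mask(g, seed)
  n <- 10
  s <- runif(n, 0.8, 1.2)
  vols <- lapply(seq_len(n), function(i) {
    v <- 2 * s[i] + rnorm(prod(g$shape), 0, 1e-9)
    vv <- array(v, dim = g$shape)
    vv[sph$membership] <- s[i]       # sphere carries the seed signal itself
    scalar_volume(g, vv)
  })
  cohort <- data.frame(group = "G", age = rnorm(n, 65, 5),
                       sex = rbinom(n, 1, 0.5))
  cm <- irca_covariance_map(vols, cohort, seed, full_mask(g))
  outside <- !sph$membership
  expect_true(all(cm$tmap$volume$values[outside] > 100))
})

test_that("seed-slope t is null-distributed when voxels are independent of the seed", {
  set.seed(32)
  g <- vol_grid(c(10, 10, 6), spacing = c(2, 2, 2))
  ctr <- voxel_to_world(g, matrix(c(5, 5, 3), 1))
  seed <- sphere_seed("s", as.numeric(ctr), 4)
  sph <- make_sphere_mask(g, seed)
  n <- 30
  vols <- lapply(seq_len(n), function(i)
    scalar_volume(g, rnorm(prod(g$shape))))
  cohort <- data.frame(group = "G", age = rnorm(n, 65, 5),
                       sex = rbinom(n, 1, 0.5))
  cm <- irca_covariance_map(vols, cohort, seed, full_mask(g))
  tvals <- cm$tmap$volume$values[!sph$membership]
  # model: intercept + seed + age + sex -> df = n - 4
  ks <- suppressWarnings(stats::ks.test(tvals, stats::pt, df = n - 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("irca matches explicit regression algebra and rejects bad input", {
  set.seed(33)
  g <- conn_grid()
  seed <- conn_seed(g)
  n <- 12
  vols <- lapply(seq_len(n), function(i)
    scalar_volume(g, rnorm(prod(g$shape), mean = 1, sd = 0.2)))
  cohort <- data.frame(group = "G", age = rnorm(n, 65, 5),
                       sex = rbinom(n, 1, 0.5))
  cm <- irca_covariance_map(vols, cohort, seed, full_mask(g))
  # oracle: lm() per voxel on 10 random voxels
  Y <- t(vapply(vols, function(v) as.vector(v$values),
                numeric(prod(g$shape))))
  pick <- sample(ncol(Y), 10)
  for (j in pick) {
    o <- summary(stats::lm(Y[, j] ~ cm$seed_values + cohort$age + cohort$sex))
    expect_equal(cm$tmap$volume$values[j],
                 unname(o$coefficients["cm$seed_values", "t value"]),
                 tolerance = 1e-8)
  }

  # group too small
  expect_error(irca_covariance_map(vols[1:4], cohort[1:4, ], seed,
                                   full_mask(g)), "sample-size")
  # seed sphere fully outside the gray-matter mask
  gm_without_sphere <- mask_complement(make_sphere_mask(g, seed))
  expect_error(irca_covariance_map(vols, cohort, seed, gm_without_sphere),
               "empty ROI")
})

test_that("GOF follows hand arithmetic on toy maps", {
  g <- vol_grid(c(4, 1, 1), spacing = c(2, 2, 2))
  tmpl <- network_template("net", binary_mask(g, c(TRUE, TRUE, FALSE, FALSE)))
  mask <- full_mask(g)

  tm <- tmap(c(3, 1, 0, -2), df = 10, grid = g)
  row <- goodness_of_fit(tm, tmpl, mask)
  expect_equal(row$t_inside, 2)
  expect_equal(row$t_outside, -1)
  expect_equal(row$gof, 3)

  # indicator map: t = c inside, 0 outside -> gof = c
  ind <- tmap(c(5, 5, 0, 0), df = 10, grid = g)
  expect_equal(goodness_of_fit(ind, tmpl, mask)$gof, 5)

  # constant map -> gof 0
  const <- tmap(rep(2, 4), df = 10, grid = g)
  expect_equal(goodness_of_fit(const, tmpl, mask)$gof, 0)

  # degenerate partitions error
  all_tmpl <- network_template("all", full_mask(g))
  expect_error(goodness_of_fit(tm, all_tmpl, mask), "partition error")
})

test_that("GOF is shift invariant and linear in the t-map", {
  set.seed(34)
  g <- tiny_grid()
  tmpl <- network_template("net", first_k_mask(g, 40))
  mask <- full_mask(g)
  t1 <- rnorm(125); t2 <- rnorm(125)
  g1 <- goodness_of_fit(tmap(t1, 10, g), tmpl, mask)$gof
  g1s <- goodness_of_fit(tmap(t1 + 7.3, 10, g), tmpl, mask)$gof
  expect_equal(g1s, g1, tolerance = 1e-12)
  g2 <- goodness_of_fit(tmap(t2, 10, g), tmpl, mask)$gof
  gl <- goodness_of_fit(tmap(2 * t1 - 0.5 * t2, 10, g), tmpl, mask)$gof
  expect_equal(gl, 2 * g1 - 0.5 * g2, tolerance = 1e-10)
})

test_that("gof_profile composes goodness_of_fit and validates its pairing", {
  set.seed(35)
  g <- conn_grid()
  seed <- conn_seed(g)
  n <- 8
  vols <- lapply(seq_len(n), function(i)
    scalar_volume(g, rnorm(prod(g$shape), 1, 0.1)))
  cohort <- data.frame(group = "G", age = rnorm(n, 65, 5),
                       sex = rbinom(n, 1, 0.5))
  tmpl <- network_template("netA", first_k_mask(g, 50))
  templates <- list(netA = tmpl, netB = network_template("netB",
                                                         first_k_mask(g, 50)))
  prof <- gof_profile(list(G = vols), list(G = cohort), templates,
                      list(seed = seed), full_mask(g),
                      pairing = c(netA = "seed", netB = "seed"))
  expect_equal(nrow(prof), 2L)
  # identical template masks -> identical GOF
  expect_equal(prof$gof[prof$network == "netA"],
               prof$gof[prof$network == "netB"])
  # single-row profile agrees with a direct goodness_of_fit call
  cm <- irca_covariance_map(vols, cohort, seed, full_mask(g))
  direct <- goodness_of_fit(cm, tmpl, full_mask(g))
  expect_equal(prof$gof[prof$network == "netA"], direct$gof)

  expect_error(gof_profile(list(G = vols), list(G = cohort), templates,
                           list(seed = seed), full_mask(g),
                           pairing = c(netA = "seed")),
               "configuration error")
})

test_that("interaction analysis negates under group relabelling and matches lm", {
  set.seed(36)
  g <- conn_grid()
  seed <- conn_seed(g)
  sph <- make_sphere_mask(g, seed)
  n <- 12
  make_group <- function(slope, label) {
    s <- runif(n, 0.8, 1.2)
    vols <- lapply(seq_len(n), function(i) {
      v <- array(1 + slope * (s[i] - 1) + rnorm(prod(g$shape), 0, 0.1),
                 dim = g$shape)
      v[sph$membership] <- s[i]
      scalar_volume(g, v)
    })
    list(vols = vols,
         cohort = data.frame(group = label, age = rnorm(n, 65, 5),
                             sex = rbinom(n, 1, 0.5)))
  }
  a <- make_group(1.0, "A")
  b <- make_group(0.0, "B")
  vols <- c(a$vols, b$vols)
  cohort <- rbind(a$cohort, b$cohort)
  r_ab <- interaction_analysis(vols, cohort, c("A", "B"), seed, full_mask(g))
  r_ba <- interaction_analysis(vols, cohort, c("B", "A"), seed, full_mask(g))
  # sphere voxels carry the seed value itself (an exact fit, t = 0/0):
  # compare where the model is non-degenerate
  out_vox <- !as.vector(sph$membership)
  expect_equal(r_ab$tmap$t[out_vox], -r_ba$tmap$t[out_vox],
               tolerance = 1e-10)

  # single-voxel oracle: lm with a group x seed interaction
  Y <- t(vapply(vols, function(v) as.vector(v$values),
                numeric(prod(g$shape))))
  j <- which(!sph$membership)[5]
  dat <- data.frame(y = Y[, j], grp = cohort$group, s = r_ab$seed_values,
                    age = cohort$age, sex = cohort$sex)
  o <- summary(stats::lm(y ~ grp + s + grp:s + age + sex, data = dat))
  # treatment coding: interaction coefficient is slope(B) - slope(A)
  expect_equal(r_ab$tmap$volume$values[j],
               -unname(o$coefficients["grpB:s", "t value"]),
               tolerance = 1e-8)

  expect_error(interaction_analysis(vols, cohort, c("A", "Z"), seed,
                                    full_mask(g)), "design error")
})

test_that("equal seed slopes give near-nominal interaction rates", {
  set.seed(37)
  g <- conn_grid()
  seed <- conn_seed(g)
  sph <- make_sphere_mask(g, seed)
  n <- 20
  vols <- list(); grp <- character(0)
  for (lab in c("A", "B")) {
    s <- runif(n, 0.8, 1.2)
    for (i in seq_len(n)) {
      v <- array(1 + 0.5 * (s[i] - 1) + rnorm(prod(g$shape), 0, 0.1),
                 dim = g$shape)
      v[sph$membership] <- s[i]
      vols <- c(vols, list(scalar_volume(g, v)))
      grp <- c(grp, lab)
    }
  }
  cohort <- data.frame(group = grp, age = rnorm(2 * n, 65, 5),
                       sex = rbinom(2 * n, 1, 0.5))
  r <- interaction_analysis(vols, cohort, c("A", "B"), seed, full_mask(g),
                            alphas = 0.05)
  outside <- !sph$membership
  rate <- mean(r$thresholds$p0.05$mask$membership[outside])
  expect_lt(abs(rate - 0.05), 0.03)
})
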