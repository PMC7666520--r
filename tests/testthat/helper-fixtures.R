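# small grids and volumes used across the suite

tiny_grid <- function(shape = c(5, 5, 5), spacing = 2) {
  vol_grid(shape, spacing = rep(spacing, 3))
}

# volume with given values (recycled) on a tiny grid
tiny_volume <- function(values, shape = c(5, 5, 5), spacing = 2) {
  g <- tiny_grid(shape, spacing)
  scalar_volume(g, rep_len(values, prod(shape)))
}

# mask selecting the first k voxels in array order
first_k_mask <- function(grid, k) {
  m <- rep(FALSE, prod(grid$shape))
  m[seq_len(k)] <- TRUE
  binary_mask(grid, m)
}

full_mask <- function(grid) binary_mask(grid, rep(TRUE, prod(grid$shape)))

# subject volumes on a flat 1-D-ish grid from a subjects x voxels matrix
volumes_from_matrix <- function(Y, grid = NULL) {
  if (is.null(grid)) grid <- vol_grid(c(ncol(Y), 1, 1), spacing = c(2, 2, 2))
  lapply(seq_len(nrow(Y)), function(i) scalar_volume(grid, Y[i, ]))
}

# a small cohort for design-matrix tests
toy_cohort <- function(n_per_group = 10, groups = c("A", "B"), seed = 7) {
  set.seed(seed)
  data.frame(
    subject_id = sprintf("s%02d", seq_len(n_per_group * length(groups))),
    group = rep(groups, each = n_per_group),
    age = runif(n_per_group * length(groups), 55, 80),
    sex = rbinom(n_per_group * length(groups), 1, 0.5),
    field_strength_t = sample(c(1.5, 3), n_per_group * length(groups),
                              replace = TRUE),
    icv_cm3 = rnorm(n_per_group * length(groups), 1450, 100),
    stringsAsFactors = FALSE)
}

# exhaustive pairwise AUC oracle: wins + half ties over all (pos, neg) pairs
pair_count_auc <- function(pos, neg) {
  wins <- 0
  for (p in pos) for (q in neg) wins <- wins + (p > q) + 0.5 * (p == q)
  wins / (length(pos) * length(neg))
}
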