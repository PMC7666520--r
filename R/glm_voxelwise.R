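#' Stack subject volumes into a subjects-by-voxels matrix
#'
#' @param volumes list of `scalar_volume`s (one per subject, same grid), or an
#'   already-stacked numeric matrix which is returned unchanged.
#' @param analysis_mask optional `binary_mask`; columns are restricted to
#'   in-mask voxels.
#' @return numeric matrix, one row per subject, one column per (in-mask) voxel.
#' @export
stack_volumes <- function(volumes, analysis_mask = NULL) {
  if (is.matrix(volumes)) return(volumes)
  stopifnot(is.list(volumes), length(volumes) >= 1L)
  g <- volumes[[1]]$grid
  for (v in volumes) check_same_grid(g, v)
  sel <- if (is.null(analysis_mask)) TRUE else {
    check_same_grid(g, analysis_mask)
    as.vector(analysis_mask$membership)
  }
  t(vapply(volumes, function(v) as.vector(v$values)[sel],
           numeric(if (isTRUE(sel)) prod(g$shape) else sum(sel))))
}

#' Build a design matrix for group comparisons with covariates
#'
#' Cell-means coding: one indicator column per group (jointly playing the
#' role of the intercept) plus covariate columns. Covariates are mean-centred
#' so that group columns estimate adjusted group means; contrast t-values are
#' unaffected by the centring. The result always has full column rank for
#' non-empty groups and non-constant covariates.
#'
#' @param cohort data.frame with at least a `group` column and any covariate
#'   columns requested.
#' @param covariates character vector of covariate column names (default
#'   `c("age", "sex")`).
#' @param center logical; mean-centre covariates (default TRUE).
#' @return numeric matrix with attribute `"groups"` naming the group columns.
#' @export
build_design <- function(cohort, covariates = c("age", "sex"), center = TRUE) {
  groups <- unique(as.character(cohort$group))
  X <- sapply(groups, function(g) as.numeric(cohort$group == g))
  colnames(X) <- groups
  for (cv in covariates) {
    if (!cv %in% names(cohort))
      stop(sprintf("covariate '%s' missing from cohort table", cv),
           call. = FALSE)
    x <- as.numeric(cohort[[cv]])
    if (stats::sd(x) == 0) next   # constant covariate: nothing to adjust for
    if (center) x <- x - mean(x)
    X <- cbind(X, x)
    colnames(X)[ncol(X)] <- cv
  }
  attr(X, "groups") <- groups
  X
}

#' Contrast vector for a pairwise group difference
#'
#' @param design matrix from [build_design()].
#' @param positive,negative group labels; the contrast estimates
#'   mean(positive) - mean(negative).
#' @return numeric contrast vector aligned with the design columns.
#' @export
group_contrast <- function(design, positive, negative) {
  cn <- colnames(design)
  if (!positive %in% cn || !negative %in% cn)
    stop(sprintf("groups '%s'/'%s' not in design columns", positive, negative),
         call. = FALSE)
  ctr <- numeric(ncol(design))
  names(ctr) <- cn
  ctr[positive] <- 1
  ctr[negative] <- -1
  ctr
}

#' Voxelwise ordinary least squares fit
#'
#' Fits the same linear model independently at every in-mask voxel:
#' `Y_v = X beta_v + eps`, by QR. Used for group ANCOVA contrasts and as the
#' engine behind the seed-covariance analyses.
#'
#' @param stacked_volumes list of per-subject `scalar_volume`s or an n x V
#'   matrix (rows = subjects in design order).
#' @param design full-column-rank design matrix (n rows).
#' @param analysis_mask optional `binary_mask` restricting the voxels
#'   (required when a grid-aware t-map is to be produced from a volume list).
#' @return an object of class `voxelwise_fit`: coefficients (p x V),
#'   residual variance (length V), df, the design, and grid/mask if known.
#' @export
fit_voxelwise_glm <- function(stacked_volumes, design, analysis_mask = NULL) {
  grid <- NULL
  if (!is.matrix(stacked_volumes) && is.list(stacked_volumes))
    grid <- stacked_volumes[[1]]$grid
  Y <- stack_volumes(stacked_volumes, analysis_mask)
  X <- as.matrix(design)
  if (nrow(X) != nrow(Y))
    stop("design rows must match number of subject volumes", call. = FALSE)
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    bad <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop(sprintf("design error: rank-deficient design; collinear columns: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (nrow(X) < ncol(X) + 2L)
    stop("sample-size error: need at least 2 more subjects than design columns",
         call. = FALSE)
  beta <- qr.coef(qx, Y)
  resid <- Y - X %*% beta
  df <- nrow(X) - ncol(X)
  sigma2 <- colSums(resid^2) / df
  structure(list(beta = beta, sigma2 = sigma2, df = df,
                 xtx_inv = chol2inv(chol(crossprod(X))), design = X,
                 grid = grid, mask = analysis_mask, n = nrow(X)),
            class = "voxelwise_fit")
}

#' t-map for a linear contrast of a voxelwise fit
#'
#' t = (c'beta) / sqrt(sigma2 * c'(X'X)^-1 c) per voxel, with the residual
#' degrees of freedom recorded.
#'
#' @param fit a `voxelwise_fit`.
#' @param contrast numeric vector, one weight per design column; must not be
#'   all zero.
#' @param label text label stored on the map.
#' @return a `tmap` object: t values (vector, and a `scalar_volume` when the
#'   fit carries grid and mask), df, label.
#' @export
group_contrast_tmap <- function(fit, contrast, label = "") {
  stopifnot(inherits(fit, "voxelwise_fit"))
  contrast <- as.numeric(contrast)
  if (length(contrast) != ncol(fit$design))
    stop("contrast length must equal number of design columns", call. = FALSE)
  if (all(contrast == 0))
    stop("domain error: contrast vector is all zero", call. = FALSE)
  num <- as.vector(contrast %*% fit$beta)
  cvc <- as.numeric(t(contrast) %*% fit$xtx_inv %*% contrast)
  tval <- num / sqrt(fit$sigma2 * cvc)
  tval[fit$sigma2 == 0 & num == 0] <- 0   # identically-zero response voxels
  tmap(tval, df = fit$df, grid = fit$grid, mask = fit$mask,
       contrast_label = label)
}

#' Construct a t-map object
#'
#' @param t_values numeric vector of t statistics (in-mask voxels, array
#'   order) or a full-length vector when no mask is given.
#' @param df residual degrees of freedom.
#' @param grid optional `vol_grid`.
#' @param mask optional `binary_mask` giving the in-mask voxel positions.
#' @param contrast_label text.
#' @return object of class `tmap` with fields `t` (vector), `df`, `grid`,
#'   `mask`, `contrast_label`, and `volume` (a `scalar_volume`, 0 outside the
#'   mask) when a grid is available.
#' @export
tmap <- function(t_values, df, grid = NULL, mask = NULL, contrast_label = "") {
  vol <- NULL
  if (!is.null(grid)) {
    full <- numeric(prod(grid$shape))
    if (!is.null(mask)) {
      sel <- as.vector(mask$membership)
      if (length(t_values) == sum(sel)) full[sel] <- t_values
      else if (length(t_values) == length(full)) full <- t_values
      else stop("t value count matches neither mask nor grid", call. = FALSE)
    } else {
      if (length(t_values) != length(full))
        stop("t value count must equal grid size when no mask given",
             call. = FALSE)
      full <- t_values
    }
    vol <- scalar_volume(grid, full)
  }
  structure(list(t = as.numeric(t_values), df = df, grid = grid, mask = mask,
                 volume = vol, contrast_label = contrast_label),
            class = "tmap")
}

#' Thresholding specification for statistical maps
#'
#' @param alpha significance level in (0, 1).
#' @param correction "uncorrected" or "fwe_permutation".
#' @param extent_k minimum cluster extent in voxels (>= 0); smaller connected
#'   components are discarded.
#' @param sidedness "one_sided" (positive direction) or "two_sided".
#' @return object of class `threshold_spec`.
#' @export
threshold_spec <- function(alpha = 0.05,
                           correction = c("uncorrected", "fwe_permutation"),
                           extent_k = 50L,
                           sidedness = c("one_sided", "two_sided")) {
  correction <- match.arg(correction)
  sidedness <- match.arg(sidedness)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must be in (0,1)", call. = FALSE)
  if (extent_k < 0) stop("extent_k must be >= 0", call. = FALSE)
  structure(list(alpha = alpha, correction = correction,
                 extent_k = as.integer(extent_k), sidedness = sidedness),
            class = "threshold_spec")
}

#' Threshold a t-map and extract clusters
#'
#' Uncorrected: a voxel passes iff its Student-t p-value (df from the map,
#' one- or two-sided per the spec) is below alpha. Permutation FWE: a voxel
#' passes iff its max-statistic permutation p-value
#' (1 + #\{null >= t\}) / (n_perm + 1) is <= alpha. Connected components
#' smaller than `extent_k` voxels (18-neighbourhood: faces + edges) are then
#' removed.
#'
#' @param tmap a `tmap` carrying a grid (needed for connectivity).
#' @param spec a `threshold_spec`.
#' @param null_max_t numeric vector of per-permutation maximum statistics
#'   from [build_permutation_null()]; required for FWE.
#' @return list with `mask` (`binary_mask` of surviving voxels) and
#'   `clusters` (data.frame: cluster_id, n_voxels, peak_t, x_mm, y_mm, z_mm).
#' @export
threshold_tmap <- function(tmap, spec, null_max_t = NULL) {
  stopifnot(inherits(tmap, "tmap"), inherits(spec, "threshold_spec"))
  if (is.null(tmap$grid))
    stop("thresholding requires a grid-aware t-map", call. = FALSE)
  tv <- tmap$volume$values
  stat <- if (spec$sidedness == "two_sided") abs(tv) else tv
  inmask <- if (is.null(tmap$mask)) array(TRUE, dim = tmap$grid$shape)
            else tmap$mask$membership
  if (spec$correction == "uncorrected") {
    p <- stats::pt(stat, df = tmap$df, lower.tail = FALSE)
    if (spec$sidedness == "two_sided") p <- 2 * p
    pass <- inmask & (p < spec$alpha)
  } else {
    if (is.null(null_max_t))
      stop("fwe_permutation requires a permutation null (null_max_t)",
           call. = FALSE)
    if (length(null_max_t) < 1 / spec$alpha)
      stop(sprintf(
        "insufficient permutations: %d permutations cannot resolve alpha = %g",
        length(null_max_t), spec$alpha), call. = FALSE)
    pfwe <- (1 + vapply(stat, function(s) sum(null_max_t >= s), 0)) /
      (length(null_max_t) + 1)
    pass <- inmask & (pfwe <= spec$alpha)
  }
  lab <- label_components(pass, connectivity = 18L)
  n_comp <- max(lab)
  keep_ids <- if (n_comp == 0L) integer(0) else
    which(tabulate(lab[lab > 0L], nbins = n_comp) >= spec$extent_k)
  keep <- array(lab %in% keep_ids & lab > 0, dim = dim(lab))
  clusters <- cluster_table(tmap, lab, keep_ids)
  list(mask = binary_mask(tmap$grid, keep), clusters = clusters)
}

cluster_table <- function(tmap, lab, keep_ids) {
  out <- data.frame(cluster_id = integer(), n_voxels = integer(),
                    peak_t = numeric(), x_mm = numeric(), y_mm = numeric(),
                    z_mm = numeric())
  if (!length(keep_ids)) return(out)
  tv <- tmap$volume$values
  for (i in seq_along(keep_ids)) {
    id <- keep_ids[i]
    vox <- which(lab == id, arr.ind = TRUE)
    tvals <- tv[vox]
    pk <- which.max(abs(tvals))
    xyz <- voxel_to_world(tmap$grid, vox[pk, , drop = FALSE])
    out[i, ] <- list(i, nrow(vox), tvals[pk], xyz[1], xyz[2], xyz[3])
  }
  out
}

# connected-component labelling of a logical 3-D array;
# connectivity 6 (faces), 18 (faces+edges) or 26 (faces+edges+corners)
label_components <- function(member, connectivity = 18L) {
  d <- dim(member)
  offs <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nz <- rowSums(offs != 0)
  offs <- switch(as.character(connectivity),
                 "6"  = offs[nz == 1, , drop = FALSE],
                 "18" = offs[nz >= 1 & nz <= 2, , drop = FALSE],
                 "26" = offs[nz >= 1, , drop = FALSE],
                 stop("connectivity must be 6, 18 or 26", call. = FALSE))
  lab <- array(0L, dim = d)
  todo <- which(member)
  nxt <- 0L
  for (start in todo) {
    if (lab[start] > 0L) next
    nxt <- nxt + 1L
    lab[start] <- nxt
    frontier <- matrix(arrayInd(start, d), ncol = 3)
    while (nrow(frontier)) {
      nb <- do.call(rbind, lapply(seq_len(nrow(offs)), function(r)
        sweep(frontier, 2, offs[r, ], "+")))
      ok <- nb[, 1] >= 1 & nb[, 1] <= d[1] &
            nb[, 2] >= 1 & nb[, 2] <= d[2] &
            nb[, 3] >= 1 & nb[, 3] <= d[3]
      nb <- nb[ok, , drop = FALSE]
      if (!nrow(nb)) break
      lin <- nb[, 1] + (nb[, 2] - 1L) * d[1] + (nb[, 3] - 1L) * d[1] * d[2]
      new <- member[lin] & lab[lin] == 0L
      lin <- unique(lin[new])
      if (!length(lin)) break
      lab[lin] <- nxt
      frontier <- arrayInd(lin, d)
    }
  }
  lab
}

#' Max-statistic permutation null for FWE thresholding
#'
#' Freedman-Lane scheme: the outcome is residualized against the nuisance
#' space (the design restricted to the null space of the contrast), the
#' residual rows are permuted, the nuisance fit is added back, and the full
#' model is refit; the maximum contrast statistic over voxels is recorded per
#' permutation. Deterministic given `rng_seed`.
#'
#' @param stacked_volumes volumes or n x V matrix as in [fit_voxelwise_glm()].
#' @param design full design matrix.
#' @param contrast contrast vector.
#' @param n_perm number of permutations (>= 100).
#' @param rng_seed integer seed.
#' @param analysis_mask optional mask (volume-list input).
#' @param sidedness "one_sided" records max t; "two_sided" records max |t|.
#' @return numeric vector of length `n_perm` of per-permutation maxima.
#' @export
build_permutation_null <- function(stacked_volumes, design, contrast, n_perm,
                                   rng_seed, analysis_mask = NULL,
                                   sidedness = c("one_sided", "two_sided")) {
  sidedness <- match.arg(sidedness)
  if (n_perm < 100)
    stop("n_perm must be >= 100", call. = FALSE)
  Y <- stack_volumes(stacked_volumes, analysis_mask)
  X <- as.matrix(design)
  contrast <- as.numeric(contrast)
  n <- nrow(X)
  # nuisance design: X restricted to the null space of the contrast
  K <- qr.Q(qr(matrix(contrast, ncol = 1)), complete = TRUE)[, -1, drop = FALSE]
  Z <- X %*% K
  hz <- Z %*% solve(crossprod(Z), t(Z))
  fitted_nuis <- hz %*% Y
  E <- Y - fitted_nuis
  xtx_inv <- chol2inv(chol(crossprod(X)))
  cvc <- as.numeric(t(contrast) %*% xtx_inv %*% contrast)
  A <- xtx_inv %*% t(X)             # beta = A %*% Y
  ca <- as.vector(t(contrast) %*% A)  # c'beta = ca %*% Y
  df <- n - ncol(X)
  set.seed(rng_seed)
  vapply(seq_len(n_perm), function(p) {
    idx <- sample.int(n)
    Ystar <- E[idx, , drop = FALSE] + fitted_nuis
    num <- as.vector(ca %*% Ystar)
    resid <- Ystar - X %*% (A %*% Ystar)
    s2 <- colSums(resid^2) / df
    tv <- num / sqrt(s2 * cvc)
    if (sidedness == "two_sided") max(abs(tv)) else max(tv)
  }, numeric(1))
}

#' Overlay labelled significance masks
#'
#' Encodes a set of binary masks as one integer-coded volume: each voxel
#' carries the bit-set of the masks containing it (mask i contributes
#' 2^(i-1)), so regional overlap between, e.g., patient-vs-control contrast
#' maps can be read off directly.
#'
#' @param masks named list of `binary_mask`s on one grid.
#' @return list with `volume` (integer-coded `scalar_volume`) and `labels`
#'   (data.frame mapping mask name to bit value).
#' @export
overlay_significance_maps <- function(masks) {
  stopifnot(is.list(masks), length(masks) >= 1L)
  g <- masks[[1]]$grid
  for (m in masks) check_same_grid(g, m, "masks")
  code <- numeric(prod(g$shape))
  for (i in seq_along(masks))
    code <- code + as.vector(masks[[i]]$membership) * 2^(i - 1)
  nm <- names(masks)
  if (is.null(nm)) nm <- paste0("mask", seq_along(masks))
  list(volume = scalar_volume(g, code),
       labels = data.frame(name = nm, bit = 2^(seq_along(masks) - 1)))
}
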