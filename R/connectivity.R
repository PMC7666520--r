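#' Seed-based interregional covariance map (IRCA) for one group
#'
#' Across the subjects of one diagnostic group, regresses every in-mask
#' voxel's SUVr on the mean SUVr within a seed sphere (restricted to the
#' gray-matter mask), adjusting for age and sex. The stored statistic is the
#' t-value of the seed slope: regions whose metabolism covaries with the seed
#' across subjects score high, which is read as metabolic connectivity.
#'
#' @param volumes list of per-subject `scalar_volume`s (SUVr maps) for the
#'   subjects of one group, in cohort row order.
#' @param cohort data.frame rows for the same subjects (columns `age`, `sex`).
#' @param seed a `sphere_seed`.
#' @param gm_mask gray-matter `binary_mask`; the seed mean is extracted over
#'   sphere-and-gray-matter voxels and the regression runs over this mask.
#' @param covariates covariate column names adjusted for (default age, sex).
#' @param group group label recorded on the result.
#' @return object of class `covariance_map`: fields `group`, `seed`,
#'   `tmap` (seed-slope t), `seed_values` (per-subject seed means).
#' @export
irca_covariance_map <- function(volumes, cohort, seed, gm_mask,
                                covariates = c("age", "sex"),
                                group = unique(as.character(cohort$group))) {
  n <- length(volumes)
  if (nrow(cohort) != n)
    stop("cohort rows must match number of volumes", call. = FALSE)
  if (n < length(covariates) + 3L)
    stop(sprintf(
      "sample-size error: group of %d is too small for %d covariates",
      n, length(covariates)), call. = FALSE)
  grid <- volumes[[1]]$grid
  check_same_grid(grid, gm_mask, "gray-matter mask")
  sphere <- make_sphere_mask(grid, seed)
  seed_vals <- vapply(volumes, extract_roi_mean, numeric(1),
                      roi = sphere, restrict = gm_mask)
  X <- cbind(intercept = 1, seed = seed_vals)
  for (cv in covariates) {
    x <- as.numeric(cohort[[cv]])
    if (stats::sd(x) == 0) next   # constant within this group: drop
    X <- cbind(X, x - mean(x))
    colnames(X)[ncol(X)] <- cv
  }
  fit <- fit_voxelwise_glm(volumes, X, analysis_mask = gm_mask)
  ctr <- as.numeric(colnames(X) == "seed")
  tm <- group_contrast_tmap(fit, ctr,
                            label = sprintf("%s seed slope [%s]",
                                            seed$name, paste(group,
                                                             collapse = "+")))
  structure(list(group = group, seed = seed, tmap = tm,
                 seed_values = seed_vals),
            class = "covariance_map")
}

#' Goodness-of-fit of a covariance map to a network template
#'
#' GOF = T_inside - T_outside: the mean t-value of the (unthresholded)
#' covariance map over the voxels inside the network template minus the mean
#' over the voxels outside it, both restricted to the analysis mask. A high
#' score indicates the pattern of metabolically covarying regions matches the
#' network's architecture.
#'
#' @param covmap a `covariance_map` (or a bare `tmap`).
#' @param template a `network_template` (or a bare `binary_mask`).
#' @param analysis_mask `binary_mask` defining "all voxels"; defaults to the
#'   mask the covariance map was computed on.
#' @return data.frame row: group, network, t_inside, t_outside, gof.
#' @export
goodness_of_fit <- function(covmap, template, analysis_mask = NULL) {
  tm <- if (inherits(covmap, "covariance_map")) covmap$tmap else covmap
  stopifnot(inherits(tm, "tmap"))
  tmask <- if (inherits(template, "network_template")) template$mask
           else template
  stopifnot(inherits(tmask, "binary_mask"))
  if (is.null(analysis_mask)) analysis_mask <- tm$mask
  if (is.null(analysis_mask))
    stop("an analysis mask is required", call. = FALSE)
  check_same_grid(tmask, analysis_mask, "template and analysis masks")
  inside <- analysis_mask$membership & tmask$membership
  outside <- analysis_mask$membership & !tmask$membership
  if (!any(inside) || !any(outside))
    stop("partition error: template must split the analysis mask into two non-empty parts",
         call. = FALSE)
  tv <- tm$volume$values
  t_in <- mean(tv[inside])
  t_out <- mean(tv[outside])
  data.frame(
    group = if (inherits(covmap, "covariance_map"))
      paste(covmap$group, collapse = "+") else NA_character_,
    network = if (inherits(template, "network_template")) template$name
              else NA_character_,
    t_inside = t_in, t_outside = t_out, gof = t_in - t_out,
    stringsAsFactors = FALSE)
}

#' GOF profile: all groups by all network templates
#'
#' Computes one covariance map per (group, seed) using the canonical
#' seed-template pairing and scores every map against every template. No
#' inferential statistics are attached: the maps are group-level objects.
#'
#' @param volumes_by_group named list (group -> list of subject volumes).
#' @param cohort_by_group named list (group -> cohort data.frame rows).
#' @param templates named list of `network_template`s.
#' @param seeds named list of `sphere_seed`s.
#' @param pairing named character vector network -> seed name (default
#'   [default_network_seed_pairing()]).
#' @param gm_mask gray-matter `binary_mask`.
#' @param matched_only if TRUE only score each seed's covariance map against
#'   its paired template; otherwise against every template.
#' @return data.frame: group, seed, network, t_inside, t_outside, gof.
#' @export
gof_profile <- function(volumes_by_group, cohort_by_group, templates, seeds,
                        gm_mask, pairing = default_network_seed_pairing(),
                        matched_only = FALSE) {
  miss <- setdiff(names(templates), names(pairing))
  if (length(miss))
    stop(sprintf("configuration error: no seed pairing for template(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unname(pairing[names(templates)]), names(seeds))
  if (length(bad))
    stop(sprintf("configuration error: paired seed(s) not supplied: %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  out <- list()
  for (g in names(volumes_by_group)) {
    for (seed_name in unique(unname(pairing[names(templates)]))) {
      map <- irca_covariance_map(volumes_by_group[[g]],
                                 cohort_by_group[[g]], seeds[[seed_name]],
                                 gm_mask, group = g)
      nets <- if (matched_only)
        names(pairing)[pairing == seed_name & names(pairing) %in%
                         names(templates)]
      else names(templates)
      for (net in nets) {
        row <- goodness_of_fit(map, templates[[net]], gm_mask)
        row$seed <- seed_name
        row$network <- net
        out[[length(out) + 1L]] <- row
      }
    }
  }
  res <- do.call(rbind, out)
  res[, c("group", "seed", "network", "t_inside", "t_outside", "gof")]
}

#' Voxelwise connectivity interaction analysis between two groups
#'
#' Tests, at every in-mask voxel, whether the slope of voxel SUVr on the
#' seed-region SUVr differs between two groups: the model carries a separate
#' intercept per group, a separate seed slope per group (the seed SUVr
#' entered per group), and shared age and sex effects. The reported t-map is
#' the slope-difference (interaction) contrast, groupA minus groupB.
#'
#' @param volumes list of per-subject volumes for both groups pooled.
#' @param cohort matching data.frame with columns `group`, `age`, `sex`;
#'   exactly two distinct groups.
#' @param group_pair character(2): (A, B); contrast is slope(A) - slope(B).
#' @param seed a `sphere_seed`.
#' @param gm_mask gray-matter `binary_mask`.
#' @param alphas uncorrected significance levels reported (default 0.001 and
#'   0.05, two-sided, no extent threshold).
#' @return object of class `interaction_result`: `tmap`, `group_pair`,
#'   `seed`, `slopes` (fitted per-group slopes is not retained; the contrast
#'   is), `thresholds` (named list of `binary_mask` + cluster tables).
#' @export
interaction_analysis <- function(volumes, cohort, group_pair, seed, gm_mask,
                                 alphas = c(0.001, 0.05)) {
  groups <- as.character(cohort$group)
  if (!all(group_pair %in% groups))
    stop(sprintf("design error: group(s) absent from cohort: %s",
                 paste(setdiff(group_pair, groups), collapse = ", ")),
         call. = FALSE)
  keep <- groups %in% group_pair
  volumes <- volumes[keep]
  cohort <- cohort[keep, , drop = FALSE]
  groups <- groups[keep]
  for (g in group_pair) if (sum(groups == g) < 5L)
    stop(sprintf("sample-size error: group '%s' has fewer than 5 subjects", g),
         call. = FALSE)
  grid <- volumes[[1]]$grid
  sphere <- make_sphere_mask(grid, seed)
  seed_vals <- vapply(volumes, extract_roi_mean, numeric(1),
                      roi = sphere, restrict = gm_mask)
  isA <- as.numeric(groups == group_pair[1])
  isB <- as.numeric(groups == group_pair[2])
  X <- cbind(gA = isA, gB = isB,
             seedA = seed_vals * isA, seedB = seed_vals * isB)
  for (cv in c("age", "sex")) {
    x <- as.numeric(cohort[[cv]])
    if (stats::sd(x) == 0) next
    X <- cbind(X, x - mean(x))
    colnames(X)[ncol(X)] <- cv
  }
  fit <- fit_voxelwise_glm(volumes, X, analysis_mask = gm_mask)
  ctr <- as.numeric(colnames(X) == "seedA") - as.numeric(colnames(X) == "seedB")
  tm <- group_contrast_tmap(fit, ctr,
                            label = sprintf("seed-slope %s minus %s (%s)",
                                            group_pair[1], group_pair[2],
                                            seed$name))
  thr <- lapply(alphas, function(a)
    threshold_tmap(tm, threshold_spec(alpha = a, correction = "uncorrected",
                                      extent_k = 0L,
                                      sidedness = "two_sided")))
  names(thr) <- paste0("p", alphas)
  structure(list(group_pair = group_pair, seed = seed, tmap = tm,
                 seed_values = seed_vals, thresholds = thr),
            class = "interaction_result")
}
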