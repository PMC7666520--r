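#' Group comparison of subcortical volumes (linear model, Bonferroni)
#'
#' Per structure, ordinary least squares of the (bilateral, cm^3) volume on
#' group indicators plus covariates (age, sex, scanner field strength, total
#' intracranial volume), followed by all pairwise group contrasts with
#' Wald t-tests. Bonferroni correction is applied over the full family
#' (structures x pairwise contrasts), and the family size is reported.
#'
#' @param table data.frame: `subject_id` plus one positive numeric column per
#'   structure.
#' @param cohort cohort data.frame (`subject_id`, `group`, covariates).
#' @param covariates covariate column names (default age, sex,
#'   field_strength_t, icv_cm3).
#' @param structures structure columns to test (default: all numeric columns
#'   of `table` other than subject_id).
#' @param pairs optional list of character(2) group pairs; default all
#'   unordered pairs.
#' @return data.frame: measure, group_a, group_b, effect (adjusted mean
#'   difference a - b), se, t, df, p_raw, p_adjusted, family_m, significant.
#' @export
subcortical_group_comparison <- function(table, cohort,
                                         covariates = c("age", "sex",
                                                        "field_strength_t",
                                                        "icv_cm3"),
                                         structures = NULL, pairs = NULL) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop(sprintf("completeness error: cohort lacks covariate(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  dat <- merge(table, cohort, by = "subject_id")
  if (nrow(dat) != nrow(table))
    stop("completeness error: cohort rows missing for some subjects",
         call. = FALSE)
  if (is.null(structures))
    structures <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                          "subject_id")
  groups <- unique(as.character(dat$group))
  if (length(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  X <- build_design(dat, covariates = covariates)
  rows <- list()
  for (st in structures) {
    fit <- fit_voxelwise_glm(matrix(dat[[st]], ncol = 1), X)
    for (pr in pairs) {
      ctr <- group_contrast(X, pr[1], pr[2])
      eff <- as.numeric(ctr %*% fit$beta)
      se <- sqrt(fit$sigma2 * as.numeric(t(ctr) %*% fit$xtx_inv %*% ctr))
      tv <- eff / se
      p <- 2 * stats::pt(-abs(tv), df = fit$df)
      rows[[length(rows) + 1L]] <-
        data.frame(measure = st, group_a = pr[1], group_b = pr[2],
                   effect = eff, se = se, t = tv, df = fit$df, p_raw = p,
                   stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_adjusted <- pmin(1, m * out$p_raw)
  out$family_m <- m
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}

#' Normalize regional WMH volumes to the cognitively normal group
#'
#' Divides every subject's regional WMH volume by the mean volume of the
#' cognitively normal reference subjects in that region, so normalized values
#' read as multiplicative factors relative to controls and the control means
#' equal 1.
#'
#' @param table data.frame: `subject_id` plus numeric regional columns.
#' @param cn_subjects character vector of reference (control) subject ids.
#' @return `table` with regional columns divided by the control means.
#' @export
wmh_normalize_to_controls <- function(table, cn_subjects) {
  cn <- table$subject_id %in% cn_subjects
  if (!any(cn)) stop("control subset is empty", call. = FALSE)
  regions <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                     "subject_id")
  for (rg in regions) {
    m <- mean(table[[rg]][cn])
    if (!is.finite(m) || m <= 0)
      stop(sprintf("normalization error: control mean for region '%s' is %g",
                   rg, m), call. = FALSE)
    table[[rg]] <- table[[rg]] / m
  }
  table
}

#' Group comparison of regional WMH volumes (gamma GLM, log link)
#'
#' Per region, fits a generalized linear model with gamma distribution and
#' log link on group indicators plus covariates, with the dispersion
#' estimated by Pearson chi-square over residual df, and performs pairwise
#' group Wald contrasts (t reference distribution on the residual df). The
#' contrast estimate is the log multiplicative factor group_a vs group_b. No
#' multiplicity correction is applied (regional volumes are strongly
#' correlated); `p_adjusted` equals `p_raw` and `family_m` is 1.
#'
#' Exact zeros are shifted by half the smallest positive observed value in
#' that region before fitting (gamma support excludes 0); the offset used is
#' recorded in the output.
#'
#' @param table data.frame: `subject_id` plus numeric regional columns
#'   (volumes >= 0).
#' @param cohort cohort data.frame.
#' @param covariates covariate columns (default age, sex, field_strength_t,
#'   icv_cm3).
#' @param regions regional columns to test (default all numeric).
#' @param pairs optional list of group pairs; default all unordered pairs.
#' @return data.frame: measure, group_a, group_b, effect (log factor), se, t,
#'   df, p_raw, p_adjusted, family_m, significant, zero_offset.
#' @export
wmh_group_comparison <- function(table, cohort,
                                 covariates = c("age", "sex",
                                                "field_strength_t",
                                                "icv_cm3"),
                                 regions = NULL, pairs = NULL) {
  miss <- setdiff(covariates, names(cohort))
  if (length(miss))
    stop(sprintf("completeness error: cohort lacks covariate(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  dat <- merge(table, cohort, by = "subject_id")
  if (is.null(regions))
    regions <- setdiff(names(table)[vapply(table, is.numeric, TRUE)],
                       "subject_id")
  groups <- unique(as.character(dat$group))
  if (is.null(pairs))
    pairs <- utils::combn(groups, 2, simplify = FALSE)
  X <- build_design(dat, covariates = covariates)
  rows <- list()
  for (rg in regions) {
    y <- dat[[rg]]
    if (any(y < 0)) stop(sprintf("negative WMH volume in region '%s'", rg),
                         call. = FALSE)
    offset_used <- 0
    if (any(y == 0)) {
      pos <- y[y > 0]
      if (!length(pos))
        stop(sprintf("fit error: region '%s' is identically zero", rg),
             call. = FALSE)
      offset_used <- min(pos) / 2
      y <- y + offset_used
    }
    fit <- tryCatch(
      stats::glm.fit(X, y, family = stats::Gamma(link = "log"),
                     control = stats::glm.control(maxit = 200)),
      error = function(e)
        stop(sprintf("fit error in region '%s': %s", rg,
                     conditionMessage(e)), call. = FALSE))
    if (!fit$converged)
      stop(sprintf("fit error: gamma GLM did not converge in region '%s'", rg),
           call. = FALSE)
    df <- nrow(X) - ncol(X)
    mu <- fit$fitted.values
    disp <- sum((y - mu)^2 / mu^2) / df          # Pearson chi^2 / df
    # weighted (X' W X)^-1 with W = working weights at convergence
    w <- fit$weights
    xtwx_inv <- chol2inv(chol(crossprod(X * sqrt(w))))
    beta <- fit$coefficients
    for (pr in pairs) {
      ctr <- group_contrast(X, pr[1], pr[2])
      eff <- as.numeric(ctr %*% beta)
      se <- sqrt(disp * as.numeric(t(ctr) %*% xtwx_inv %*% ctr))
      tv <- eff / se
      p <- 2 * stats::pt(-abs(tv), df = df)
      rows[[length(rows) + 1L]] <-
        data.frame(measure = rg, group_a = pr[1], group_b = pr[2],
                   effect = eff, se = se, t = tv, df = df, p_raw = p,
                   zero_offset = offset_used, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$p_adjusted <- out$p_raw
  out$family_m <- 1L
  out$significant <- out$p_adjusted < 0.05
  rownames(out) <- NULL
  out
}
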