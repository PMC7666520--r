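#' ROC AUC for one feature and one group pair
#'
#' AUC in the Mann-Whitney formulation with midrank tie handling:
#' P(X_pos > X_neg) + 0.5 P(X_pos = X_neg), reported for the fixed
#' orientation positive-over-negative (so values below 0.5 indicate the
#' negative group scores higher). The 95% confidence interval and the
#' two-sided p-value against AUC = 0.5 use the DeLong variance estimator
#' (via pROC); the CI is clipped to [0, 1].
#'
#' @param values_pos numeric feature values of the positive group.
#' @param values_neg numeric feature values of the negative group.
#' @param feature,pair optional labels carried through to the result.
#' @param conf_level confidence level (default 0.95).
#' @return one-row data.frame of class `roc_result`: feature, group_pos,
#'   group_neg, n_pos, n_neg, auc, ci_low, ci_high, direction, p_value.
#' @export
roc_auc <- function(values_pos, values_neg, feature = "feature",
                    pair = c("pos", "neg"), conf_level = 0.95) {
  values_pos <- as.numeric(values_pos)
  values_neg <- as.numeric(values_neg)
  if (!length(values_pos) || !length(values_neg))
    stop("both groups must be non-empty", call. = FALSE)
  if (anyNA(values_pos) || anyNA(values_neg))
    stop("feature values must not be missing", call. = FALSE)
  pooled <- c(values_pos, values_neg)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    warning("degenerate feature: pooled sample is constant; AUC = 0.5",
            call. = FALSE)
    auc <- 0.5
    ci <- c(0.5, 0.5)
    p <- 1
  } else {
    # Mann-Whitney with midranks: AUC = (R_pos - n_pos(n_pos+1)/2)/(n_pos*n_neg)
    r <- rank(pooled)
    n1 <- length(values_pos); n2 <- length(values_neg)
    auc <- (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
    ro <- suppressMessages(pROC::roc(
      response = c(rep(1, n1), rep(0, n2)), predictor = pooled,
      levels = c(0, 1), direction = "<", quiet = TRUE))
    # v == 0 (perfect separation) is handled below; silence pROC's note
    v <- suppressWarnings(pROC::var(ro, method = "delong"))
    # pROC orients its own AUC; the DeLong variance is orientation-free.
    # With a single observation in a group the variance is undefined.
    if (!is.finite(v)) {
      ci <- c(0, 1)
      p <- NA_real_
    } else {
      z <- stats::qnorm(1 - (1 - conf_level) / 2)
      half <- z * sqrt(v)
      ci <- pmin(1, pmax(0, c(auc - half, auc + half)))
      p <- if (v == 0) as.numeric(auc == 0.5) else
        2 * stats::pnorm(-abs(auc - 0.5) / sqrt(v))
    }
  }
  direction <- if (mean(values_pos) >= mean(values_neg)) "pos>neg" else
    "pos<neg"
  out <- data.frame(feature = feature, group_pos = pair[1], group_neg = pair[2],
                    n_pos = length(values_pos), n_neg = length(values_neg),
                    auc = auc, ci_low = ci[1], ci_high = ci[2],
                    direction = direction, p_value = p,
                    stringsAsFactors = FALSE)
  class(out) <- c("roc_result", class(out))
  out
}

#' Rank the discriminating power of all features for a group pair
#'
#' Runs [roc_auc()] on every feature column for the two groups and sorts by
#' the orientation-free discrimination score max(AUC, 1 - AUC), descending,
#' ties broken by feature name.
#'
#' @param features a feature table from [assemble_feature_table()] (columns
#'   `subject_id`, `group`, then numeric features).
#' @param pair character(2): (positive group, negative group).
#' @param top_k number of features to return (default all).
#' @return data.frame of `roc_result` rows plus a `score` column, ordered.
#' @export
rank_discriminators <- function(features, pair, top_k = Inf) {
  groups <- as.character(features$group)
  for (g in pair) if (!g %in% groups)
    stop(sprintf("unknown group label: '%s'", g), call. = FALSE)
  for (g in pair) if (sum(groups == g) < 2L)
    stop(sprintf("group '%s' needs at least 2 subjects", g), call. = FALSE)
  feat_cols <- setdiff(names(features), c("subject_id", "group"))
  feat_cols <- feat_cols[vapply(features[feat_cols], is.numeric, TRUE)]
  rows <- lapply(feat_cols, function(f) {
    if (anyNA(features[[f]][groups %in% pair]))
      stop(sprintf("feature '%s' has missing values for this pair", f),
           call. = FALSE)
    roc_auc(features[[f]][groups == pair[1]],
            features[[f]][groups == pair[2]],
            feature = f, pair = pair)
  })
  out <- do.call(rbind, rows)
  out$score <- pmax(out$auc, 1 - out$auc)
  out <- out[order(-out$score, out$feature), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top_k)
}
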