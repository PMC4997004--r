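#' Two-level t-test feature filters
#'
#' The three ordered emotion categories are reduced to two binary
#' partitions ("levels"): level 1 contrasts `low` against `{medium, high}`,
#' level 2 contrasts `{low, medium}` against `high`. Each feature is tested
#' at both levels with a two-sample t test and the two filter variants use
#' the results in opposite directions:
#'
#' * [ttest_select()] (Welch, unequal variances): a feature is *chosen* if
#'   its P value is below .05 at either level; if fewer than five features
#'   are chosen, the features with the smallest (min-over-levels) P values
#'   are added until five are selected.
#' * [ttest_homoscedastic_select()] (pooled variance): all features start
#'   chosen and any feature with P below .05 at either level is *deleted*
#'   (a small P marks the feature as unstable across the category split);
#'   if deletion empties the set, the five largest-P features are retained.
#'
#' Features with an undefined t statistic (zero variability in both groups)
#' are never auto-selected by the first variant and never deleted by the
#' second. A level whose partition has an empty side is skipped with a
#' warning; if both levels are degenerate the call errors.
#'
#' @name ttest-selection
NULL

#' The two binary category partitions
#' @return List of two logical-maker functions, one per level; each maps a
#'   label vector to TRUE (upper group) / FALSE (lower group).
#' @keywords internal
two_level_split <- function() {
  list(
    level1 = function(y) y != "low", # low vs {medium, high}
    level2 = function(y) y == "high" # {low, medium} vs high
  )
}

# Vectorized two-sample t test P values for every column of X.
# pooled = FALSE gives Welch. Returns NA where the statistic is undefined.
column_t_pvalues <- function(X, grp, pooled) {
  n1 <- sum(!grp)
  n2 <- sum(grp)
  if (n1 == 0 || n2 == 0 || n1 + n2 < 3) {
    return(rep(NA_real_, ncol(X)))
  }
  X1 <- X[!grp, , drop = FALSE]
  X2 <- X[grp, , drop = FALSE]
  m1 <- colMeans(X1)
  m2 <- colMeans(X2)
  v1 <- if (n1 > 1) (colSums(X1^2) - n1 * m1^2) / (n1 - 1) else rep(0, ncol(X))
  v2 <- if (n2 > 1) (colSums(X2^2) - n2 * m2^2) / (n2 - 1) else rep(0, ncol(X))
  v1 <- pmax(v1, 0)
  v2 <- pmax(v2, 0)
  if (pooled) {
    sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n2)
    df <- rep(n1 + n2 - 2, ncol(X))
  } else {
    se2 <- v1 / n1 + v2 / n2
    df <- se2^2 / (v1^2 / (n1^2 * (n1 - 1)) + v2^2 / (n2^2 * (n2 - 1)))
  }
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  p[!is.finite(t) | !is.finite(df) | se2 == 0] <- NA_real_
  unname(p)
}

level_pvalues <- function(X, y, pooled) {
  splits <- two_level_split()
  y <- as.character(y)
  ps <- lapply(names(splits), function(nm) {
    grp <- splits[[nm]](y)
    if (all(grp) || !any(grp)) {
      warn(sprintf("%s partition has an empty group; level skipped", nm))
      return(rep(NA_real_, ncol(X)))
    }
    column_t_pvalues(X, grp, pooled)
  })
  if (all(is.na(ps[[1]])) && all(is.na(ps[[2]])) &&
    (all(!is.na(y)) && length(unique(y)) < 2)) {
    abort("both levels have an empty group: labels are single-category",
      class = "moodphone_validation_error"
    )
  }
  tibble::tibble(
    feature = colnames(X),
    p_level1 = ps[[1]], p_level2 = ps[[2]],
    p_min = pmin(ps[[1]], ps[[2]], na.rm = TRUE)
  ) %>%
    dplyr::mutate(p_min = ifelse(is.finite(.data$p_min), .data$p_min, NA_real_))
}

new_selection <- function(method, selected, p_values = NULL, trajectory = NULL,
                          score = NA_real_) {
  structure(
    list(
      method = method, selected = selected,
      p_values = p_values, trajectory = trajectory, score = score
    ),
    class = "mood_selection"
  )
}

#' @export
print.mood_selection <- function(x, ...) {
  cat(sprintf(
    "<mood_selection: %s> %d features%s\n",
    x$method, length(x$selected),
    if (!is.na(x$score)) sprintf(", score %.3f", x$score) else ""
  ))
  invisible(x)
}

#' Welch two-level t-test selection
#'
#' @param x Feature matrix (tags x features, named columns).
#' @param y Category labels for one scale.
#' @param alpha Per-level significance threshold (default .05).
#' @param minimum Minimum number of features to return (default 5).
#' @return A `mood_selection` with `selected` ordered by increasing
#'   min-over-levels P value and a `p_values` tibble.
#' @export
ttest_select <- function(x, y, alpha = 0.05, minimum = 5) {
  X <- as_feature_matrix(x)
  pv <- level_pvalues(X, y, pooled = FALSE)
  hit <- (pv$p_level1 < alpha & !is.na(pv$p_level1)) |
    (pv$p_level2 < alpha & !is.na(pv$p_level2))
  sel <- pv$feature[hit]
  if (length(sel) < minimum) {
    pool <- pv %>%
      dplyr::filter(!hit, !is.na(.data$p_min)) %>%
      dplyr::arrange(.data$p_min)
    sel <- c(sel, utils::head(pool$feature, minimum - length(sel)))
  }
  ord <- order(pv$p_min[match(sel, pv$feature)])
  new_selection("ttest", sel[ord], p_values = pv)
}

#' Homoscedastic two-level t-test deletion
#'
#' @inheritParams ttest_select
#' @param keep_if_empty How many largest-P features to retain should the
#'   deletion empty the set (default 5).
#' @return A `mood_selection`; `selected` keeps the original column order.
#' @export
ttest_homoscedastic_select <- function(x, y, alpha = 0.05, keep_if_empty = 5) {
  X <- as_feature_matrix(x)
  pv <- level_pvalues(X, y, pooled = TRUE)
  del <- (pv$p_level1 < alpha & !is.na(pv$p_level1)) |
    (pv$p_level2 < alpha & !is.na(pv$p_level2))
  sel <- pv$feature[!del]
  if (length(sel) == 0) {
    keep <- pv %>%
      dplyr::arrange(dplyr::desc(.data$p_min)) %>%
      utils::head(keep_if_empty)
    sel <- pv$feature[pv$feature %in% keep$feature]
  }
  new_selection("ttest_homoscedastic", sel, p_values = pv)
}
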