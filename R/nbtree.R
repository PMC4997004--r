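# Naive Bayes decision tree (NBTree): a shallow decision tree whose leaves
# hold Gaussian naive Bayes models. At each node the candidate split is a
# threshold on the feature with the largest between/within-class variance
# ratio (threshold at the feature's class-pooled median); the split is
# accepted only if the size-weighted cross-validated accuracy of the child
# leaves' NB models improves on the node's own cross-validated NB accuracy.

nbtree_cv_acc <- function(X, y, folds = 3, seed = 1) {
  y <- droplevels(factor(y))
  n <- length(y)
  if (n < 2 || nlevels(y) < 2) {
    return(max(table(y)) / max(n, 1))
  }
  fold <- stratified_folds(y, min(folds, n), seed)
  correct <- 0
  for (f in unique(fold)) {
    tr <- fold != f
    if (!any(tr) || length(unique(y[tr])) == 0) next
    fit <- gnb_fit(X[tr, , drop = FALSE], y[tr])
    correct <- correct + sum(gnb_predict(fit, X[!tr, , drop = FALSE]) == y[!tr])
  }
  correct / n
}

nbtree_grow <- function(X, y, depth, max_depth, min_node, cv_folds, seed) {
  y <- droplevels(factor(y))
  leaf <- list(type = "leaf", fit = gnb_fit(X, y))
  if (depth >= max_depth || nrow(X) < 2 * min_node ||
    nlevels(y) < 2 || ncol(X) == 0) {
    return(leaf)
  }
  # split feature: largest between/within class F ratio
  mu_c <- rowsum(X, y) / as.numeric(table(y))
  grand <- colMeans(X)
  between <- colSums(as.numeric(table(y)) * sweep(mu_c, 2, grand)^2)
  within <- colSums(X^2) - nrow(X) * grand^2 - between
  f_ratio <- between / pmax(within, 1e-12)
  f_ratio[!is.finite(f_ratio)] <- 0
  j <- which.max(f_ratio)
  thr <- stats::median(X[, j])
  left <- X[, j] <= thr
  if (sum(left) < min_node / 2 || sum(!left) < min_node / 2) {
    return(leaf)
  }
  node_acc <- nbtree_cv_acc(X, y, cv_folds, seed)
  acc_l <- nbtree_cv_acc(X[left, , drop = FALSE], y[left], cv_folds, seed)
  acc_r <- nbtree_cv_acc(X[!left, , drop = FALSE], y[!left], cv_folds, seed)
  split_acc <- (sum(left) * acc_l + sum(!left) * acc_r) / nrow(X)
  if (split_acc <= node_acc + 1e-9) {
    return(leaf)
  }
  list(
    type = "split", feature = j, threshold = thr,
    left = nbtree_grow(X[left, , drop = FALSE], y[left],
      depth + 1, max_depth, min_node, cv_folds, seed
    ),
    right = nbtree_grow(X[!left, , drop = FALSE], y[!left],
      depth + 1, max_depth, min_node, cv_folds, seed
    )
  )
}

nbtree_fit <- function(X, y, max_depth = 3, min_node = 10, cv_folds = 3, seed = 1) {
  structure(
    list(root = nbtree_grow(X, y, 0, max_depth, min_node, cv_folds, seed)),
    class = "moodphone_nbtree"
  )
}

nbtree_predict_one <- function(node, x) {
  while (node$type == "split") {
    node <- if (x[node$feature] <= node$threshold) node$left else node$right
  }
  gnb_predict(node$fit, matrix(x, nrow = 1))
}

nbtree_predict <- function(fit, X) {
  vapply(seq_len(nrow(X)), function(i) {
    nbtree_predict_one(fit$root, X[i, ])
  }, character(1))
}
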