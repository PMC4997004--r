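#' Classifier families
#'
#' Four conventional families are available behind one train/predict
#' contract, each producing a three-category emotion prediction per scale:
#'
#' * `naive_bayes` — Gaussian naive Bayes with variance smoothing;
#' * `c45_tree` — a C4.5-style decision tree (information-gain splits with
#'   cost-complexity pruning, backed by [rpart::rpart()]);
#' * `nb_tree` — NBTree, a shallow decision tree with naive-Bayes leaves;
#'   a split is accepted only if cross-validated leaf accuracy improves;
#' * `svm` — RBF-kernel support vector machine (cost 1, median-heuristic
#'   kernel scale, backed by [e1071::svm()]), on internally standardized
#'   features.
#'
#' Models predict only categories seen at training; single-class training
#' data yields a constant predictor with a warning.
#'
#' @name classifier-families
NULL

#' The four classifier family names
#' @return `c("naive_bayes", "c45_tree", "nb_tree", "svm")`.
#' @export
classifier_families <- function() c("naive_bayes", "c45_tree", "nb_tree", "svm")

#' Describe a classifier to train
#'
#' @param family One of [classifier_families()].
#' @param seed Integer seed controlling any internal randomness (NBTree's
#'   internal cross-validation folds).
#' @return A `mood_classifier_spec`.
#' @export
mood_classifier <- function(family = classifier_families(), seed = 1L) {
  family <- match.arg(family)
  structure(list(family = family, seed = as.integer(seed)),
    class = "mood_classifier_spec"
  )
}

as_feature_matrix <- function(x, keys = NULL) {
  if (is.matrix(x)) {
    X <- x
  } else if (is.data.frame(x)) {
    X <- as.matrix(x)
  } else {
    X <- matrix(x, nrow = 1, dimnames = list(NULL, names(x)))
  }
  if (!is.null(keys)) {
    missing <- setdiff(keys, colnames(X))
    if (length(missing) > 0) {
      abort(sprintf("missing feature key(s): %s", paste(missing, collapse = ", ")),
        class = "moodphone_validation_error"
      )
    }
    X <- X[, keys, drop = FALSE]
  }
  X
}

# Deterministic stratified fold assignment: within each class, rows are
# randomly permuted (seeded) and dealt out cyclically.
stratified_folds <- function(y, folds, seed) {
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    perm <- with_seed(derive_seed(seed, paste0("fold:", cl)), sample(idx))
    fold[perm] <- rep_len(seq_len(folds), length(perm))
  }
  fold
}

# rpart needs syntactic column names and a data.frame
rpart_frame <- function(X) {
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(ncol(X)))
  df
}

median_heuristic_gamma <- function(X) {
  n <- nrow(X)
  idx <- if (n > 80) round(seq(1, n, length.out = 80)) else seq_len(n)
  d2 <- as.numeric(stats::dist(X[idx, , drop = FALSE]))^2
  m <- stats::median(d2[d2 > 0])
  if (!length(m) || !is.finite(m) || m <= 0) 1 / max(ncol(X), 1) else 1 / (2 * m)
}

#' Train a personalized emotion classifier
#'
#' @param spec A [mood_classifier()] spec (or a family name).
#' @param x Numeric feature matrix or data frame, one row per tag, columns
#'   named by feature key.
#' @param y Category labels (factor or character, levels low/medium/high).
#' @param ... Passed to family internals (currently unused).
#' @return A `mood_model` holding the fitted parameters, the feature keys it
#'   expects, and the categories seen at training.
#' @export
train_model <- function(spec, x, y, ...) {
  if (is.character(spec)) spec <- mood_classifier(spec)
  X <- as_feature_matrix(x)
  if (nrow(X) == 0) {
    abort("cannot train on an empty matrix", class = "moodphone_validation_error")
  }
  y <- factor(as.character(y), levels = emotion_levels())
  y <- droplevels(y)
  classes <- levels(y)
  constant <- length(classes) < 2 || ncol(X) == 0
  if (length(classes) < 2) {
    warn(sprintf("single training class '%s': constant predictor", classes[1]))
  }
  fit <- if (constant) {
    names(which.max(table(y)))
  } else if (spec$family == "naive_bayes") {
    gnb_fit(X, y)
  } else if (spec$family == "c45_tree") {
    df <- rpart_frame(X)
    df$.y <- y
    rpart::rpart(.y ~ ., df,
      method = "class",
      parms = list(split = "information"),
      control = rpart::rpart.control(minsplit = 5, cp = 0.01, xval = 0)
    )
  } else if (spec$family == "nb_tree") {
    nbtree_fit(X, y, seed = spec$seed)
  } else {
    center <- colMeans(X)
    scale <- apply(X, 2, stats::sd)
    scale[scale == 0] <- 1
    Xs <- sweep(sweep(X, 2, center), 2, scale, "/")
    list(
      svm = e1071::svm(Xs, y,
        kernel = "radial", cost = 1,
        gamma = median_heuristic_gamma(Xs), scale = FALSE
      ),
      center = center, scale = scale
    )
  }
  structure(
    list(
      family = spec$family, fit = fit, constant = constant,
      feature_keys = colnames(X), classes = classes, seed = spec$seed
    ),
    class = "mood_model"
  )
}

#' @export
print.mood_model <- function(x, ...) {
  cat(sprintf(
    "<mood_model: %s> %d features, classes {%s}%s\n",
    x$family, length(x$feature_keys), paste(x$classes, collapse = ", "),
    if (x$constant) " (constant)" else ""
  ))
  invisible(x)
}

#' Predict emotion categories
#'
#' @param object A `mood_model`.
#' @param newdata Feature matrix / data frame / named vector containing at
#'   least the model's expected feature keys (an error names any missing
#'   key).
#' @param ... Ignored.
#' @return Factor of predicted categories with levels low/medium/high.
#' @export
predict.mood_model <- function(object, newdata, ...) {
  X <- as_feature_matrix(newdata, object$feature_keys)
  pred <- if (object$constant) {
    rep(object$fit, nrow(X))
  } else if (object$family == "naive_bayes") {
    gnb_predict(object$fit, X)
  } else if (object$family == "c45_tree") {
    as.character(stats::predict(object$fit, rpart_frame(X), type = "class"))
  } else if (object$family == "nb_tree") {
    nbtree_predict(object$fit, X)
  } else {
    Xs <- sweep(sweep(X, 2, object$fit$center), 2, object$fit$scale, "/")
    as.character(stats::predict(object$fit$svm, Xs))
  }
  factor(pred, levels = emotion_levels(), ordered = TRUE)
}

#' Stratified cross-validated accuracy
#'
#' Mean held-out accuracy over seeded stratified folds; the fold assignment
#' is a deterministic function of the labels and `seed`, so repeated calls
#' agree exactly.
#'
#' @param spec Classifier spec or family name.
#' @param x Feature matrix.
#' @param y Labels.
#' @param folds Number of folds (default 5).
#' @param seed Fold seed.
#' @return Accuracy fraction in `[0, 1]`.
#' @export
cross_validated_accuracy <- function(spec, x, y, folds = 5, seed = 1) {
  if (is.character(spec)) spec <- mood_classifier(spec)
  X <- as_feature_matrix(x)
  y <- factor(as.character(y), levels = emotion_levels())
  n <- length(y)
  if (folds < 2) abort("folds must be >= 2", class = "moodphone_config_error")
  if (n < folds) {
    abort("fewer samples than folds", class = "moodphone_validation_error")
  }
  fold <- stratified_folds(droplevels(y), folds, seed)
  correct <- 0
  for (f in seq_len(folds)) {
    tr <- fold != f
    if (all(tr) || !any(tr)) next
    fit <- suppressWarnings(train_model(spec, X[tr, , drop = FALSE], y[tr]))
    correct <- correct +
      sum(as.character(predict(fit, X[!tr, , drop = FALSE])) == as.character(y[!tr]))
  }
  correct / n
}
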