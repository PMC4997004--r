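# Gaussian naive Bayes with variance smoothing, written as lean matrix code
# because it sits in the inner loop of the greedy wrappers and of NBTree
# (hundreds of refits per feature-selection run).

gnb_fit <- function(X, y) {
  y <- droplevels(factor(y))
  classes <- levels(y)
  n_c <- as.numeric(table(y))
  if (ncol(X) == 0) {
    return(structure(
      list(classes = classes, priors = n_c / length(y), mu = NULL, v = NULL),
      class = "moodphone_gnb"
    ))
  }
  sums <- rowsum(X, y)
  sq <- rowsum(X^2, y)
  mu <- sums / n_c
  v <- sq / n_c - mu^2
  v[v < 0] <- 0
  # per-feature smoothing keeps zero-variance features finite; tying the
  # epsilon to the feature's own pooled variance makes class log-densities
  # additive across features (exploited by the wrapper scorer)
  vt <- colMeans(X^2) - colMeans(X)^2
  eps <- 1e-9 * pmax(vt, 1)
  structure(
    list(
      classes = classes, priors = n_c / length(y), mu = mu,
      v = sweep(v, 2, eps, "+")
    ),
    class = "moodphone_gnb"
  )
}

gnb_predict <- function(fit, X) {
  k <- length(fit$classes)
  if (k == 1 || is.null(fit$mu)) {
    maj <- fit$classes[which.max(fit$priors)]
    return(rep(maj, nrow(X)))
  }
  n <- nrow(X)
  ll <- matrix(log(fit$priors), n, k, byrow = TRUE)
  for (j in seq_len(k)) {
    mu <- fit$mu[j, ]
    v <- fit$v[j, ]
    d <- sweep(X, 2, mu)
    ll[, j] <- ll[, j] - 0.5 * sum(log(2 * pi * v)) -
      0.5 * rowSums(sweep(d^2, 2, v, "/"))
  }
  fit$classes[max.col(ll, ties.method = "first")]
}

# Class log-posteriors (up to normalization removed), used by tests probing
# the symmetric two-class case.
gnb_posterior <- function(fit, X) {
  k <- length(fit$classes)
  n <- nrow(X)
  ll <- matrix(log(fit$priors), n, k, byrow = TRUE)
  if (!is.null(fit$mu) && k > 1) {
    for (j in seq_len(k)) {
      d <- sweep(X, 2, fit$mu[j, ])
      ll[, j] <- ll[, j] - 0.5 * sum(log(2 * pi * fit$v[j, ])) -
        0.5 * rowSums(sweep(d^2, 2, fit$v[j, ], "/"))
    }
  }
  p <- exp(ll - apply(ll, 1, max))
  p <- p / rowSums(p)
  colnames(p) <- fit$classes
  p
}
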