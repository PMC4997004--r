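test_that("every family separates linearly separable labels", {
  withr::with_seed(20, {
    y <- factor(rep(c("low", "high"), each = 20),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    X[, 1] <- ifelse(y == "high", 4, -4)
    for (fam in classifier_families()) {
      m <- train_model(fam, X, y)
      expect_equal(as.character(predict(m, X)), as.character(y), info = fam)
    }
  })
})

test_that("single-class training yields a constant predictor with a warning", {
  X <- matrix(rnorm(20), 10, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(rep("medium", 10), levels = c("low", "medium", "high"))
  for (fam in classifier_families()) {
    expect_warning(m <- train_model(fam, X, y), "single")
    expect_true(all(predict(m, X) == "medium"), info = fam)
  }
})

test_that("naive Bayes posterior is symmetric at the class midpoint", {
  y <- factor(rep(c("low", "high"), each = 30), levels = c("low", "high"))
  X <- matrix(c(rep(-2, 30), rep(2, 30)) + rep(c(-0.5, 0.5), 30), ncol = 1)
  fit <- moodphone:::gnb_fit(X, y)
  post <- moodphone:::gnb_posterior(fit, matrix(0, 1, 1))
  expect_equal(unname(post[1, "low"]), 0.5, tolerance = 1e-9)
})

test_that("in-package naive Bayes agrees with e1071 on random data", {
  withr::with_seed(21, {
    y <- factor(sample(c("low", "medium", "high"), 60, replace = TRUE),
      levels = c("low", "medium", "high")
    )
    X <- matrix(rnorm(60 * 4), 60, 4, dimnames = list(NULL, paste0("v", 1:4)))
    X[, 1] <- X[, 1] + as.integer(y)
    mine <- moodphone:::gnb_fit(X, y)
    ref <- e1071::naiveBayes(X, y)
    Xn <- matrix(rnorm(30 * 4), 30, 4, dimnames = list(NULL, paste0("v", 1:4)))
    Xn[, 1] <- Xn[, 1] + sample(1:3, 30, replace = TRUE)
    # variance estimators differ slightly (ML + smoothing vs n-1), so demand
    # near-total rather than exact agreement
    agree <- mean(moodphone:::gnb_predict(mine, Xn) ==
      as.character(stats::predict(ref, Xn)))
    expect_gte(agree, 0.95)
  })
})

test_that("predictions are deterministic and validate feature keys", {
  withr::with_seed(22, {
    pm <- planted_matrix(n = 30, p = 4, sep = 2)
    m <- train_model("svm", pm$X, pm$y)
    p1 <- predict(m, pm$X)
    expect_identical(p1, predict(m, pm$X))
    bad <- pm$X[, 1:2]
    expect_error(predict(m, bad), "feat3")
    # column order of newdata does not matter
    expect_identical(predict(m, pm$X[, 4:1]), p1)
  })
})

test_that("models survive a persistence round trip", {
  pm <- planted_matrix(n = 36, p = 4, sep = 2, seed = 23)
  for (fam in classifier_families()) {
    m <- train_model(fam, pm$X, pm$y)
    path <- withr::local_tempfile(fileext = ".rds")
    saveRDS(m, path)
    m2 <- readRDS(path)
    expect_identical(predict(m2, pm$X), predict(m, pm$X), info = fam)
  }
})

test_that("cross-validated accuracy is exact on separable data and honest on noise", {
  withr::with_seed(24, {
    y <- factor(rep(c("low", "high"), each = 25),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(50 * 2), 50, 2, dimnames = list(NULL, c("a", "b")))
    X[, 1] <- ifelse(y == "high", 6, -6)
    for (fam in classifier_families()) {
      expect_equal(cross_validated_accuracy(fam, X, y, 5, 1), 1, info = fam)
    }
    # labels independent of features, 3 balanced classes, n = 300:
    # accuracy stays inside the binomial interval around 1/3
    y0 <- factor(rep(c("low", "medium", "high"), 100),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X0 <- matrix(rnorm(300 * 4), 300, 4, dimnames = list(NULL, paste0("v", 1:4)))
    a <- cross_validated_accuracy("naive_bayes", X0, y0, 5, 1)
    expect_gte(a, 0.23)
    expect_lte(a, 0.43)
  })
})

test_that("cross-validation is deterministic given its seed and errors sensibly", {
  pm <- planted_matrix(n = 30, p = 3, sep = 1, seed = 25)
  a1 <- cross_validated_accuracy("c45_tree", pm$X, pm$y, 5, 7)
  a2 <- cross_validated_accuracy("c45_tree", pm$X, pm$y, 5, 7)
  expect_identical(a1, a2)
  expect_error(cross_validated_accuracy("naive_bayes", pm$X[1:3, ], pm$y[1:3], 5, 1),
    class = "moodphone_validation_error"
  )
  expect_error(cross_validated_accuracy("naive_bayes", pm$X, pm$y, 1, 1),
    class = "moodphone_config_error"
  )
})

test_that("training accuracy dominates cross-validated accuracy on average", {
  diffs <- list(naive_bayes = c(), c45_tree = c(), nb_tree = c(), svm = c())
  for (rep in 1:20) {
    pm <- planted_matrix(n = 45, p = 4, sep = 1, seed = 200 + rep)
    for (fam in names(diffs)) {
      m <- train_model(fam, pm$X, pm$y)
      tr_acc <- mean(as.character(predict(m, pm$X)) == as.character(pm$y))
      cv_acc <- cross_validated_accuracy(fam, pm$X, pm$y, 5, rep)
      diffs[[fam]] <- c(diffs[[fam]], tr_acc - cv_acc)
    }
  }
  for (fam in names(diffs)) expect_gte(mean(diffs[[fam]]), 0)
})

test_that("NBTree accepts a split only when it helps leaf accuracy", {
  withr::with_seed(26, {
    # two clusters whose class structure flips across the split: a single
    # NB leaf cannot model it, a split + NB leaves can
    n <- 80
    g <- rep(c(0, 1), each = n / 2)
    y <- factor(ifelse(g == 0, ifelse(rnorm(n) + 2 * rep(c(-1, 1), n / 2) > 0, "high", "low"),
      ifelse(rnorm(n) + 2 * rep(c(-1, 1), n / 2) > 0, "low", "high")
    ), levels = c("low", "medium", "high"))
    X <- cbind(split_var = g * 10, noise = rnorm(n), signal = 2 * rep(c(-1, 1), n / 2))
    fit <- moodphone:::nbtree_fit(X, y, seed = 1)
    expect_equal(fit$root$type, "split")
    # pure single-cluster data stays a leaf
    y2 <- factor(rep(c("low", "high"), n / 2), levels = c("low", "medium", "high"))
    X2 <- cbind(a = ifelse(y2 == "high", 3, -3), b = rnorm(n))
    fit2 <- moodphone:::nbtree_fit(X2, y2, seed = 1)
    expect_equal(fit2$root$type, "leaf")
  })
})
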