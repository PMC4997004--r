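test_that("t-test P values match the stats::t.test oracle at both levels", {
  pm <- planted_matrix(n = 45, p = 4, sep = 2, seed = 3)
  sel_w <- ttest_select(pm$X, pm$y)
  sel_p <- ttest_homoscedastic_select(pm$X, pm$y)
  g1 <- pm$y != "low"
  g2 <- pm$y == "high"
  for (j in seq_len(ncol(pm$X))) {
    f <- colnames(pm$X)[j]
    expect_equal(
      sel_w$p_values$p_level1[sel_w$p_values$feature == f],
      stats::t.test(pm$X[!g1, j], pm$X[g1, j], var.equal = FALSE)$p.value
    )
    expect_equal(
      sel_w$p_values$p_level2[sel_w$p_values$feature == f],
      stats::t.test(pm$X[!g2, j], pm$X[g2, j], var.equal = FALSE)$p.value
    )
    expect_equal(
      sel_p$p_values$p_level1[sel_p$p_values$feature == f],
      stats::t.test(pm$X[!g1, j], pm$X[g1, j], var.equal = TRUE)$p.value
    )
  }
})

test_that("a strongly separating feature is chosen with a tiny P value", {
  withr::with_seed(5, {
    y <- factor(rep(c("low", "medium", "high"), times = c(20, 10, 10)),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(40 * 3), 40, 3, dimnames = list(NULL, c("a", "b", "c")))
    X[, 1] <- X[, 1] + 10 * (y != "low") # 10 sd separation at level 1
    sel <- ttest_select(X, y)
    expect_true("a" %in% sel$selected)
    expect_lt(sel$p_values$p_level1[sel$p_values$feature == "a"], 1e-6)
  })
})

test_that("the minimum-5 fill and constant-feature exclusion apply", {
  withr::with_seed(6, {
    y <- factor(rep(c("low", "medium", "high"), length.out = 30),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(30 * 10), 30, 10, dimnames = list(NULL, paste0("n", 1:10)))
    X <- cbind(X, const = 1)
    sel <- ttest_select(X, y)
    expect_gte(length(sel$selected), 5)
    expect_false("const" %in% sel$selected)
    # pure-noise features rarely clear .05 at both levels; the fill tops the
    # selection up to exactly 5 when fewer cross the threshold
    pv <- sel$p_values
    hits <- sum((pv$p_level1 < .05 | pv$p_level2 < .05), na.rm = TRUE)
    if (hits < 5) expect_equal(length(sel$selected), 5)
  })
})

test_that("homoscedastic selection deletes small-P features", {
  withr::with_seed(7, {
    y <- factor(rep(c("low", "medium", "high"), length.out = 36),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(36 * 6), 36, 6, dimnames = list(NULL, paste0("f", 1:6)))
    X[, 2] <- X[, 2] + 8 * (y == "high") # small P at level 2 -> deleted
    sel <- ttest_homoscedastic_select(X, y)
    expect_false("f2" %in% sel$selected)
    pv <- sel$p_values
    survivors <- pv$feature[!((pv$p_level1 < .05 & !is.na(pv$p_level1)) |
      (pv$p_level2 < .05 & !is.na(pv$p_level2)))]
    expect_setequal(sel$selected, survivors)
  })
})

test_that("emptied homoscedastic selection keeps the 5 largest-P features", {
  withr::with_seed(8, {
    y <- factor(rep(c("low", "high"), each = 15),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(30 * 7), 30, 7, dimnames = list(NULL, paste0("f", 1:7)))
    X <- X + 10 * matrix(y == "high", 30, 7) # every feature separates
    sel <- suppressWarnings(ttest_homoscedastic_select(X, y))
    expect_equal(length(sel$selected), 5)
  })
})

test_that("single-category labels are an error, degenerate levels warn", {
  pm <- planted_matrix(n = 20, p = 3, seed = 9)
  y_one <- factor(rep("low", 20), levels = c("low", "medium", "high"))
  suppressWarnings(
    expect_error(ttest_select(pm$X, y_one), class = "moodphone_validation_error")
  )
  y_two <- factor(rep(c("low", "medium"), 10), levels = c("low", "medium", "high"))
  expect_warning(ttest_select(pm$X, y_two), "level2")
})

test_that("forward search finds a perfectly separating feature first", {
  withr::with_seed(10, {
    y <- factor(rep(c("low", "high"), each = 20),
      levels = c("low", "medium", "high"), ordered = TRUE
    )
    X <- matrix(rnorm(40 * 5), 40, 5, dimnames = list(NULL, paste0("f", 1:5)))
    X[, 3] <- ifelse(y == "high", 5, -5) + rnorm(40, 0, 0.1)
    sel <- greedy_select(X, y, "forward")
    expect_equal(sel$trajectory$feature[2], "f3")
    expect_equal(sel$trajectory$score[2], 1)
  })
})

test_that("a flat scorer stops forward empty and backward full", {
  # identical zero columns: every subset scores the majority baseline
  y <- factor(rep(c("low", "medium", "high"), length.out = 18),
    levels = c("low", "medium", "high"), ordered = TRUE
  )
  X <- matrix(0, 18, 4, dimnames = list(NULL, paste0("z", 1:4)))
  fwd <- greedy_select(X, y, "forward")
  expect_equal(length(fwd$selected), 0)
  bwd <- greedy_select(X, y, "backward")
  expect_equal(length(bwd$selected), 4)
  bi <- greedy_select(X, y, "bidirectional")
  expect_equal(length(bi$selected), 0)
})

test_that("forward search attains the exhaustive best-subset score", {
  pm <- planted_matrix(n = 48, p = 6, sep = 4, seed = 11)
  fwd <- greedy_select(pm$X, pm$y, "forward", folds = 5, seed = 2)
  scorer <- moodphone:::nb_cv_scorer(pm$X, pm$y, 5, 2)
  all_scores <- vapply(seq_len(2^6) - 1, function(mask) {
    scorer(which(bitwAnd(mask, 2^(0:5)) > 0))
  }, numeric(1))
  expect_equal(fwd$score, max(all_scores))
})

test_that("greedy trajectories improve monotonically to the returned score", {
  pm <- planted_matrix(n = 45, p = 8, sep = 2, seed = 12)
  for (dir in c("forward", "backward", "bidirectional")) {
    sel <- greedy_select(pm$X, pm$y, dir)
    expect_true(all(diff(sel$trajectory$score) > 0), info = dir)
    expect_gte(sel$score, max(sel$trajectory$score))
    # determinism
    sel2 <- greedy_select(pm$X, pm$y, dir)
    expect_identical(sel$selected, sel2$selected)
    expect_identical(sel$score, sel2$score)
  }
  expect_error(greedy_select(pm$X[, 0], pm$y, "forward"),
    class = "moodphone_config_error"
  )
})

test_that("planted features are recovered by the t-test filter", {
  hits <- 0
  total <- 0
  for (rep in 1:20) {
    cfg <- fast_sim_config(
      n_users = 1, seed = 100 + rep, n_days_train = 10, n_days_eval = 0,
      effect_size = 30, noise_sd = 5
    )
    sim <- simulate_user(cfg, "u01", raw = FALSE)
    u <- sim_train_user(sim)
    d <- build_design_matrix(u$events, u$tags, 2)
    for (scale in emotion_scales()) {
      sel <- suppressWarnings(ttest_select(d$features, d$labels[[scale]]))
      hits <- hits + sum(cfg$planted %in% sel$selected)
      total <- total + length(cfg$planted)
    }
  }
  expect_gte(hits / total, 0.8)
})
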