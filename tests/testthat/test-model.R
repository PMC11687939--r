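test_that("stratified split is exhaustive, proportionate and reproducible", {
  set.seed(2)
  X <- matrix(rnorm(375 * 4), 375, 4)
  y <- factor(rep(c("stable", "unstable"), c(297, 78)))
  sp <- split_data(X, y, 0.70, seed = 5)
  expect_equal(sort(c(sp$train_idx, sp$test_idx)), 1:375)
  expect_true(length(sp$train$y) %in% c(262, 263))
  # stratified within one subject of 70% per class
  for (lv in levels(y)) {
    got <- sum(sp$train$y == lv)
    expect_lte(abs(got - 0.7 * sum(y == lv)), 1)
  }
  sp2 <- split_data(X, y, 0.70, seed = 5)
  expect_identical(sp$train_idx, sp2$train_idx)

  expect_error(split_data(X, factor(rep("stable", 375))), "both classes")
})

test_that("min-max scaling uses training bounds without clipping", {
  Xtr <- cbind(a = c(10, 20), b = c(5, 5))
  expect_warning(sc <- fit_scaler(Xtr), "constant feature")
  out <- apply_scaler(sc, cbind(a = c(15, 25), b = c(7, 5)))
  expect_equal(out[, "a"], c(0.5, 1.5))   # midpoint, and out-of-range > 1
  expect_equal(out[, "b"], c(0, 0))
})

test_that("SMOTE balances classes with on-segment synthetics", {
  set.seed(8)
  Xmaj <- matrix(rnorm(80, 5), 40, 2)
  Xmin <- matrix(rnorm(24), 12, 2)
  X <- rbind(Xmaj, Xmin)
  y <- factor(rep(c("stable", "unstable"), c(40, 12)))
  aug <- smote(X, y, k = 5, seed = 4)
  expect_equal(as.integer(table(aug$y)), c(40L, 40L))
  expect_equal(aug$X[1:52, ], X)           # originals untouched, majority first
  synth <- aug$X[53:80, , drop = FALSE]
  on_segment <- function(p) {
    for (i in 1:11) for (j in (i + 1):12) {
      a <- Xmin[i, ]; b <- Xmin[j, ]
      d <- b - a
      u <- if (abs(d[1]) > abs(d[2])) (p[1] - a[1]) / d[1] else (p[2] - a[2]) / d[2]
      if (u >= -1e-9 && u <= 1 + 1e-9 &&
          max(abs(a + u * d - p)) < 1e-9) return(TRUE)
    }
    FALSE
  }
  expect_true(all(apply(synth, 1, on_segment)))

  # identical minority points generate identical synthetics
  Xid <- rbind(matrix(rnorm(40, 5), 20, 2),
               matrix(1, 4, 2))
  yid <- factor(rep(c("a", "b"), c(20, 4)))
  augid <- suppressWarnings(smote(Xid, yid, seed = 1))
  expect_true(all(augid$X[augid$y == "b", ] == 1))

  expect_warning(smote(rbind(Xmaj, Xmin[1:3, ]),
                       factor(rep(c("a", "b"), c(40, 3))), k = 5, seed = 1),
                 "reducing SMOTE k")
  expect_error(smote(rbind(Xmaj, Xmin[1, , drop = FALSE]),
                     factor(rep(c("a", "b"), c(40, 1)))), "minority")
})

test_that("AUROC equals the rank-statistic oracle and its tie conventions", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(0, 0, 1, 1)), 1)
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  set.seed(44)
  for (rep_i in 1:10) {
    n <- sample(10:40, 1)
    scores <- round(runif(n), 2)          # rounding forces ties
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0 || sum(y) == n) next
    expect_equal(auroc(scores, y), auroc_oracle(scores, y), tolerance = 1e-12)
  }
  expect_error(auroc(runif(5), rep(1, 5)), "single class")
})

test_that("AUROC agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(45)
  scores <- runif(60); y <- rbinom(60, 1, 0.3)
  expect_equal(auroc(scores, y),
               as.numeric(pROC::auc(pROC::roc(y, scores, quiet = TRUE))),
               tolerance = 1e-12)
})

test_that("confusion metrics satisfy their identities for arbitrary counts", {
  set.seed(6)
  for (rep_i in 1:10) {
    cnt <- rpois(4, 20) + 1
    m <- confusion_metrics(cnt[1], cnt[2], cnt[3], cnt[4])
    expect_equal(m$sensitivity, cnt[4] / (cnt[4] + cnt[3]))
    expect_equal(m$specificity, cnt[1] / (cnt[1] + cnt[2]))
    expect_equal(m$accuracy, (cnt[1] + cnt[4]) / sum(cnt))
  }
})

toy_data <- function(n = 60, seed = 1, sep = 3) {
  set.seed(seed)
  y <- factor(rep(c("stable", "unstable"), c(n * 2 / 3, n / 3)))
  X <- matrix(rnorm(n * 4), n, 4)
  X[y == "unstable", 1] <- X[y == "unstable", 1] + sep
  colnames(X) <- paste0("f", 1:4)
  list(X = X, y = y)
}

test_that("every classifier family trains, is seeded and predicts probabilities", {
  d <- toy_data(seed = 3)
  for (fam in c("logistic", "knn", "svm", "random_forest")) {
    spec <- classifier_spec(fam, seed = 7)
    m1 <- train_classifier(spec, d$X, d$y)
    p1 <- predict(m1, d$X)
    p2 <- predict(train_classifier(spec, d$X, d$y), d$X)
    expect_true(all(p1 >= 0 & p1 <= 1), info = fam)
    expect_equal(p1, p2, info = fam)
    expect_gt(auroc(p1, d$y), 0.9)
  }
  # default spec is the optimized random forest
  spec <- classifier_spec()
  expect_equal(spec$family, "random_forest")
  expect_equal(spec$hyperparameters, list(num_trees = 50, max_depth = 6))
})

test_that("evaluation thresholds scores and reports AUROC", {
  d <- toy_data(seed = 9)
  m <- train_classifier(classifier_spec(seed = 2), d$X, d$y)
  rep_ <- evaluate_classifier(m, d$X, d$y)
  expect_equal(rep_$tn + rep_$fp + rep_$fn + rep_$tp, length(d$y))
  expect_equal(rep_$sensitivity, rep_$tp / (rep_$tp + rep_$fn))
  expect_gt(rep_$auroc, 0.9)
  expect_error(evaluate_classifier(m, d$X, factor(rep("stable", length(d$y)),
                                                  levels = levels(d$y))),
               "single class")
})

test_that("grid search selects by cross-validated AUROC, reproducibly", {
  d <- toy_data(n = 90, seed = 12)
  single <- list(classifier_spec("random_forest", num_trees = 50,
                                 max_depth = 6, seed = 1))
  gs <- grid_search(d$X, d$y, grid = single, seed = 3)
  expect_equal(gs$best$family, "random_forest")
  expect_equal(gs$best$hyperparameters$num_trees, 50)
  expect_gte(gs$cv_auroc, 0.95)            # separable toy

  small_grid <- c(list(classifier_spec("logistic", seed = 1)), single)
  g1 <- grid_search(d$X, d$y, grid = small_grid, seed = 3)
  g2 <- grid_search(d$X, d$y, grid = small_grid, seed = 3)
  expect_equal(g1$best$family, g2$best$family)
  expect_equal(g1$table$mean_auroc, g2$table$mean_auroc)

  expect_error(grid_search(d$X, d$y, grid = list(), seed = 1), "empty grid")
})

test_that("PIH threshold rules fire as defined", {
  # any post-induction MAP sample below 65
  mapv <- rep(80, 1201); mapv[700] <- 64
  sig <- make_signal(rep(120, 1201), map = mapv)
  expect_true(pih_classify(sig, "map_lt_65"))
  mapv[700] <- 66
  expect_false(pih_classify(make_signal(rep(120, 1201), map = mapv),
                            "map_lt_65"))

  # SAP drop > 20% of the pre-induction mean
  sapv <- rep(150, 1201); sapv[600:1201] <- 119    # 20.7% drop
  expect_true(pih_classify(make_signal(sapv), "sap_drop_gt_20pct"))
  sapv[600:1201] <- 121                            # 19.3%
  expect_false(pih_classify(make_signal(sapv), "sap_drop_gt_20pct"))
})

test_that("overlap report matches set arithmetic", {
  a <- c(TRUE, TRUE, FALSE, FALSE)
  expect_equal(overlap_report(a, a)$overlap_pih_also_model, 1)
  expect_equal(overlap_report(a, !a)$overlap_pih_also_model, 0)
  set.seed(10)
  m <- runif(50) < 0.3; p <- runif(50) < 0.4
  rep_ <- overlap_report(m, p)
  expect_equal(rep_$incidence_pih, sum(p) / 50)
  expect_equal(rep_$overlap_pih_also_model, length(intersect(which(m), which(p))) / sum(p))
})
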