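#' Stratified train/test split
#'
#' Partitions a feature table into disjoint, exhaustive train and test sets,
#' stratified by class (per-class training counts are `round(fraction *
#' n_class)`, so the overall proportion is within one subject of the
#' target), reproducible under the seed.
#'
#' @param X data frame or matrix of features (no id column).
#' @param y class labels, coercible to factor with two levels; the second
#'   level is treated as the positive (unstable) class throughout.
#' @param train_fraction proportion assigned to training (default 0.70).
#' @param seed integer RNG seed.
#' @return List with `train = list(X, y)`, `test = list(X, y)`, and the
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_data <- function(X, y, train_fraction = 0.70, seed = 1) {
  stopifnot(train_fraction > 0, train_fraction < 1, nrow(X) == length(y))
  y <- as.factor(y)
  if (nlevels(droplevels(y)) < 2) stop("both classes must be present", call. = FALSE)
  if (any(table(y) < 2)) stop("each class needs >= 2 members", call. = FALSE)
  set.seed(seed)
  train_idx <- integer(0)
  for (lv in levels(y)) {
    idx <- which(y == lv)
    n_tr <- round(train_fraction * length(idx))
    n_tr <- min(max(n_tr, 1L), length(idx) - 1L)
    train_idx <- c(train_idx, sample(idx, n_tr))
  }
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_along(y), train_idx)
  list(train = list(X = X[train_idx, , drop = FALSE], y = y[train_idx]),
       test = list(X = X[test_idx, , drop = FALSE], y = y[test_idx]),
       train_idx = train_idx, test_idx = test_idx)
}

#' Min-max feature scaling
#'
#' Learns per-feature `(min, max)` bounds from the training data and maps
#' each value to `(x - min) / (max - min)`. Test values outside the training
#' range are allowed to fall below 0 or above 1 (no clipping). A feature
#' constant in training maps to 0 everywhere, with a warning.
#'
#' @param X training feature matrix/data frame.
#' @return `fit_scaler` returns a `scaler_state` (per-feature min and max);
#'   `apply_scaler` returns the scaled matrix.
#' @export
fit_scaler <- function(X) {
  X <- as.matrix(X)
  if (nrow(X) == 0) stop("empty training data", call. = FALSE)
  mins <- apply(X, 2, min); maxs <- apply(X, 2, max)
  if (any(maxs == mins))
    warning("constant feature(s) map to 0: ",
            paste(colnames(X)[maxs == mins], collapse = ", "), call. = FALSE)
  structure(list(min = mins, max = maxs), class = "scaler_state")
}

#' @rdname fit_scaler
#' @param state a `scaler_state` from `fit_scaler`.
#' @export
apply_scaler <- function(state, X) {
  stopifnot(inherits(state, "scaler_state"))
  X <- as.matrix(X)
  rng <- state$max - state$min
  out <- sweep(X, 2, state$min)
  out <- sweep(out, 2, ifelse(rng == 0, 1, rng), "/")
  out[, rng == 0] <- 0
  out
}

#' Synthetic minority oversampling (SMOTE)
#'
#' Oversamples the minority class to exactly the majority count. Each
#' synthetic observation is `x + u * (x_nn - x)` with `u ~ Uniform(0, 1)`
#' and `x_nn` one of the `k` nearest minority-class neighbours of `x`
#' (Euclidean distance in the supplied — normally scaled — feature space).
#' The majority class is untouched. When the minority class has fewer than
#' `k + 1` members, `k` is reduced with a warning.
#'
#' @param X feature matrix (scaled).
#' @param y factor labels; the minority class is detected from the counts.
#' @param k number of nearest neighbours (default 5).
#' @param seed integer RNG seed.
#' @return List `X`, `y` with the synthetic rows appended.
#' @export
smote <- function(X, y, k = 5, seed = 1) {
  X <- as.matrix(X); y <- as.factor(y)
  stopifnot(nrow(X) == length(y), nlevels(droplevels(y)) == 2)
  tab <- table(y)
  minority <- names(tab)[which.min(tab)]
  n_min <- min(tab); n_maj <- max(tab)
  if (n_min <= 1) stop("minority class has <= 1 member", call. = FALSE)
  n_new <- n_maj - n_min
  if (n_new == 0) return(list(X = X, y = y))
  if (n_min < k + 1) {
    warning("reducing SMOTE k from ", k, " to ", n_min - 1, call. = FALSE)
    k <- n_min - 1
  }
  Xm <- X[y == minority, , drop = FALSE]
  d <- as.matrix(stats::dist(Xm))
  diag(d) <- Inf
  nn <- apply(d, 1, function(r) order(r)[seq_len(k)])
  nn <- if (k == 1) matrix(nn, ncol = 1) else t(nn)
  set.seed(seed)
  base <- rep_len(seq_len(n_min), n_new)
  pick <- nn[cbind(base, sample.int(k, n_new, replace = TRUE))]
  u <- stats::runif(n_new)
  Xnew <- Xm[base, , drop = FALSE] +
    u * (Xm[pick, , drop = FALSE] - Xm[base, , drop = FALSE])
  rownames(Xnew) <- NULL
  list(X = rbind(X, Xnew),
       y = factor(c(as.character(y), rep(minority, n_new)), levels = levels(y)))
}

#' Classifier specification
#'
#' The four families tested by the harness: logistic regression (`stats::glm`),
#' K-nearest neighbours (`class::knn`), support vector machine
#' (`e1071::svm`, RBF kernel), and random forest (`ranger`). The default is
#' the harness's optimized configuration: a random forest with 50 trees and
#' maximum depth 6.
#'
#' @param family one of `"logistic"`, `"knn"`, `"svm"`, `"random_forest"`.
#' @param ... hyperparameters: `k` (knn), `cost` (svm), `num_trees` and
#'   `max_depth` (random forest).
#' @param seed integer seed used at training time.
#' @return A list of class `classifier_spec`.
#' @export
classifier_spec <- function(family = c("random_forest", "logistic", "knn", "svm"),
                            ..., seed = 1) {
  family <- match.arg(family)
  hp <- list(...)
  defaults <- switch(family,
    random_forest = list(num_trees = 50, max_depth = 6),
    knn = list(k = 5),
    svm = list(cost = 1),
    logistic = list())
  hp <- utils::modifyList(defaults, hp)
  structure(list(family = family, hyperparameters = hp, seed = seed),
            class = "classifier_spec")
}

#' @export
print.classifier_spec <- function(x, ...) {
  hp <- if (length(x$hyperparameters))
    paste(names(x$hyperparameters), unlist(x$hyperparameters),
          sep = "=", collapse = ", ") else "defaults"
  cat(sprintf("<classifier_spec> %s (%s)\n", x$family, hp))
  invisible(x)
}

#' Train a classifier
#'
#' Fits the specified classifier on a (scaled, typically SMOTE-augmented)
#' training set. The returned model predicts the probability of the
#' positive class — the second factor level, conventionally `"unstable"`.
#'
#' @param spec a [classifier_spec()].
#' @param X training feature matrix.
#' @param y training labels (two-level factor).
#' @return A `hemo_classifier` with a [predict()] method returning
#'   probabilities.
#' @export
train_classifier <- function(spec, X, y) {
  stopifnot(inherits(spec, "classifier_spec"))
  X <- as.matrix(X); y <- as.factor(y)
  pos <- levels(y)[2]
  hp <- spec$hyperparameters
  set.seed(spec$seed)
  fit <- switch(spec$family,
    logistic = {
      df <- data.frame(.y = y, X, check.names = FALSE)
      suppressWarnings(stats::glm(.y ~ ., data = df, family = stats::binomial()))
    },
    knn = list(X = X, y = y, k = hp$k),
    svm = e1071::svm(X, y, cost = hp$cost, kernel = "radial",
                     probability = TRUE, scale = FALSE),
    random_forest = ranger::ranger(
      x = X, y = y, num.trees = hp$num_trees, max.depth = hp$max_depth,
      probability = TRUE, seed = spec$seed, num.threads = 1))
  structure(list(spec = spec, fit = fit, positive = pos,
                 features = colnames(X)),
            class = "hemo_classifier")
}

#' @export
#' @param object a `hemo_classifier`.
#' @param newdata feature matrix with the training columns.
#' @param ... unused.
#' @rdname train_classifier
predict.hemo_classifier <- function(object, newdata, ...) {
  X <- as.matrix(newdata)[, object$features, drop = FALSE]
  spec <- object$spec
  switch(spec$family,
    logistic = {
      df <- as.data.frame(X, check.names = FALSE)
      as.numeric(stats::predict(object$fit, newdata = df, type = "response"))
    },
    knn = {
      set.seed(spec$seed)  # knn breaks distance ties at random
      pr <- class::knn(object$fit$X, X, object$fit$y, k = object$fit$k,
                       prob = TRUE)
      p_win <- attr(pr, "prob")
      ifelse(pr == object$positive, p_win, 1 - p_win)
    },
    svm = {
      pred <- stats::predict(object$fit, X, probability = TRUE)
      attr(pred, "probabilities")[, object$positive]
    },
    random_forest =
      stats::predict(object$fit, data = X,
                     num.threads = 1)$predictions[, object$positive])
}

#' Area under the ROC curve
#'
#' AUROC by the mid-rank Mann-Whitney statistic, equivalent to the
#' trapezoidal rule over all score thresholds with tied scores handled by
#' mid-rank equivalence.
#'
#' @param scores numeric classifier scores.
#' @param labels binary labels (positive = second factor level, or 1).
#' @return AUROC in \[0, 1\].
#' @export
auroc <- function(scores, labels) {
  y <- if (is.factor(labels)) labels == levels(labels)[2] else labels == 1
  n1 <- sum(y); n0 <- sum(!y)
  if (n1 == 0 || n0 == 0)
    stop("AUROC undefined: test set has a single class", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Confusion-matrix metrics from counts
#'
#' The evaluation identities: sensitivity = tp/(tp+fn), specificity =
#' tn/(tn+fp), accuracy = (tp+tn)/total.
#'
#' @param tn,fp,fn,tp confusion counts (positive class = unstable).
#' @return Named list with the counts and the three proportions.
#' @export
confusion_metrics <- function(tn, fp, fn, tp) {
  list(tn = tn, fp = fp, fn = fn, tp = tp,
       sensitivity = tp / (tp + fn),
       specificity = tn / (tn + fp),
       accuracy = (tp + tn) / (tn + fp + fn + tp))
}

#' Evaluate a trained classifier on a held-out set
#'
#' Thresholds the predicted probabilities to form the confusion matrix and
#' computes sensitivity, specificity, accuracy and AUROC.
#'
#' @param model a `hemo_classifier`.
#' @param X,y held-out features and labels (both classes present).
#' @param threshold probability cutoff for the confusion matrix.
#' @return A list of class `eval_report`: counts, metrics, `auroc`,
#'   `threshold`, and the score vector.
#' @export
evaluate_classifier <- function(model, X, y, threshold = 0.5) {
  y <- as.factor(y)
  if (nrow(as.matrix(X)) == 0) stop("empty test set", call. = FALSE)
  scores <- predict(model, X)
  pos <- y == levels(y)[2]
  pred <- scores >= threshold
  rep <- confusion_metrics(tn = sum(!pred & !pos), fp = sum(pred & !pos),
                           fn = sum(!pred & pos), tp = sum(pred & pos))
  rep$auroc <- auroc(scores, y)
  rep$threshold <- threshold
  rep$scores <- scores
  class(rep) <- "eval_report"
  rep
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(paste0("<eval_report> AUROC %.3f | sens %.3f spec %.3f acc %.3f",
                     " (threshold %.2f)\n  tn=%d fp=%d fn=%d tp=%d\n"),
              x$auroc, x$sensitivity, x$specificity, x$accuracy,
              x$threshold, x$tn, x$fp, x$fn, x$tp))
  invisible(x)
}

#' ROC curve points
#'
#' Sensitivity / 1-specificity pairs over all score thresholds, for
#' plotting or CSV export.
#'
#' @param scores,labels as in [auroc()].
#' @return Data frame with `threshold`, `sensitivity`, `specificity`.
#' @export
roc_points <- function(scores, labels) {
  y <- if (is.factor(labels)) labels == levels(labels)[2] else labels == 1
  th <- c(Inf, sort(unique(scores), decreasing = TRUE))
  do.call(rbind, lapply(th, function(cut) {
    pred <- scores >= cut
    data.frame(threshold = cut,
               sensitivity = sum(pred & y) / sum(y),
               specificity = sum(!pred & !y) / sum(!y))
  }))
}

#' Default hyperparameter grid
#'
#' Grid-search candidates for the four classifier families, ordered from
#' simpler to more complex within each family so that AUROC ties resolve
#' toward the simpler model.
#'
#' @param seed seed stored in every spec.
#' @return List of [classifier_spec()]s.
#' @export
default_grid <- function(seed = 1) {
  c(list(classifier_spec("logistic", seed = seed)),
    lapply(c(11, 7, 5, 3), function(k) classifier_spec("knn", k = k, seed = seed)),
    lapply(c(0.1, 1, 10), function(cst) classifier_spec("svm", cost = cst, seed = seed)),
    lapply(list(c(50, 4), c(50, 6), c(100, 6), c(100, 8)), function(p)
      classifier_spec("random_forest", num_trees = p[1], max_depth = p[2],
                      seed = seed)))
}

stratified_folds <- function(y, n_folds, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- sample(which(y == lv))
    fold[idx] <- rep_len(seq_len(n_folds), length(idx))
  }
  fold
}

#' Grid search by cross-validated AUROC
#'
#' Stratified k-fold cross-validation on the training set; within each
#' fold, SMOTE is applied to the fold's training portion only (never the
#' validation portion, preventing leakage), the candidate is trained, and
#' the validation AUROC recorded. The selected specification maximizes mean
#' CV AUROC; exact ties resolve toward the earlier (simpler) grid entry.
#'
#' @param X scaled training features.
#' @param y training labels.
#' @param grid list of [classifier_spec()]s (default [default_grid()]).
#' @param cv_folds number of folds (default 5).
#' @param seed integer seed for fold assignment and SMOTE.
#' @return List: `best` (a spec), `cv_auroc` (its mean CV AUROC), `table`
#'   (per-candidate mean and sd).
#' @export
grid_search <- function(X, y, grid = default_grid(), cv_folds = 5, seed = 1) {
  if (length(grid) == 0) stop("empty grid", call. = FALSE)
  X <- as.matrix(X); y <- as.factor(y)
  fold <- stratified_folds(y, cv_folds, seed)
  if (any(tapply(seq_along(y), fold, function(i) nlevels(droplevels(y[i]))) < 2))
    stop("a fold lacks both classes; reduce cv_folds", call. = FALSE)
  fold_data <- lapply(seq_len(cv_folds), function(f) {
    tr <- fold != f
    aug <- smote(X[tr, , drop = FALSE], y[tr], seed = seed + f)
    list(aug = aug, Xv = X[!tr, , drop = FALSE], yv = y[!tr])
  })
  scores <- vapply(grid, function(spec) {
    aucs <- vapply(fold_data, function(fd) {
      m <- train_classifier(spec, fd$aug$X, fd$aug$y)
      auroc(predict(m, fd$Xv), fd$yv)
    }, numeric(1))
    c(mean(aucs), stats::sd(aucs))
  }, numeric(2))
  best_i <- which.max(scores[1, ])   # which.max: earliest on ties
  tab <- data.frame(
    family = vapply(grid, `[[`, "", "family"),
    params = vapply(grid, function(s)
      paste(names(s$hyperparameters), unlist(s$hyperparameters),
            sep = "=", collapse = ","), ""),
    mean_auroc = scores[1, ], sd_auroc = scores[2, ])
  list(best = grid[[best_i]], cv_auroc = scores[1, best_i], table = tab)
}

#' Threshold-based postinduction hypotension comparators
#'
#' The two conventional PIH definitions the instability classifier is
#' compared against: `map_lt_65` flags a record when any available
#' post-induction (section C) MAP sample is below 65 mmHg; `sap_drop_gt_20pct`
#' flags when the post-induction SAP minimum falls below 80% of the
#' pre-induction (section A) mean SAP.
#'
#' @param signal a smoothed `clean_signal`.
#' @param rule `"map_lt_65"` or `"sap_drop_gt_20pct"`.
#' @return Logical flag.
#' @export
pih_classify <- function(signal, rule = c("map_lt_65", "sap_drop_gt_20pct")) {
  rule <- match.arg(rule)
  idxC <- section_index(signal, "C") & signal$mask
  if (rule == "map_lt_65")
    return(any(signal$map[idxC] < 65, na.rm = TRUE))
  baseline <- section_stats(signal, "sap", "A")$mean
  min(signal$sap[idxC], na.rm = TRUE) < 0.8 * baseline
}

#' Incidence and overlap of two instability definitions
#'
#' @param model_unstable,pih_positive logical vectors over the same
#'   subjects.
#' @return List: incidence of each definition and the fraction of
#'   PIH-positive subjects also labelled unstable by the model.
#' @export
overlap_report <- function(model_unstable, pih_positive) {
  stopifnot(length(model_unstable) == length(pih_positive))
  list(incidence_model = mean(model_unstable),
       incidence_pih = mean(pih_positive),
       overlap_pih_also_model = if (sum(pih_positive) == 0) NA_real_
       else mean(model_unstable[pih_positive]))
}
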