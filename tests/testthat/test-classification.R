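test_that("perfect predictions score perfectly", {
  truth <- rep(c("pain", "control"), each = 5)
  scores <- rep(c(0.9, 0.1), each = 5)
  m <- compute_metrics(truth, truth, scores)
  expect_equal(unname(m[c("accuracy", "balanced_accuracy", "sensitivity",
                          "specificity", "auc")]), rep(1, 5))
  expect_equal(unname(m["brier"]), mean((scores - rep(c(1, 0), each = 5))^2))
})

test_that("balanced accuracy is the arithmetic mean of sensitivity and specificity", {
  # construct folds with exact sensitivity/specificity to three decimals
  make_fold <- function(sens, spec, n = 1000) {
    truth <- rep(c("pain", "control"), each = n)
    pred <- c(rep("pain", sens * n), rep("control", n - sens * n),
              rep("pain", n - spec * n), rep("control", spec * n))
    compute_metrics(truth, pred, ifelse(pred == "pain", 0.9, 0.1))
  }
  rf <- make_fold(0.782, 0.840)
  expect_equal(unname(rf["sensitivity"]), 0.782)
  expect_equal(unname(rf["specificity"]), 0.840)
  expect_equal(unname(rf["balanced_accuracy"]), 0.811)
  knn <- make_fold(0.798, 0.782)
  expect_equal(unname(knn["balanced_accuracy"]), 0.790)
})

test_that("rank-based AUC equals brute-force pair counting, ties counted half", {
  brute_auc <- function(truth, scores, positive = "pain") {
    pos <- scores[truth == positive]
    neg <- scores[truth != positive]
    cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    mean(cmp)
  }
  set.seed(31)
  for (i in 1:20) {
    n <- sample(10:30, 1)
    truth <- sample(rep(c("pain", "control"), length.out = n))
    scores <- round(runif(n), 2)  # rounding forces ties
    m <- compute_metrics(truth, ifelse(scores >= 0.5, "pain", "control"),
                         scores)
    expect_equal(unname(m["auc"]), brute_auc(truth, scores))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(32)
  truth <- sample(rep(c("pain", "control"), 15))
  scores <- runif(30)
  m <- compute_metrics(truth, ifelse(scores >= 0.5, "pain", "control"), scores)
  ref <- pROC::auc(pROC::roc(response = truth, predictor = scores,
                             levels = c("control", "pain"),
                             direction = "<", quiet = TRUE))
  expect_equal(unname(m["auc"]), as.numeric(ref))
})

test_that("single-class test sets raise a metric error", {
  expect_error(compute_metrics(rep("pain", 4), rep("pain", 4), runif(4)),
               "single-class")
})

test_that("summaries use means and 2.5/97.5% empirical quantiles", {
  rec <- data.frame(algorithm = "rf", rep = 1, fold = 1:100,
                    accuracy = 0.7, balanced_accuracy = 0.7,
                    sensitivity = 0.7, specificity = 0.7,
                    auc = (1:100) / 100, brier = 0.2)
  cv <- structure(list(records = rec), class = "swe_cv")
  s <- summary(cv)
  auc <- s[s$metric == "auc", ]
  expect_equal(auc$mean, mean((1:100) / 100))
  # type-7 order-statistic oracle: quantile at p is x[(n-1)p + 1] interpolated
  idx <- (100 - 1) * c(0.025, 0.975) + 1
  xs <- sort((1:100) / 100)
  oracle <- xs[floor(idx)] + (idx - floor(idx)) *
    (xs[ceiling(idx)] - xs[floor(idx)])
  expect_equal(c(auc$ci_low, auc$ci_high), oracle)
  # identical values collapse the interval
  acc <- s[s$metric == "accuracy", ]
  expect_equal(c(acc$mean, acc$ci_low, acc$ci_high), rep(0.7, 3))
  # shuffle invariance
  cv2 <- structure(list(records = rec[sample(100), ]), class = "swe_cv")
  expect_equal(summary(cv2), s, ignore_attr = TRUE)
  expect_true(all(s$ci_low <= s$ci_high))
})

make_separable_features <- function(n = 60, p = 8, seed = 33, delta = 2) {
  set.seed(seed)
  label <- rep(c("pain", "control"), length.out = n)
  x <- matrix(rnorm(n * p), n, p)
  x[label == "pain", 1:2] <- x[label == "pain", 1:2] + delta
  colnames(x) <- paste0("feat", seq_len(p))
  ft <- data.frame(x, check.names = FALSE)
  ft$label <- label
  ft$participant <- sprintf("id%02d", rep(1:(n / 2), each = 2))
  attr(ft, "feature_cols") <- colnames(x)
  class(ft) <- c("swe_features", "data.frame")
  ft
}

test_that("nested CV yields n_outer x n_repeats records per algorithm, reproducibly", {
  ft <- make_separable_features()
  grids <- list(rf = data.frame(num.trees = 50L),
                knn = data.frame(k = c(3L, 5L)))
  cv1 <- nested_cv(ft, algorithms = c("rf", "knn"), n_outer = 4,
                   n_repeats = 2, inner_folds = 2, seed = 99, grids = grids)
  expect_equal(nrow(cv1$records), 2 * 4 * 2)
  expect_equal(sum(cv1$records$algorithm == "rf"), 8)
  metrics <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
               "auc", "brier")
  expect_true(all(as.matrix(cv1$records[, metrics]) >= 0 &
                    as.matrix(cv1$records[, metrics]) <= 1))
  cv2 <- nested_cv(ft, algorithms = c("rf", "knn"), n_outer = 4,
                   n_repeats = 2, inner_folds = 2, seed = 99, grids = grids)
  expect_identical(cv1$records, cv2$records)
  expect_identical(cv1$selected, cv2$selected)
  # separable data: every algorithm should do clearly better than chance
  expect_gt(mean(cv1$records$auc), 0.8)
})

test_that("all six classifiers run through the nested CV harness", {
  ft <- make_separable_features(n = 80, seed = 34)
  grids <- list(rf = data.frame(num.trees = 30L),
                dt = data.frame(maxdepth = 3L),
                svm = data.frame(kernel = "radial", cost = 1,
                                 stringsAsFactors = FALSE),
                knn = data.frame(k = 5L),
                lr = data.frame(lambda = 0.1),
                nb = data.frame(dummy = NA))
  cv <- nested_cv(ft, algorithms = c("rf", "dt", "svm", "knn", "lr", "nb"),
                  n_outer = 3, n_repeats = 1, seed = 7, grids = grids)
  expect_equal(nrow(cv$records), 6 * 3)
  expect_false(anyNA(cv$records$auc))
  s <- summary(cv)
  expect_equal(nrow(s), 6 * 6)
  tab <- benchmark_table(cv)
  expect_equal(dim(tab), c(6L, 7L))
})

test_that("participant grouping never splits a participant across folds", {
  ft <- make_separable_features(n = 80, seed = 35)
  # 20 pain and 20 control participants, 2 images each
  cv <- nested_cv(ft, algorithms = "rf", n_outer = 4, n_repeats = 1,
                  inner_folds = 2, grouping = "participant", seed = 5,
                  grids = list(rf = data.frame(num.trees = 30L)))
  expect_equal(nrow(cv$records), 4)
  set.seed(5)
  fold <- swequant:::make_folds(ft$label, 4, ft$participant, "participant")
  expect_true(all(tapply(fold, ft$participant,
                         function(f) length(unique(f))) == 1))
  expect_error(
    swequant:::make_folds(ft$label[1:10], 10, ft$participant[1:10],
                          "participant"),
    "participants per class")
})

test_that("label permutation drives AUC to chance level", {
  ft <- make_separable_features(n = 80, seed = 36)
  set.seed(36)
  ft$label <- sample(ft$label)
  cv <- nested_cv(ft, algorithms = "rf", n_outer = 5, n_repeats = 2,
                  seed = 12, grids = list(rf = data.frame(num.trees = 50L)))
  aucs <- cv$records$auc
  mc_se <- sd(aucs) / sqrt(length(aucs))
  expect_lt(abs(mean(aucs) - 0.5), 3 * mc_se + 0.02)
})

test_that("Gini importances are normalized and identify a perfect predictor", {
  ft <- make_separable_features(n = 60, seed = 37, delta = 0)
  ft$oracle_feature <- as.numeric(ft$label == "pain")
  attr(ft, "feature_cols") <- c(attr(ft, "feature_cols"), "oracle_feature")
  fit <- fit_rf_importance(ft, num.trees = 100, seed = 3)
  imp <- rank_importances(fit, feature_names = feature_cols(ft), top_k = Inf)
  expect_equal(sum(imp$importance), 1)
  expect_true(all(imp$importance >= 0))
  expect_equal(imp$feature[1], "oracle_feature")
  expect_equal(attr(imp, "total_features"), 9)
  top2 <- rank_importances(fit, feature_names = feature_cols(ft), top_k = 2)
  expect_equal(nrow(top2), 2)
})
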