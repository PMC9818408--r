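#' Classification performance metrics for one validation fold
#'
#' Computes the six benchmark metrics for a binary pain-vs-control fold:
#' accuracy, sensitivity (true-positive rate on the pain class), specificity
#' (true-negative rate), balanced accuracy (arithmetic mean of sensitivity
#' and specificity), AUC and Brier score. AUC is the probability that a
#' randomly chosen positive image receives a higher score than a randomly
#' chosen negative one, with ties counted 1/2 (the rank / Mann-Whitney
#' formulation). Brier is the mean squared difference between the predicted
#' positive-class probability and the 0/1 outcome.
#'
#' @param truth true class labels (two classes present).
#' @param pred predicted class labels.
#' @param scores predicted positive-class probabilities in \[0, 1\].
#' @param positive label of the positive class (default `"pain"`).
#' @return named numeric vector: `accuracy`, `balanced_accuracy`,
#'   `sensitivity`, `specificity`, `auc`, `brier`.
#' @examples
#' compute_metrics(c("pain", "pain", "control"), c("pain", "control", "control"),
#'                 c(0.9, 0.4, 0.2))
#' @export
compute_metrics <- function(truth, pred, scores, positive = "pain") {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(unique(truth)) < 2L) {
    stop("single-class test set: metrics undefined for this fold")
  }
  stopifnot(length(truth) == length(pred), length(truth) == length(scores))
  pos <- truth == positive
  sens <- mean(pred[pos] == positive)
  spec <- mean(pred[!pos] != positive)
  r <- rank(scores, ties.method = "average")
  n1 <- sum(pos); n0 <- sum(!pos)
  auc <- (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  c(accuracy = mean(pred == truth),
    balanced_accuracy = (sens + spec) / 2,
    sensitivity = sens,
    specificity = spec,
    auc = auc,
    brier = mean((scores - as.numeric(pos))^2))
}

#' Default hyperparameter grids for the six classifiers
#'
#' Small, documented grids per algorithm, tuned by the inner grid search:
#' random forest (`rf`): number of trees; decision tree (`dt`): maximal
#' depth; SVM (`svm`): kernel (RBF and linear) and cost; k-nearest neighbors
#' (`knn`): k; ridge-penalized logistic regression (`lr`): penalty strength;
#' naive Bayes (`nb`): no tunable parameter.
#'
#' @return named list of `data.frame` grids.
#' @export
default_grids <- function() {
  list(
    rf = expand.grid(num.trees = c(100L, 500L)),
    dt = expand.grid(maxdepth = c(3L, 5L, 10L)),
    svm = expand.grid(kernel = c("radial", "linear"), cost = c(0.1, 1, 10),
                      stringsAsFactors = FALSE),
    knn = expand.grid(k = c(3L, 5L, 7L, 11L)),
    lr = expand.grid(lambda = c(0.01, 0.1, 1)),
    nb = data.frame(dummy = NA)
  )
}

# scale-sensitive learners get train-split standardization
scale_train <- function(x) {
  mu <- colMeans(x)
  sd <- apply(x, 2, stats::sd)
  sd[!is.finite(sd) | sd == 0] <- 1
  list(mu = mu, sd = sd)
}

apply_scale <- function(x, sc) {
  sweep(sweep(x, 2, sc$mu, "-"), 2, sc$sd, "/")
}

fit_learner <- function(algorithm, x, y, params, positive) {
  switch(algorithm,
    rf = {
      seed <- sample.int(.Machine$integer.max, 1L)
      list(model = ranger::ranger(x = x, y = y, probability = TRUE,
                                  num.trees = params$num.trees,
                                  num.threads = 1, seed = seed))
    },
    dt = {
      df <- data.frame(x, check.names = TRUE)
      df$.y <- y
      list(model = rpart::rpart(.y ~ ., data = df, method = "class",
                                control = rpart::rpart.control(
                                  maxdepth = params$maxdepth, cp = 0.001)))
    },
    svm = {
      sc <- scale_train(x)
      list(model = e1071::svm(x = apply_scale(x, sc), y = y,
                              kernel = params$kernel, cost = params$cost,
                              probability = TRUE), scale = sc)
    },
    knn = {
      sc <- scale_train(x)
      list(train = apply_scale(x, sc), y = y, k = params$k, scale = sc)
    },
    lr = {
      list(model = glmnet::glmnet(x = as.matrix(x), y = y,
                                  family = "binomial", alpha = 0,
                                  lambda = params$lambda))
    },
    nb = {
      list(model = e1071::naiveBayes(x = data.frame(x, check.names = TRUE),
                                     y = y))
    },
    stop("unknown algorithm: ", algorithm))
}

predict_prob <- function(algorithm, fit, x, positive) {
  switch(algorithm,
    rf = stats::predict(fit$model, data = x,
                        num.threads = 1)$predictions[, positive],
    dt = stats::predict(fit$model,
                        newdata = data.frame(x, check.names = TRUE),
                        type = "prob")[, positive],
    svm = {
      p <- stats::predict(fit$model, apply_scale(x, fit$scale),
                          probability = TRUE)
      attr(p, "probabilities")[, positive]
    },
    knn = {
      pr <- class::knn(fit$train, apply_scale(x, fit$scale), fit$y,
                       k = fit$k, prob = TRUE)
      pwin <- attr(pr, "prob")
      ifelse(as.character(pr) == positive, pwin, 1 - pwin)
    },
    lr = as.numeric(stats::predict(fit$model, newx = as.matrix(x),
                                   type = "response")),
    nb = stats::predict(fit$model,
                        newdata = data.frame(x, check.names = TRUE),
                        type = "raw")[, positive])
}

# stratified fold ids; with grouping, whole participants are assigned to folds
make_folds <- function(labels, k, participant = NULL, grouping = "none") {
  fold <- integer(length(labels))
  if (grouping == "participant") {
    pid <- unique(participant)
    pgrp <- labels[match(pid, participant)]
    for (cl in unique(pgrp)) {
      ids <- pid[pgrp == cl]
      if (length(ids) < k) {
        stop(sprintf("grouping by participant needs >= %d participants per class (got %d)",
                     k, length(ids)))
      }
      pf <- rep_len(seq_len(k), length(ids))[sample.int(length(ids))]
      for (j in seq_along(ids)) fold[participant == ids[j]] <- pf[j]
    }
  } else {
    for (cl in unique(labels)) {
      idx <- which(labels == cl)
      fold[idx] <- rep_len(seq_len(k), length(idx))[sample.int(length(idx))]
    }
  }
  fold
}

#' Repeated nested cross-validation benchmark
#'
#' Benchmarks the configured classifiers with repeated, nested, stratified
#' 10-fold cross-validation: in every repeat a fresh outer partition is
#' drawn; within each outer training split an inner grid search
#' cross-validates every hyperparameter combination and selects the one with
#' the highest mean inner AUC; the model is refit on the full outer training
#' split and evaluated on the held-out fold. With the default 10 repeats this
#' yields 100 validation records per algorithm. Fold assignment is at image
#' level by default (`grouping = "none"`); `grouping = "participant"` keeps
#' all images of a participant in one fold, which avoids identity leakage
#' when images per participant are correlated.
#'
#' @param ft an `swe_features` table (or data.frame with a `label` column and
#'   a `feature_cols` attribute).
#' @param algorithms subset of `c("rf", "dt", "svm", "knn", "lr", "nb")`.
#' @param n_outer outer folds (default 10).
#' @param n_repeats repeats of the whole procedure (default 10).
#' @param inner_folds folds of the inner grid-search CV (default 5).
#' @param grouping `"none"` (image-level folds) or `"participant"`.
#' @param seed integer seed; the complete procedure is reproducible from it.
#' @param grids hyperparameter grids, see [default_grids()].
#' @param positive positive class label.
#' @return object of class `swe_cv`: list with `records` (one row per
#'   algorithm x repeat x fold with the six metrics), `selected` (chosen
#'   hyperparameters per outer fold) and the call configuration.
#' @seealso [summary.swe_cv()], [rank_importances()]
#' @export
nested_cv <- function(ft, algorithms = c("rf", "dt", "svm", "knn", "lr", "nb"),
                      n_outer = 10L, n_repeats = 10L, inner_folds = 5L,
                      grouping = c("none", "participant"), seed = 1L,
                      grids = default_grids(), positive = "pain") {
  grouping <- match.arg(grouping)
  algorithms <- match.arg(algorithms, several.ok = TRUE)
  cols <- feature_cols(ft)
  if (is.null(cols)) cols <- setdiff(names(ft), c("label", "participant"))
  x <- as.matrix(as.data.frame(ft, check.names = FALSE)[, cols])
  colnames(x) <- sprintf("f%04d", seq_along(cols))   # model-safe names
  labels <- as.character(ft$label)
  if (length(unique(labels)) < 2L) stop("need two classes in the label column")
  negative <- setdiff(unique(labels), positive)[1]
  y <- factor(labels, levels = c(negative, positive))
  participant <- if ("participant" %in% names(ft)) {
    as.character(ft$participant)
  }
  set.seed(seed)
  records <- list(); selected <- list()
  for (rep_i in seq_len(n_repeats)) {
    fold <- make_folds(labels, n_outer, participant, grouping)
    for (fold_i in seq_len(n_outer)) {
      test <- fold == fold_i
      xtr <- x[!test, , drop = FALSE]; ytr <- y[!test]
      for (alg in algorithms) {
        grid <- grids[[alg]]
        best <- 1L
        if (nrow(grid) > 1L) {
          ifold <- make_folds(as.character(ytr), inner_folds,
                              participant[!test], grouping)
          score <- numeric(nrow(grid))
          for (gi in seq_len(nrow(grid))) {
            aucs <- rep(NA_real_, inner_folds)
            for (ii in seq_len(inner_folds)) {
              itr <- ifold != ii
              if (length(unique(ytr[!itr])) < 2L) next
              fitted <- fit_learner(alg, xtr[itr, , drop = FALSE], ytr[itr],
                                    grid[gi, , drop = FALSE], positive)
              pr <- predict_prob(alg, fitted, xtr[!itr, , drop = FALSE],
                                 positive)
              m <- compute_metrics(as.character(ytr[!itr]),
                                   ifelse(pr >= 0.5, positive, negative),
                                   pr, positive)
              aucs[ii] <- m[["auc"]]
            }
            score[gi] <- mean(aucs, na.rm = TRUE)
          }
          best <- which.max(score)
        }
        params <- grid[best, , drop = FALSE]
        fitted <- fit_learner(alg, xtr, ytr, params, positive)
        pr <- predict_prob(alg, fitted, x[test, , drop = FALSE], positive)
        rec <- tryCatch(
          compute_metrics(labels[test], ifelse(pr >= 0.5, positive, negative),
                          pr, positive),
          error = function(e) {
            warning(sprintf("repeat %d fold %d (%s): %s", rep_i, fold_i, alg,
                            conditionMessage(e)), call. = FALSE)
            stats::setNames(rep(NA_real_, 6),
                            c("accuracy", "balanced_accuracy", "sensitivity",
                              "specificity", "auc", "brier"))
          })
        records[[length(records) + 1L]] <- data.frame(
          algorithm = alg, rep = rep_i, fold = fold_i, t(rec),
          check.names = FALSE)
        selected[[length(selected) + 1L]] <- data.frame(
          algorithm = alg, rep = rep_i, fold = fold_i,
          params = paste(names(params), unlist(params), sep = "=",
                         collapse = ", "),
          stringsAsFactors = FALSE)
      }
    }
  }
  structure(
    list(records = do.call(rbind, records),
         selected = do.call(rbind, selected),
         algorithms = algorithms, n_outer = n_outer, n_repeats = n_repeats,
         inner_folds = inner_folds, grouping = grouping, seed = seed,
         positive = positive),
    class = "swe_cv")
}

#' @export
#' @method print swe_cv
print.swe_cv <- function(x, ...) {
  cat(sprintf("Nested %d-fold cross-validation, %d repeat(s), grouping = %s\n",
              x$n_outer, x$n_repeats, x$grouping))
  cat(sprintf("  algorithms: %s; %d validation records\n",
              paste(x$algorithms, collapse = ", "), nrow(x$records)))
  s <- summary(x)
  auc <- s[s$metric == "auc", ]
  for (i in seq_len(nrow(auc))) {
    cat(sprintf("  %-4s mean AUC %.3f (%.3f-%.3f)\n", auc$algorithm[i],
                auc$mean[i], auc$ci_low[i], auc$ci_high[i]))
  }
  invisible(x)
}

#' Summarize cross-validation records
#'
#' Per algorithm and metric: arithmetic mean and the 2.5% / 97.5% empirical
#' quantiles of the per-fold values (order statistics with linear
#' interpolation, `stats::quantile()` type 7).
#'
#' @param object an `swe_cv` object.
#' @param ... unused.
#' @return data.frame with columns `algorithm`, `metric`, `mean`, `ci_low`,
#'   `ci_high`.
#' @export
#' @method summary swe_cv
summary.swe_cv <- function(object, ...) {
  metrics <- c("accuracy", "balanced_accuracy", "sensitivity", "specificity",
               "auc", "brier")
  out <- list()
  for (alg in unique(object$records$algorithm)) {
    sub <- object$records[object$records$algorithm == alg, ]
    for (m in metrics) {
      v <- sub[[m]]
      v <- v[!is.na(v)]
      q <- stats::quantile(v, c(0.025, 0.975), type = 7, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(
        algorithm = alg, metric = m, mean = mean(v),
        ci_low = q[1], ci_high = q[2], stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

#' @export
plot.swe_cv <- function(x, metric = "auc", ...) {
  graphics::boxplot(stats::as.formula(paste(metric, "~ algorithm")),
                    data = x$records, ylab = metric,
                    main = sprintf("Nested CV (%d records/algorithm)",
                                   x$n_outer * x$n_repeats), ...)
  invisible(x)
}

#' Fit a random forest on the full feature table for importance analysis
#'
#' Fits one probability forest on all rows (the model used for biomarker
#' screening, not for performance estimation) with Gini (impurity)
#' importance.
#'
#' @param ft an `swe_features` table.
#' @param num.trees forest size.
#' @param seed integer seed.
#' @param positive positive class label.
#' @return a `ranger` fit with impurity importances.
#' @export
fit_rf_importance <- function(ft, num.trees = 500L, seed = 1L,
                              positive = "pain") {
  cols <- feature_cols(ft)
  x <- as.matrix(as.data.frame(ft, check.names = FALSE)[, cols])
  labels <- as.character(ft$label)
  negative <- setdiff(unique(labels), positive)[1]
  set.seed(seed)
  ranger::ranger(x = x, y = factor(labels, levels = c(negative, positive)),
                 importance = "impurity", num.trees = num.trees,
                 num.threads = 1, seed = sample.int(.Machine$integer.max, 1L))
}

#' Rank features by Gini importance
#'
#' Orders features by decreasing mean decrease in Gini impurity from a
#' trained random forest; importances are normalized to sum to 1 over all
#' features. Ties are broken by feature-name order.
#'
#' @param fit a `ranger` forest trained with `importance = "impurity"` (for
#'   example from [fit_rf_importance()]).
#' @param feature_names optional clean names overriding the fit's variable
#'   names (same order).
#' @param top_k number of top features to return (`Inf` for all).
#' @return data.frame of class `swe_importance` with columns `feature`,
#'   `importance`, ranked descending; attribute `total_features`.
#' @export
rank_importances <- function(fit, feature_names = NULL, top_k = 20L) {
  imp <- tryCatch(ranger::importance(fit), error = function(e) NULL)
  if (is.null(imp) || length(imp) == 0L) {
    stop("model carries no importances; train with importance = 'impurity'")
  }
  nm <- if (is.null(feature_names)) names(imp) else feature_names
  stopifnot(length(nm) == length(imp))
  imp <- pmax(as.numeric(imp), 0)
  imp <- imp / sum(imp)
  ord <- order(-imp, nm)
  out <- data.frame(feature = nm[ord], importance = imp[ord],
                    stringsAsFactors = FALSE)
  total <- nrow(out)
  out <- utils::head(out, top_k)
  attr(out, "total_features") <- total
  class(out) <- c("swe_importance", "data.frame")
  out
}

#' @export
#' @method print swe_importance
print.swe_importance <- function(x, ...) {
  cat(sprintf("Top %d of %d features by Gini importance:\n", nrow(x),
              attr(x, "total_features")))
  print.data.frame(data.frame(feature = x$feature,
                              importance = signif(x$importance, 3)),
                   row.names = FALSE)
  invisible(x)
}
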