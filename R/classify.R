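#' Cross-validated decision-tree classification of cohorts
#'
#' Stratified k-fold cross-validation of a pruned CART decision tree
#' (rpart, cost-complexity pruning at the minimum cross-validated error) on
#' the distance-vector features. Reports the pooled out-of-fold confusion
#' matrix, the ROC area of the out-of-fold class probabilities, and per-fold
#' accuracies. Deterministic given `seed`.
#'
#' @param vectors an `nps_distances` (or `nps_deltas`) tibble; feature
#'   columns are everything except `sample_id`/`cohort`.
#' @param labels class label per subject; defaults to the `cohort` column.
#' @param folds number of stratified folds (default 10).
#' @param seed integer seed controlling fold assignment and tree fitting.
#' @return A list of class `nps_classification`: `confusion` (2x2 matrix,
#'   rows = truth), `accuracy`, `roc_auc`, `fold_accuracy` (length `folds`),
#'   `folds`, `seed`.
#' @export
classify_cohort <- function(vectors, labels = vectors$cohort, folds = 10,
                            seed = 1L) {
  y <- factor(labels)
  if (nlevels(y) < 2L) stop("classification needs both classes present")
  if (min(table(y)) < folds) stop("folds exceed the smallest class size")
  feats <- dplyr::select(tibble::as_tibble(vectors),
                         -dplyr::any_of(c("sample_id", "cohort")))
  dat <- data.frame(.y = y, feats, check.names = TRUE)

  withr::with_seed(as.integer(seed), {
    fold_id <- integer(length(y))
    for (lev in levels(y)) {
      idx <- which(y == lev)
      fold_id[idx] <- sample(rep_len(seq_len(folds), length(idx)))
    }
    prob <- numeric(length(y))
    pred <- factor(rep(levels(y)[1], length(y)), levels = levels(y))
    fold_acc <- numeric(folds)
    for (f in seq_len(folds)) {
      test <- fold_id == f
      fit <- rpart::rpart(.y ~ ., data = dat[!test, , drop = FALSE],
                          method = "class",
                          control = rpart::rpart.control(xval = 10, cp = 0.001))
      cptab <- fit$cptable
      best_cp <- cptab[which.min(cptab[, "xerror"]), "CP"]
      fit <- rpart::prune(fit, cp = best_cp)
      p <- predict(fit, dat[test, , drop = FALSE], type = "prob")
      prob[test] <- p[, levels(y)[2]]
      pred[test] <- factor(colnames(p)[max.col(p, ties.method = "first")],
                           levels = levels(y))
      fold_acc[f] <- mean(pred[test] == y[test])
    }
    auc <- if (length(unique(prob)) > 1L) {
      as.numeric(pROC::auc(pROC::roc(y, prob, quiet = TRUE,
                                     levels = levels(y), direction = "<")))
    } else {
      0.5
    }
    structure(list(
      confusion = table(truth = y, predicted = pred),
      accuracy = mean(pred == y),
      roc_auc = auc,
      fold_accuracy = fold_acc,
      folds = folds,
      seed = as.integer(seed)
    ), class = "nps_classification")
  })
}

#' @export
print.nps_classification <- function(x, ...) {
  cat("<nps_classification> ", x$folds, "-fold CV, accuracy ",
      round(x$accuracy, 3), ", ROC AUC ", round(x$roc_auc, 3), "\n", sep = "")
  print(x$confusion)
  invisible(x)
}

#' @export
glance.nps_classification <- function(x, ...) {
  tibble::tibble(
    accuracy = x$accuracy,
    roc_auc = x$roc_auc,
    folds = x$folds,
    sd_fold_accuracy = stats::sd(x$fold_accuracy)
  )
}
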