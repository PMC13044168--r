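#' Area under the ROC curve
#'
#' Mann-Whitney formulation: the probability that a randomly chosen positive
#' scores higher than a randomly chosen negative, with ties counting one
#' half. Invariant to any strictly monotone transform of the scores.
#'
#' @param scores numeric predicted scores or probabilities.
#' @param labels logical or 0/1 vector; `TRUE`/1 = positive class.
#' @return AUC in [0, 1].
#' @export
auc_score <- function(scores, labels) {
  labels <- as.logical(labels)
  np <- sum(labels); nn <- sum(!labels)
  if (np == 0L || nn == 0L) stopf("both classes must be non-empty")
  r <- rank(scores)
  (sum(r[labels]) - np * (np + 1) / 2) / (np * nn)
}

roc_points <- function(scores, labels) {
  labels <- as.logical(labels)
  ord <- order(-scores)
  tpr <- c(0, cumsum(labels[ord]) / sum(labels))
  fpr <- c(0, cumsum(!labels[ord]) / sum(!labels))
  data.frame(fpr = fpr, tpr = tpr)
}

# stratified fold assignment: each class split as evenly as possible
stratified_folds <- function(labels, folds) {
  assign <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- sample(which(labels == cl))
    assign[idx] <- rep_len(seq_len(folds), length(idx))
  }
  assign
}

#' Random-forest discrimination of STS extremes
#'
#' Trains a random forest to separate the tolerant and sensitive extreme
#' groups from retention-trait features and evaluates it with stratified
#' cross-validated held-out probabilities (ROC and AUC). Because the labels
#' are themselves derived by thresholding the STS — a function of the same
#' feature matrix — a (near-)perfect AUC is the expected outcome and reads
#' as "the extremes are cleanly separated in multi-trait space", not as
#' generalisation to new data. The in-sample (out-of-bag) AUC is reported
#' alongside for reference.
#'
#' @param fit an `sts` fit, or a numeric feature matrix with accession
#'   rownames.
#' @param extremes list with `tolerant` and `sensitive` accession vectors,
#'   as returned by [select_extremes()].
#' @param trees number of trees.
#' @param folds stratified CV folds; reduced with a warning when a class is
#'   smaller than the fold count.
#' @param seed integer seed covering fold assignment and forest growth.
#' @return Object of class `sts_classifier`: `auc` (held-out), `auc_oob`,
#'   `roc` (data frame of fpr/tpr), `prob` (held-out probability of the
#'   tolerant class per labeled accession), `labels`, `gini_importance`
#'   (normalized, sums to 1), per-fold fitted forests, and settings.
#' @export
classify_extremes <- function(fit, extremes, trees = 500, folds = 5,
                              seed = NULL) {
  features <- if (inherits(fit, "sts")) fit$z else as.matrix(fit)
  if (anyNA(features)) features <- impute_col_median(features)
  if (!is.list(extremes) ||
      !all(c("tolerant", "sensitive") %in% names(extremes)))
    stopf("extremes must be a list with tolerant and sensitive accessions")
  acc <- c(extremes$tolerant, extremes$sensitive)
  missing_acc <- setdiff(acc, rownames(features))
  if (length(missing_acc) > 0L)
    stopf("labeled accession(s) absent from features: %s",
          paste(missing_acc, collapse = ", "))
  if (length(extremes$tolerant) == 0L || length(extremes$sensitive) == 0L)
    stopf("both classes must be non-empty")
  x <- features[acc, , drop = FALSE]
  y <- factor(rep(c("tolerant", "sensitive"),
                  c(length(extremes$tolerant), length(extremes$sensitive))),
              levels = c("sensitive", "tolerant"))
  min_class <- min(table(y))
  if (folds > min_class) {
    warnf("reducing folds from %d to %d (smallest class size)",
          folds, min_class)
    folds <- min_class
  }

  with_seed(seed, {
    fold_of <- stratified_folds(y, folds)
    prob <- numeric(length(y))
    fold_fits <- vector("list", folds)
    for (f in seq_len(folds)) {
      test <- fold_of == f
      rf <- randomForest::randomForest(x[!test, , drop = FALSE], y[!test],
                                       ntree = trees)
      fold_fits[[f]] <- list(fit = rf, test = which(test))
      prob[test] <- stats::predict(rf, x[test, , drop = FALSE],
                                   type = "prob")[, "tolerant"]
    }
    full <- randomForest::randomForest(x, y, ntree = trees, importance = TRUE)
  })
  names(prob) <- acc
  pos <- y == "tolerant"
  gini <- full$importance[, "MeanDecreaseGini"]
  gini <- if (sum(gini) > 0) gini / sum(gini) else gini

  structure(list(auc = auc_score(prob, pos),
                 auc_oob = auc_score(full$votes[, "tolerant"], pos),
                 roc = roc_points(prob, pos),
                 prob = prob, labels = y, features = x,
                 gini_importance = gini,
                 fold_fits = fold_fits, forest = full,
                 settings = list(trees = trees, folds = folds, seed = seed)),
            class = "sts_classifier")
}

#' @export
print.sts_classifier <- function(x, ...) {
  cat("Random-forest discrimination of STS extremes\n")
  cat(sprintf("  held-out AUC %.3f (OOB %.3f), %d trees, %d folds\n",
              x$auc, x$auc_oob, x$settings$trees, x$settings$folds))
  top <- sort(x$gini_importance, decreasing = TRUE)
  cat("  top traits by Gini importance:",
      paste(sprintf("%s %.3f", names(top)[1:min(3, length(top))],
                    top[1:min(3, length(top))]), collapse = ", "), "\n")
  invisible(x)
}

#' Gini importance of retention traits
#'
#' Normalized mean decrease in node impurity per feature from the
#' full-data forest; the scores sum to 1.
#'
#' @param result an `sts_classifier`.
#' @return Named numeric vector, descending.
#' @export
gini_importance <- function(result) {
  if (!inherits(result, "sts_classifier"))
    stopf("result must come from classify_extremes()")
  sort(result$gini_importance, decreasing = TRUE)
}

#' Permutation importance on held-out AUC
#'
#' Shuffles one feature column at a time in the held-out samples, re-scores
#' them with the cross-validation fold forests, and reports the mean drop in
#' held-out AUC over repeats. With a panel of highly correlated traits the
#' forest can route around any single shuffled feature, so most drops sit
#' near zero — the redundancy signature of a multi-trait composite.
#'
#' @param result an `sts_classifier`.
#' @param repeats shuffles per feature.
#' @param seed integer seed.
#' @return Named numeric vector of mean AUC drops, descending.
#' @export
permutation_importance <- function(result, repeats = 10, seed = NULL) {
  if (!inherits(result, "sts_classifier"))
    stopf("result must come from classify_extremes()")
  if (!is_count(repeats)) stopf("repeats must be a positive integer")
  x <- result$features
  pos <- result$labels == "tolerant"
  base <- result$auc
  n <- nrow(x)

  heldout_prob <- function(xp) {
    prob <- numeric(n)
    for (ff in result$fold_fits) {
      prob[ff$test] <- stats::predict(ff$fit, xp[ff$test, , drop = FALSE],
                                      type = "prob")[, "tolerant"]
    }
    prob
  }
  drops <- with_seed(seed, {
    vapply(seq_len(ncol(x)), function(j) {
      mean(vapply(seq_len(repeats), function(r) {
        xp <- x
        xp[, j] <- xp[sample.int(n), j]
        base - auc_score(heldout_prob(xp), pos)
      }, numeric(1)))
    }, numeric(1))
  })
  sort(stats::setNames(drops, colnames(x)), decreasing = TRUE)
}
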