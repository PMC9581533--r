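## Evaluation protocol: repeated random splits, confusion metrics,
## ROC curves, k-fold cross-validation, distribution comparison.

#' One-vs-rest rates from a confusion matrix
#'
#' Sensitivity `TP/(TP+FN)`, specificity `TN/(TN+FP)`, positive and
#' negative predictive values per class, each computed one-vs-rest.
#' Zero denominators yield `NA` (undefined), never 0.
#'
#' @param confusion Square non-negative matrix, rows = true classes,
#'   columns = predicted classes (same order).
#' @return Data.frame with one row per class: `class`, `sensitivity`,
#'   `specificity`, `ppv`, `npv`.
#' @examples
#' cm <- matrix(c(8, 0, 1, 90), 2, byrow = TRUE,
#'              dimnames = list(c(1, 0), c(1, 0)))
#' confusion_metrics(cm)  # sensitivity 1.0, PPV 8/9 for class "1"
#' @export
confusion_metrics <- function(confusion) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion) || any(confusion < 0))
    stop("confusion must be a square non-negative matrix")
  cls <- rownames(confusion)
  if (is.null(cls)) cls <- as.character(seq_len(nrow(confusion)))
  tot <- sum(confusion)
  rate <- function(num, den) if (den > 0) num / den else NA_real_
  out <- lapply(seq_len(nrow(confusion)), function(k) {
    tp <- confusion[k, k]
    fn <- sum(confusion[k, ]) - tp
    fp <- sum(confusion[, k]) - tp
    tn <- tot - tp - fn - fp
    data.frame(class = cls[k],
               sensitivity = rate(tp, tp + fn),
               specificity = rate(tn, tn + fp),
               ppv = rate(tp, tp + fp),
               npv = rate(tn, tn + fn))
  })
  do.call(rbind, out)
}

confusion_table <- function(truth, pred, classes) {
  tab <- table(factor(truth, levels = classes),
               factor(pred, levels = classes))
  m <- as.matrix(unclass(tab))
  dimnames(m) <- list(as.character(classes), as.character(classes))
  m
}

#' Repeated random 50/50 split evaluation
#'
#' The study's main protocol: for each repeat, a uniform random half of
#' the cells trains the tree and the other half is tested; one-vs-rest
#' sensitivity and specificity are taken per class from the test
#' confusion matrix, and the mean and standard deviation over repeats
#' are reported. Repeats whose training half lacks a class are re-drawn
#' (and counted).
#'
#' @param X Feature matrix.
#' @param y Integer class labels.
#' @param hp Tree hyperparameters ([tree_hyperparams()]).
#' @param n_repeats Number of random splits (the study used 10,000;
#'   1,000 gives means stable to the third decimal).
#' @param seed Integer seed; the split sequence is the only source of
#'   randomness.
#' @return An object of class `eval_report`: per-class
#'   `sensitivity_mean/sd`, `specificity_mean/sd` (data.frame `metrics`),
#'   `confusion` (pooled over repeats), `n_repeats`, `n_redraws`.
#' @examples
#' feats <- cells_to_features(simulate_reference_cells(seed = 1))
#' rep <- repeated_split_eval(feats$X, feats$y, n_repeats = 50, seed = 2)
#' rep$metrics
#' @export
repeated_split_eval <- function(X, y, hp = tree_hyperparams(),
                                n_repeats = 1000L, seed = NULL) {
  stopifnot(n_repeats >= 1)
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  classes <- sort(unique(y))
  K <- length(classes)
  n_train <- floor(n / 2)
  with_local_seed(seed, {
    sens <- matrix(NA_real_, n_repeats, K)
    spec <- matrix(NA_real_, n_repeats, K)
    pooled <- matrix(0, K, K,
                     dimnames = list(as.character(classes),
                                     as.character(classes)))
    n_redraws <- 0L
    for (r in seq_len(n_repeats)) {
      repeat {
        idx <- sample.int(n, n_train)
        if (length(unique(y[idx])) == K &&
            length(unique(y[-idx])) >= 2) break
        n_redraws <- n_redraws + 1L
      }
      tree <- fit_tree(X[idx, , drop = FALSE], y[idx], hp)
      pred <- predict(tree, X[-idx, , drop = FALSE])
      cm <- confusion_table(y[-idx], pred, classes)
      pooled <- pooled + cm
      m <- confusion_metrics(cm)
      sens[r, ] <- m$sensitivity
      spec[r, ] <- m$specificity
    }
    metrics <- data.frame(
      class = classes,
      sensitivity_mean = colMeans(sens, na.rm = TRUE),
      sensitivity_sd = apply(sens, 2, sd, na.rm = TRUE),
      specificity_mean = colMeans(spec, na.rm = TRUE),
      specificity_sd = apply(spec, 2, sd, na.rm = TRUE))
    out <- list(metrics = metrics, confusion = pooled,
                n_repeats = as.integer(n_repeats),
                n_redraws = n_redraws, classes = classes)
    class(out) <- "eval_report"
    out
  })
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("Repeated 50/50 split evaluation (%d repeats, %d re-draws):\n",
              x$n_repeats, x$n_redraws))
  m <- x$metrics
  for (i in seq_len(nrow(m)))
    cat(sprintf("  class %s: sensitivity %.3f +- %.3f, specificity %.3f +- %.3f\n",
                m$class[i], m$sensitivity_mean[i], m$sensitivity_sd[i],
                m$specificity_mean[i], m$specificity_sd[i]))
  invisible(x)
}

#' ROC curve by threshold sweep
#'
#' Sweeps all distinct score values as thresholds (score >= threshold is
#' called positive) and reports the false/true positive rates plus the
#' trapezoidal area under the curve.
#'
#' @param scores Numeric scores for the positive class (e.g. a column of
#'   [predict_scores()]).
#' @param labels Class labels.
#' @param positive_class The label counted as positive.
#' @return A list with `fpr`, `tpr`, `thresholds` (descending, with a
#'   leading `Inf`) and `auc`.
#' @examples
#' roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 1)$auc  # 0.75
#' @export
roc_curve <- function(scores, labels, positive_class) {
  pos <- labels == positive_class
  if (!any(pos) || all(pos))
    stop("need at least one positive and one negative label")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) mean(scores[pos] >= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(scores[!pos] >= t), numeric(1))
  auc <- sum(diff(fpr) * (head(tpr, -1) + tail(tpr, -1)) / 2)
  list(fpr = fpr, tpr = tpr, thresholds = thr, auc = auc)
}

#' Shuffled k-fold cross-validation
#'
#' Samples are shuffled once and dealt into `k` folds; each fold is held
#' out in turn and the accuracy on it recorded.
#'
#' @inheritParams repeated_split_eval
#' @param k Number of folds (default 5).
#' @return A list with `scores` (per-fold accuracy), `mean`, `folds`.
#' @examples
#' feats <- cells_to_features(simulate_reference_cells(seed = 1))
#' kfold_cv(feats$X, feats$y, seed = 2)$mean
#' @export
kfold_cv <- function(X, y, hp = tree_hyperparams(), k = 5L, seed = NULL) {
  X <- as.matrix(X)
  y <- as.integer(y)
  n <- length(y)
  stopifnot(k >= 2, n >= k)
  with_local_seed(seed, {
    fold <- rep_len(seq_len(k), n)[sample.int(n)]
    scores <- vapply(seq_len(k), function(f) {
      test <- fold == f
      tree <- fit_tree(X[!test, , drop = FALSE], y[!test], hp)
      mean(predict(tree, X[test, , drop = FALSE]) == y[test])
    }, numeric(1))
    list(scores = scores, mean = mean(scores), folds = fold)
  })
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Wraps [stats::ks.test()] (two-sample, asymptotic p-value) with a
#' rejection flag at the chosen significance level.
#'
#' @param sample_a,sample_b Numeric samples (each at least 2 values).
#' @param alpha Significance level (default 0.05).
#' @return A list with `D`, `p`, `reject`.
#' @export
ks_compare <- function(sample_a, sample_b, alpha = 0.05) {
  if (length(sample_a) < 2 || length(sample_b) < 2)
    stop("both samples need at least 2 values")
  res <- suppressWarnings(ks.test(sample_a, sample_b, exact = FALSE))
  list(D = unname(res$statistic), p = res$p.value,
       reject = res$p.value < alpha)
}
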