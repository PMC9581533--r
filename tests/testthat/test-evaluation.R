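test_that("confusion metrics implement the one-vs-rest definitions", {
  # diagonal matrix: perfect rates
  d <- diag(c(5, 8, 11))
  m <- confusion_metrics(d)
  expect_equal(m$sensitivity, rep(1, 3))
  expect_equal(m$specificity, rep(1, 3))

  # published staining concordances: 8 of 9 flagged M1 stained positive,
  # all stained cells flagged -> PPV 8/9, sensitivity 1
  cm <- matrix(c(8, 0, 1, 20), 2, 2, byrow = TRUE,
               dimnames = list(c("pos", "neg"), c("pos", "neg")))
  m1 <- confusion_metrics(cm)
  expect_equal(m1$sensitivity[1], 1)
  expect_equal(m1$ppv[1], 8 / 9)
  # 12 of 14 flagged M2, no stained cell missed -> PPV 12/14
  cm2 <- matrix(c(12, 0, 2, 20), 2, 2, byrow = TRUE)
  expect_equal(confusion_metrics(cm2)$ppv[1], 12 / 14)

  # zero denominator: undefined, not zero
  empty <- matrix(c(0, 0, 3, 7), 2, 2, byrow = TRUE)
  expect_true(is.na(confusion_metrics(empty)$sensitivity[1]))
  expect_error(confusion_metrics(matrix(1:6, 2, 3)), "square")
})

test_that("metrics from the confusion matrix equal their direct definitions", {
  d <- blob_data(n = 90, K = 3, p = 4, sep = 2.2, sd = 1.5, seed = 4)
  set.seed(10)
  idx <- sample(90, 45)
  tr <- fit_tree(d$X[idx, ], d$y[idx])
  pred <- predict(tr, d$X[-idx, ]); truth <- d$y[-idx]
  cm <- macroflim:::confusion_table(truth, pred, sort(unique(d$y)))
  m <- confusion_metrics(cm)
  for (k in 0:2) {
    expect_equal(m$sensitivity[k + 1], mean(pred[truth == k] == k))
    expect_equal(m$specificity[k + 1], mean(pred[truth != k] != k))
  }
})

test_that("repeated split evaluation is seeded and separates separable data", {
  d <- blob_data(n = 80, K = 2, p = 3, sep = 12, sd = 0.5, seed = 6)
  r1 <- repeated_split_eval(d$X, d$y, n_repeats = 20, seed = 3)
  r2 <- repeated_split_eval(d$X, d$y, n_repeats = 20, seed = 3)
  expect_identical(r1$metrics, r2$metrics)
  expect_equal(r1$metrics$sensitivity_mean, c(1, 1))
  expect_equal(r1$metrics$specificity_mean, c(1, 1))
  expect_equal(r1$metrics$sensitivity_sd, c(0, 0))
  expect_equal(sum(r1$confusion), 20 * 40)

  # single repeat, deterministic
  s1 <- repeated_split_eval(d$X, d$y, n_repeats = 1, seed = 9)
  s2 <- repeated_split_eval(d$X, d$y, n_repeats = 1, seed = 9)
  expect_identical(s1$confusion, s2$confusion)
})

test_that("metric SDs shrink with more repeats", {
  cells <- simulate_reference_cells(seed = 2)
  f <- cells_to_features(cells)
  r_small <- repeated_split_eval(f$X, f$y, n_repeats = 30, seed = 1)
  # SE of the reported mean ~ sd/sqrt(n_repeats): the 30-repeat mean must
  # agree with a longer run within a few joint standard errors
  r_big <- repeated_split_eval(f$X, f$y, n_repeats = 300, seed = 2)
  se <- r_small$metrics$sensitivity_sd / sqrt(30)
  expect_true(all(abs(r_small$metrics$sensitivity_mean -
                        r_big$metrics$sensitivity_mean) < 6 * se + 0.02))
})

test_that("ROC curve matches hand enumeration and the pROC oracle", {
  r <- roc_curve(c(0.9, 0.8, 0.3, 0.2), c(1, 0, 1, 0), 1)
  expect_equal(r$auc, 0.75)
  expect_equal(max(r$tpr), 1)
  expect_equal(max(r$fpr), 1)

  # perfect scores
  expect_equal(roc_curve(c(1, 1, 0, 0), c(1, 1, 0, 0), 1)$auc, 1)
  # label-independent scores: AUC near 0.5
  set.seed(2)
  sc <- runif(4000); lb <- rep(0:1, 2000)
  expect_lt(abs(roc_curve(sc, lb, 1)$auc - 0.5), 0.03)
  expect_error(roc_curve(c(0.1, 0.2), c(1, 1), 1), "positive and one negative")

  skip_if_not_installed("pROC")
  set.seed(3)
  scores <- c(rnorm(50, 1), rnorm(50))
  labels <- rep(c(1, 0), each = 50)
  ours <- roc_curve(scores, labels, 1)$auc
  ref <- suppressMessages(pROC::auc(pROC::roc(labels, scores,
                                              direction = "<")))
  expect_equal(ours, as.numeric(ref), tolerance = 1e-12)
})

test_that("AUC equals the Mann-Whitney pair probability on small instances", {
  set.seed(7)
  for (i in 1:5) {
    scores <- round(runif(12), 2)
    labels <- sample(0:1, 12, replace = TRUE)
    if (length(unique(labels)) < 2) next
    pos <- scores[labels == 1]; neg <- scores[labels == 0]
    pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
    expect_equal(roc_curve(scores, labels, 1)$auc, mean(pairs),
                 tolerance = 1e-12)
  }
})

test_that("k-fold cross-validation is seeded and partitions correctly", {
  d <- blob_data(n = 70, K = 2, p = 3, sep = 12, sd = 0.5, seed = 5)
  cv <- kfold_cv(d$X, d$y, k = 5, seed = 11)
  expect_length(cv$scores, 5)
  expect_equal(cv$scores, rep(1, 5))          # separable data
  expect_equal(cv$mean, 1)
  expect_equal(as.vector(table(cv$folds)), c(14, 14, 14, 14, 14))
  expect_identical(kfold_cv(d$X, d$y, k = 5, seed = 11)$scores, cv$scores)
  expect_error(kfold_cv(d$X[1:3, ], d$y[1:3], k = 5), "n >= k")
})

test_that("KS comparison separates classes and holds its size", {
  tab <- load_reference_table()
  expect_error(ks_compare(1, 1:5), "at least 2")
  x <- rnorm(30)
  same <- ks_compare(x, x)
  expect_equal(same$D, 0)
  expect_false(same$reject)

  # power: in vivo M1 vs M2 tau1 at the study's sample sizes
  rej <- vapply(1:40, function(i) {
    a <- sample_cells(tab[7, ], 35, seed = i)$tau1
    b <- sample_cells(tab[9, ], 25, seed = 1000 + i)$tau1
    ks_compare(a, b)$reject
  }, logical(1))
  expect_gte(mean(rej), 0.95)

  # type-I error near alpha for same-generator samples
  rej0 <- vapply(1:400, function(i) {
    a <- sample_cells(tab[7, ], 30, seed = 2 * i)$tau1
    b <- sample_cells(tab[7, ], 30, seed = 2 * i + 1)$tau1
    ks_compare(a, b)$reject
  }, logical(1))
  expect_lt(mean(rej0), 0.10)  # asymptotic test is conservative at n = 30
})
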