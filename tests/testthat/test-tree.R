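test_that("entropy impurity follows the definition", {
  expect_equal(entropy_impurity(1), 0)
  expect_equal(entropy_impurity(c(0.5, 0.5)), 1)
  expect_equal(entropy_impurity(c(0.25, 0.75)), 0.811278, tolerance = 1e-6)
  expect_equal(entropy_impurity(c(0, 1)), 0)  # 0*log0 = 0
  expect_error(entropy_impurity(c(-0.1, 1.1)), "non-negative")
})

test_that("best split minimises weighted child entropy", {
  sp <- best_split(matrix(c(1, 2, 9, 10)), c(0L, 0L, 1L, 1L))
  expect_equal(sp$feature, 1)
  expect_equal(sp$threshold, 5.5)
  expect_equal(sp$G, 0)
  # pure node and constant feature yield no split
  expect_null(best_split(matrix(1:4), rep(0L, 4)))
  expect_null(best_split(matrix(rep(2, 4)), c(0L, 1L, 0L, 1L)))
})

test_that("best split equals brute-force enumeration on random data", {
  set.seed(5)
  for (i in 1:25) {
    n <- sample(5:40, 1); p <- sample(1:4, 1)
    X <- matrix(round(rnorm(n * p), 1), n, p)
    y <- sample(0:2, n, replace = TRUE)
    if (length(unique(y)) < 2) next
    sp <- best_split(X, y)
    bf <- brute_force_split(X, y)
    if (is.null(bf)) { expect_null(sp); next }
    expect_equal(sp$G, bf$G, tolerance = 1e-12)
    expect_equal(sp$feature, bf$feature)
    expect_equal(sp$threshold, bf$threshold)
  }
})

test_that("tree training handles base cases and XOR", {
  # single-class data: root leaf
  tr <- fit_tree(matrix(rnorm(10), 5, 2), rep(1L, 5))
  expect_true(tr$root$leaf)
  expect_equal(predict(tr, matrix(rnorm(4), 2, 2)), c(1L, 1L))
  expect_error(fit_tree(matrix(1), 1L), "at least 2")

  # 2-D XOR needs depth >= 2; solved under the default depth cap
  X <- matrix(c(0, 0, 1, 1, 0, 1, 0, 1), 4, 2)
  y <- c(0L, 1L, 1L, 0L)
  xor_tree <- fit_tree(X, y)
  expect_equal(predict(xor_tree, X), y)
  # a depth-1 stump cannot fit XOR
  stump <- fit_tree(X, y, tree_hyperparams(max_depth = 1))
  expect_gt(sum(predict(stump, X) != y), 0)
})

test_that("tree is deterministic and respects its stopping rules", {
  d <- blob_data(n = 150, K = 3, p = 5, sep = 4, seed = 3)
  t1 <- fit_tree(d$X, d$y); t2 <- fit_tree(d$X, d$y)
  expect_identical(t1, t2)
  depths <- local({
    mx <- 0
    walk <- function(nd) {
      mx <<- max(mx, nd$depth)
      if (!nd$leaf) { walk(nd$left); walk(nd$right) }
    }
    walk(t1$root); mx
  })
  expect_lte(depths, 9)
  # scores are leaf proportions and sum to 1; labels argmax with low tie
  sc <- predict_scores(t1, d$X)
  expect_equal(rowSums(sc), rep(1, nrow(sc)))
  expect_equal(predict(t1, d$X),
               t1$classes[max.col(sc, ties.method = "first")])
  expect_error(predict_scores(t1, d$X[, 1:2]), "feature count")
})

test_that("impurity never increases down a path", {
  d <- blob_data(n = 120, K = 2, p = 4, sep = 2, sd = 2, seed = 8)
  tr <- fit_tree(d$X, d$y)
  check <- function(nd) {
    if (nd$leaf) return(invisible())
    H <- entropy_impurity(nd$counts / sum(nd$counts))
    HL <- entropy_impurity(nd$left$counts / sum(nd$left$counts))
    HR <- entropy_impurity(nd$right$counts / sum(nd$right$counts))
    nl <- sum(nd$left$counts); nr <- sum(nd$right$counts)
    G <- (nl * HL + nr * HR) / (nl + nr)
    expect_lte(G, H + 1e-12)
    check(nd$left); check(nd$right)
  }
  check(tr$root)
})

test_that("predictions are invariant to monotone feature transforms", {
  d <- blob_data(n = 100, K = 3, p = 4, sep = 3, seed = 13)
  X2 <- d$X
  X2[, 2] <- exp(d$X[, 2] / 2)     # strictly increasing transform
  t1 <- fit_tree(d$X, d$y); t2 <- fit_tree(X2, d$y)
  expect_equal(predict(t1, d$X), predict(t2, X2))
})

test_that("tree predictions match the reference CART implementation", {
  skip_if_not_installed("rpart")
  set.seed(99)
  matched <- 0; total <- 0
  for (rep in 1:20) {
    K <- sample(2:3, 1); p <- sample(3:8, 1); n <- sample(30:200, 1)
    cen <- matrix(rnorm(K * p, sd = 2.5), K, p)
    y <- sample(0:(K - 1), n, replace = TRUE)
    X <- cen[y + 1, , drop = FALSE] + matrix(rnorm(n * p), n, p)
    colnames(X) <- paste0("f", seq_len(p))
    ours <- predict(fit_tree(X, y), X)
    df <- data.frame(y = factor(y), X)
    ref <- rpart::rpart(y ~ ., df, method = "class",
                        parms = list(split = "information"),
                        control = rpart::rpart.control(
                          minsplit = 2, minbucket = 1, cp = 0,
                          maxdepth = 9, xval = 0))
    refp <- as.integer(as.character(predict(ref, df, type = "class")))
    total <- total + 1
    if (all(ours == refp)) matched <- matched + 1
  }
  expect_equal(matched, total)
})

test_that("JSON serialization round-trips losslessly", {
  d <- blob_data(n = 80, K = 3, p = 4, sep = 3, seed = 21)
  tr <- fit_tree(d$X, d$y)
  path <- tempfile(fileext = ".json")
  save_tree_json(tr, path)
  back <- load_tree_json(path)
  expect_equal(predict(back, d$X), predict(tr, d$X))
  expect_equal(predict_scores(back, d$X), predict_scores(tr, d$X))
  expect_equal(back$classes, tr$classes)
  notatree <- tempfile(fileext = ".json")
  jsonlite::write_json(list(foo = 1), notatree)
  expect_error(load_tree_json(notatree), "not a macroflim tree")
})
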