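## From-scratch CART decision tree with entropy impurity.

#' Decision-tree hyperparameters
#'
#' Defaults follow the phenotyping model: entropy impurity, maximum
#' depth 9, minimum 2 samples to split, equal sample weights.
#'
#' @param max_depth Maximum tree depth (root at depth 0).
#' @param min_samples_split Minimum node size eligible for splitting.
#' @return A list with `criterion`, `max_depth`, `min_samples_split`.
#' @export
tree_hyperparams <- function(max_depth = 9L, min_samples_split = 2L) {
  stopifnot(max_depth >= 1, min_samples_split >= 2)
  list(criterion = "entropy", max_depth = as.integer(max_depth),
       min_samples_split = as.integer(min_samples_split))
}

#' Entropy impurity
#'
#' `H = -sum(p_k * log2(p_k))` in bits, with `0 * log(0) = 0`.
#'
#' @param p Class proportions (non-negative, summing to 1).
#' @return Entropy in bits.
#' @examples
#' entropy_impurity(c(0.5, 0.5))  # 1 bit
#' @export
entropy_impurity <- function(p) {
  if (any(p < 0)) stop("proportions must be non-negative")
  if (abs(sum(p) - 1) > 1e-8) stop("proportions must sum to 1")
  nz <- p[p > 0]
  -sum(nz * log2(nz))
}

# entropy (bits) for rows of a count matrix C with row totals n
ent_rows <- function(C, n) {
  p <- C / n
  lp <- ifelse(p > 0, log2(p), 0)
  -rowSums(p * lp)
}

#' Best split of a node by weighted child entropy
#'
#' Exhaustive scan over all features and candidate thresholds (midpoints
#' between consecutive distinct sorted values). The split `x_j <= t`
#' minimising `G = (n_left/N)*H(left) + (n_right/N)*H(right)` is
#' returned; ties are broken by lowest feature index, then lowest
#' threshold.
#'
#' @param X Numeric matrix (samples x features), no missing values.
#' @param y Integer class labels.
#' @param classes Class values to tabulate over (default `sort(unique(y))`).
#' @return `NULL` when no valid split exists (pure node or all feature
#'   values constant); otherwise a list with `feature` (column index),
#'   `threshold`, and `G` (weighted child entropy, bits).
#' @examples
#' best_split(matrix(c(1, 2, 9, 10)), c(0L, 0L, 1L, 1L))  # threshold 5.5, G = 0
#' @export
best_split <- function(X, y, classes = sort(unique(y))) {
  n <- length(y)
  if (n < 2 || length(unique(y)) < 2) return(NULL)
  yk <- match(y, classes)
  K <- length(classes)
  best <- NULL
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    ord <- order(x)
    xs <- x[ord]
    cut <- which(xs[-n] < xs[-1])   # boundaries between distinct values
    if (!length(cut)) next
    ind <- matrix(0, n, K)
    ind[cbind(seq_len(n), yk[ord])] <- 1
    cumC <- apply(ind, 2, cumsum)
    left <- cumC[cut, , drop = FALSE]
    tot <- cumC[n, ]
    right <- rep(1, length(cut)) %o% tot - left
    nL <- cut
    nR <- n - nL
    G <- (nL * ent_rows(left, nL) + nR * ent_rows(right, nR)) / n
    k <- which.min(G)
    if (is.null(best) || G[k] < best$G)
      best <- list(feature = j, threshold = (xs[cut[k]] + xs[cut[k] + 1]) / 2,
                   G = G[k])
  }
  best
}

build_node <- function(X, y, classes, depth, hp) {
  counts <- tabulate(match(y, classes), nbins = length(classes))
  node <- list(counts = counts, depth = depth)
  n <- length(y)
  H <- entropy_impurity(counts / n)
  if (H == 0 || n < hp$min_samples_split || depth >= hp$max_depth) {
    node$leaf <- TRUE
    return(node)
  }
  sp <- best_split(X, y, classes)
  if (is.null(sp)) { # no valid split (all feature values identical)
    node$leaf <- TRUE
    return(node)
  }
  go_left <- X[, sp$feature] <= sp$threshold
  node$leaf <- FALSE
  node$feature <- sp$feature
  node$threshold <- sp$threshold
  node$left <- build_node(X[go_left, , drop = FALSE], y[go_left],
                          classes, depth + 1L, hp)
  node$right <- build_node(X[!go_left, , drop = FALSE], y[!go_left],
                           classes, depth + 1L, hp)
  node
}

#' Fit an entropy decision tree
#'
#' Recursive binary splitting with entropy impurity: a node becomes a
#' leaf when pure, smaller than `min_samples_split`, at `max_depth`, or
#' when no feature has two distinct values. An impure node with a valid
#' split is always split, even at zero impurity gain (so e.g. 2-D XOR is
#' fit exactly); splitting is fully deterministic (ties broken by
#' feature index, then threshold).
#'
#' @param X Numeric matrix or data.frame (samples x features), no
#'   missing values, at least 2 rows.
#' @param y Integer class labels (e.g. 0 = M1, 1 = M2, 2 = other).
#' @param hp Hyperparameters from [tree_hyperparams()].
#' @return An object of class `flim_tree` with the nested `root` node,
#'   `classes`, `feature_names`, `hp` and `n_samples`.
#' @examples
#' cells <- simulate_reference_cells(seed = 1)
#' feats <- cells_to_features(cells)
#' tree <- fit_tree(feats$X, feats$y)
#' @export
fit_tree <- function(X, y, hp = tree_hyperparams()) {
  X <- as.matrix(X)
  if (nrow(X) < 2) stop("need at least 2 samples to fit a tree")
  if (nrow(X) != length(y)) stop("X and y sizes differ")
  if (anyNA(X) || anyNA(y)) stop("missing values are not supported")
  classes <- sort(unique(as.integer(y)))
  obj <- list(root = build_node(X, as.integer(y), classes, 0L, hp),
              classes = classes,
              feature_names = colnames(X),
              hp = hp, n_samples = nrow(X))
  class(obj) <- "flim_tree"
  obj
}

count_nodes <- function(node) {
  if (node$leaf) return(c(nodes = 1L, leaves = 1L))
  c(nodes = 1L, leaves = 0L) + count_nodes(node$left) + count_nodes(node$right)
}

#' @export
print.flim_tree <- function(x, ...) {
  cn <- count_nodes(x$root)
  cat(sprintf(
    "Entropy decision tree: %d samples, classes {%s}, %d nodes (%d leaves), max depth %d\n",
    x$n_samples, paste(x$classes, collapse = ", "), cn["nodes"],
    cn["leaves"], x$hp$max_depth))
  invisible(x)
}

assign_scores <- function(node, X, idx, out) {
  if (!length(idx)) return(out)
  if (node$leaf) {
    out[idx, ] <- matrix(node$counts / sum(node$counts), length(idx),
                         length(node$counts), byrow = TRUE)
    return(out)
  }
  go_left <- X[idx, node$feature] <= node$threshold
  out <- assign_scores(node$left, X, idx[go_left], out)
  assign_scores(node$right, X, idx[!go_left], out)
}

#' Per-class scores (leaf class proportions)
#'
#' Each sample is routed to its leaf; the returned scores are the leaf's
#' training-class proportions `p_mk` (rows sum to 1). Used for ROC
#' analysis.
#'
#' @param model A `flim_tree`.
#' @param X Feature matrix with the training feature count.
#' @return Numeric matrix (samples x classes), columns named by class.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "flim_tree"))
  X <- as.matrix(X)
  nf <- length(model$feature_names)
  if (nf > 0 && ncol(X) != nf)
    stop("feature count mismatch: model expects ", nf)
  out <- matrix(NA_real_, nrow(X), length(model$classes),
                dimnames = list(NULL, model$classes))
  assign_scores(model$root, X, seq_len(nrow(X)), out)
}

#' Predict class labels
#'
#' Label of the highest leaf class proportion; ties resolve to the
#' lowest class value.
#'
#' @param object A `flim_tree`.
#' @param X Feature matrix.
#' @param ... Unused.
#' @return Integer labels in the training class set.
#' @export
predict.flim_tree <- function(object, X, ...) {
  sc <- predict_scores(object, X)
  object$classes[max.col(sc, ties.method = "first")]
}

node_to_list <- function(node) {
  if (node$leaf)
    return(list(leaf = TRUE, counts = node$counts, depth = node$depth))
  list(leaf = FALSE, counts = node$counts, depth = node$depth,
       feature = node$feature, threshold = node$threshold,
       left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(l) {
  out <- list(counts = as.integer(l$counts), depth = as.integer(l$depth),
              leaf = isTRUE(l$leaf))
  if (!out$leaf) {
    out$feature <- as.integer(l$feature)
    out$threshold <- as.numeric(l$threshold)
    out$left <- node_from_list(l$left)
    out$right <- node_from_list(l$right)
  }
  out
}

#' Save / load a tree model as JSON
#'
#' Lossless round trip of the nested node structure (feature indices,
#' thresholds at full precision, class counts).
#'
#' @param model A `flim_tree`.
#' @param path Output/input JSON path.
#' @return `save_tree_json` returns `path` invisibly; `load_tree_json`
#'   returns the restored `flim_tree`.
#' @export
save_tree_json <- function(model, path) {
  stopifnot(inherits(model, "flim_tree"))
  obj <- list(format = "macroflim_tree_v1",
              classes = model$classes,
              feature_names = model$feature_names,
              hp = model$hp, n_samples = model$n_samples,
              root = node_to_list(model$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname save_tree_json
#' @export
load_tree_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  if (!identical(obj$format, "macroflim_tree_v1"))
    stop("not a macroflim tree JSON file")
  model <- list(root = node_from_list(obj$root),
                classes = as.integer(obj$classes),
                feature_names = obj$feature_names,
                hp = tree_hyperparams(obj$hp$max_depth,
                                      obj$hp$min_samples_split),
                n_samples = as.integer(obj$n_samples))
  class(model) <- "flim_tree"
  model
}
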