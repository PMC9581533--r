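# Shared fixtures: a clean instrument, representative cells, and small
# random blob datasets for classifier checks.

test_instrument <- function(background_rate = 0, ...) {
  flim_instrument(background_rate = background_rate, ...)
}

# in vivo M1-like ground truth (tau1 = 196 ps, tau2 = 1698 ps, a1/a2 = 5)
m1_cell <- function() list(tau1 = 196, tau2 = 1698, a1 = 5 / 6)

# well-separated Gaussian blob dataset for classifier tests
blob_data <- function(n = 60, K = 2, p = 3, sep = 6, sd = 1, seed = 1) {
  set.seed(seed)
  y <- sample(0:(K - 1), n, replace = TRUE)
  cen <- matrix(seq_len(K * p) * sep / p, K, p)
  X <- cen[y + 1, , drop = FALSE] + matrix(rnorm(n * p, sd = sd), n, p)
  colnames(X) <- paste0("f", seq_len(p))
  list(X = X, y = y)
}

# brute-force best-split oracle: scan every (feature, midpoint) pair
brute_force_split <- function(X, y) {
  n <- length(y)
  ent <- function(yy) {
    p <- table(yy) / length(yy)
    -sum(p * log2(p))
  }
  best <- NULL
  for (j in seq_len(ncol(X))) {
    v <- sort(unique(X[, j]))
    if (length(v) < 2) next
    for (t in (head(v, -1) + tail(v, -1)) / 2) {
      L <- y[X[, j] <= t]; R <- y[X[, j] > t]
      G <- (length(L) * ent(L) + length(R) * ent(R)) / n
      if (is.null(best) || G < best$G)
        best <- list(feature = j, threshold = t, G = G)
    }
  }
  best
}
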