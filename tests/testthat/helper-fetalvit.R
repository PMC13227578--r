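# Shared fixtures and independent oracles for the test suite.  Oracles are
# deliberately written as plain double loops / direct formula evaluations so
# they stay independent of the implementation paths they check.

# Direct evaluation of softmax(Q K' / sqrt(d_k)) V from the definition.
attn_oracle <- function(E_q, E_c, W_Q, W_K, W_V) {
  Q <- E_q %*% W_Q; K <- E_c %*% W_K; V <- E_c %*% W_V
  S <- Q %*% t(K) / sqrt(ncol(W_Q))
  A <- t(apply(S, 1L, function(z) { e <- exp(z - max(z)); e / sum(e) }))
  if (nrow(S) == 1L) A <- matrix(A, 1L)   # apply() drops the row dimension
  list(output = A %*% V, weights = A)
}

# Intensity-weighted centroid by explicit double loop (0-based coordinates).
centroid_oracle <- function(w) {
  tot <- 0; sr <- 0; sc <- 0
  for (i in seq_len(nrow(w))) for (j in seq_len(ncol(w))) {
    tot <- tot + w[i, j]
    sr <- sr + (i - 1) * w[i, j]
    sc <- sc + (j - 1) * w[i, j]
  }
  c(row = sr / tot, col = sc / tot)
}

# Per-class precision/recall by explicit counting.
counting_oracle <- function(y_true, y_pred, C) {
  prec <- numeric(C); rec <- numeric(C)
  for (k in 0:(C - 1L)) {
    tp <- sum(y_true == k & y_pred == k)
    fp <- sum(y_true != k & y_pred == k)
    fn <- sum(y_true == k & y_pred != k)
    prec[k + 1L] <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec[k + 1L] <- if (tp + fn > 0) tp / (tp + fn) else 0
  }
  list(precision = prec, recall = rec)
}

# Healthy-vs-severe phantom task used by the training-level tests.
mk_binary_task <- function(seed, n = 160, size = 32) {
  ds <- generate_dataset(
    n = n,
    class_proportions = c(healthy = 0.5, mild = 0, moderate = 0, severe = 0.5),
    seed = seed, height = size, width = size)
  samp <- as_model_samples(ds$samples, binary_severe = TRUE)
  list(train = samp[ds$manifest$split == "train"],
       val = samp[ds$manifest$split %in% c("val", "test")])
}

small_run_config <- function(seed, size = 32, depth = 1L, epochs = 12L,
                             lr = 1e-3, lambda = 0.5) {
  validate_config(list(
    image_height = size, image_width = size, patch_size = 8L,
    embed_dim = 32L, depth = depth, heads = 4L, n_classes = 2L,
    lambda = lambda, learning_rate = lr, batch_size = 16L,
    max_epochs = epochs, patience = epochs, seed = seed))
}

# Rebuild a parameter tree from a flat coordinate vector (finite differences).
nl_rebuild <- function(tree, vals, pos = 1L) {
  if (is.list(tree)) {
    for (i in seq_along(tree)) {
      r <- nl_rebuild(tree[[i]], vals, pos)
      tree[[i]] <- r$tree; pos <- r$pos
    }
    list(tree = tree, pos = pos)
  } else {
    n <- length(tree)
    tree[] <- vals[pos:(pos + n - 1L)]
    list(tree = tree, pos = pos + n)
  }
}

perturb_param <- function(params, k, h) {
  f <- fetalvit:::nl_flatten(params)
  f[k] <- f[k] + h
  nl_rebuild(params, f)$tree
}

# Vectorized IoU/DSC over all pairs of 3x3 binary masks (for the identity
# check): rows of M are the 512 masks flattened.
all_3x3_pairs <- function() {
  M <- as.matrix(expand.grid(rep(list(0:1), 9L)))
  I <- M %*% t(M)
  s <- rowSums(M)
  U <- outer(s, s, `+`) - I
  iou <- ifelse(U == 0, 100, 100 * I / U)
  dsc <- ifelse(outer(s, s, `+`) == 0, 100, 100 * 2 * I / outer(s, s, `+`))
  list(M = M, iou = iou, dsc = dsc)
}
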