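# Patch-based transformer: patchify, linear patch embedding, sinusoidal
# positional encoding, (multi-head) self- and cross-attention, pre-norm
# encoder blocks, and the dual classification/severity heads.

#' Transformer model configuration
#'
#' @param image_size Integer vector `c(H, W)` in pixels; the patch size must
#'   divide both.
#' @param patch_size Patch side length P in pixels.
#' @param embed_dim Token embedding dimension D (must be divisible by
#'   `heads`).
#' @param depth Number of encoder blocks L (0 is allowed and reduces the
#'   trunk to patch embedding + pooling).
#' @param heads Number of attention heads; each head has key dimension
#'   `embed_dim / heads`, and `heads = 1` reproduces the single-head
#'   attention equations exactly.
#' @param n_classes Number of health classes C (>= 2); 3 matches the
#'   reference classification report, 4 covers
#'   healthy/mild/moderate/severe labelling.
#' @param mlp_mult Feed-forward hidden width as a multiple of D.
#' @param pos_encoding `"1d"` (sinusoidal over the row-major patch index),
#'   `"2d"` (factored row/column encodings) or `"none"`.
#' @param cross_attention Add one cross-attention block whose queries come
#'   from the final encoder layer and keys/values from an earlier layer.
#' @param cross_source Index of the encoder layer feeding keys/values to the
#'   cross-attention block.
#' @param attention `"standard"`, or `"identity"` to replace every attention
#'   mixer with an identity pass-through (ablation variant).
#' @return An object of class `vit_config`.
#' @export
vit_config <- function(image_size = c(224L, 224L), patch_size = 16L,
                       embed_dim = 64L, depth = 4L, heads = 4L,
                       n_classes = 3L, mlp_mult = 4L,
                       pos_encoding = c("1d", "2d", "none"),
                       cross_attention = FALSE, cross_source = 1L,
                       attention = c("standard", "identity")) {
  pos_encoding <- match.arg(pos_encoding)
  attention <- match.arg(attention)
  if (length(image_size) == 1L) image_size <- rep(image_size, 2L)
  image_size <- as.integer(image_size)
  patch_size <- as.integer(patch_size)
  if (any(image_size %% patch_size != 0L))
    stop_invalid("patch_size must divide both image dimensions")
  if (embed_dim %% heads != 0L)
    stop_invalid("embed_dim must be divisible by heads")
  if (n_classes < 2L) stop_invalid("n_classes must be >= 2")
  if (depth < 0L) stop_invalid("depth must be >= 0")
  if (cross_attention && (cross_source < 1L || cross_source > max(depth, 1L)))
    stop_invalid("cross_source must name an encoder layer")
  structure(list(
    image_size = image_size, patch_size = patch_size,
    embed_dim = as.integer(embed_dim), depth = as.integer(depth),
    heads = as.integer(heads), d_k = as.integer(embed_dim / heads),
    n_classes = as.integer(n_classes), mlp_mult = as.integer(mlp_mult),
    pos_encoding = pos_encoding, cross_attention = isTRUE(cross_attention),
    cross_source = as.integer(cross_source), attention = attention
  ), class = "vit_config")
}

#' @export
print.vit_config <- function(x, ...) {
  cat(sprintf(
    "<vit_config> %dx%d image, P=%d (N=%d tokens), D=%d, depth=%d, heads=%d, C=%d\n",
    x$image_size[1], x$image_size[2], x$patch_size,
    prod(x$image_size %/% x$patch_size), x$embed_dim, x$depth, x$heads,
    x$n_classes))
  cat(sprintf("  pos_encoding=%s, cross_attention=%s, attention=%s\n",
              x$pos_encoding,
              if (x$cross_attention) sprintf("layer %d -> final", x$cross_source)
              else "off", x$attention))
  invisible(x)
}

#' Split an image into non-overlapping square patches
#'
#' Divides an H x W image into `(H/P) * (W/P)` patches of size P x P, ordered
#' row-major over the patch grid.  Each patch is flattened row-major into one
#' row of the returned matrix, so [unpatchify()] reconstructs the image
#' exactly.
#'
#' @param img Numeric matrix.
#' @param patch_size Patch side P; must divide both image dimensions (no
#'   implicit padding).
#' @return An object of class `patch_grid`: list with `patches`
#'   (N x P^2 matrix), `rows`, `cols`, `patch_size`.
#' @export
patchify <- function(img, patch_size) {
  assert_image(img)
  P <- as.integer(patch_size)
  H <- nrow(img); W <- ncol(img)
  if (P < 1L || H %% P != 0L || W %% P != 0L)
    stop_invalid("patch_size must divide both image dimensions (",
                 H, "x", W, " with P=", P, ")")
  rows <- H %/% P; cols <- W %/% P
  N <- rows * cols
  patches <- matrix(0, N, P * P)
  k <- 1L
  for (pr in seq_len(rows)) {
    r0 <- (pr - 1L) * P
    for (pc in seq_len(cols)) {
      c0 <- (pc - 1L) * P
      block <- img[(r0 + 1L):(r0 + P), (c0 + 1L):(c0 + P), drop = FALSE]
      patches[k, ] <- as.vector(t(block))  # row-major flattening
      k <- k + 1L
    }
  }
  structure(list(patches = patches, rows = rows, cols = cols,
                 patch_size = P), class = "patch_grid")
}

#' Reassemble an image from a patch grid
#'
#' Exact inverse of [patchify()].
#'
#' @param grid A `patch_grid`.
#' @return The reconstructed image matrix.
#' @export
unpatchify <- function(grid) {
  if (!inherits(grid, "patch_grid")) stop_invalid("grid must be a patch_grid")
  P <- grid$patch_size
  img <- matrix(0, grid$rows * P, grid$cols * P)
  k <- 1L
  for (pr in seq_len(grid$rows)) {
    r0 <- (pr - 1L) * P
    for (pc in seq_len(grid$cols)) {
      c0 <- (pc - 1L) * P
      img[(r0 + 1L):(r0 + P), (c0 + 1L):(c0 + P)] <-
        matrix(grid$patches[k, ], P, P, byrow = TRUE)
      k <- k + 1L
    }
  }
  img
}

#' Linearly embed flattened patches
#'
#' Maps each flattened P^2 patch to a D-dimensional token:
#' `E[i, ] = patches[i, ] %*% projection + bias`.
#'
#' @param grid A `patch_grid` (or plain N x P^2 matrix).
#' @param projection P^2 x D projection matrix.
#' @param bias Length-D bias vector (defaults to zeros).
#' @return N x D embedding matrix.
#' @export
embed_patches <- function(grid, projection, bias = NULL) {
  X <- if (inherits(grid, "patch_grid")) grid$patches else grid
  if (!is.matrix(X) || !is.matrix(projection))
    stop_invalid("patches and projection must be matrices")
  if (ncol(X) != nrow(projection))
    stop_invalid("projection must have P^2 rows (got ", nrow(projection),
                 ", need ", ncol(X), ")")
  D <- ncol(projection)
  if (is.null(bias)) bias <- numeric(D)
  if (length(bias) != D) stop_invalid("bias length must equal embedding dim")
  X %*% projection + matrix(bias, nrow(X), D, byrow = TRUE)
}

#' Sinusoidal positional encoding
#'
#' Classic fixed encoding: for position `pos` (0-based) and channel pair `i`,
#' `PE[pos, 2i] = sin(pos / 10000^(2i/D))` and
#' `PE[pos, 2i+1] = cos(pos / 10000^(2i/D))`.  Added element-wise to the
#' patch embeddings.  For 2-D grids a factored variant is available in which
#' the first D/2 channels encode the patch row and the last D/2 the patch
#' column.
#'
#' @param n_positions Number of positions N.
#' @param dim Embedding dimension D (must be even).
#' @return N x D matrix with entries in \[-1, 1\].
#' @export
positional_encoding <- function(n_positions, dim) {
  if (dim %% 2L != 0L) stop_invalid("dim must be even")
  if (n_positions < 1L) stop_invalid("n_positions must be >= 1")
  pos <- 0:(n_positions - 1L)
  i <- 0:(dim %/% 2L - 1L)
  freq <- 1 / 10000^(2 * i / dim)
  ang <- outer(pos, freq)            # N x D/2
  PE <- matrix(0, n_positions, dim)
  PE[, 2L * i + 1L] <- sin(ang)
  PE[, 2L * i + 2L] <- cos(ang)
  PE
}

# Factored 2-D variant: row index encoded in channels 1..D/2, column index in
# channels D/2+1..D (each half itself sinusoidal).
positional_encoding_2d <- function(rows, cols, dim) {
  if (dim %% 2L != 0L) stop_invalid("dim must be even")
  half <- dim %/% 2L
  if (half %% 2L != 0L) stop_invalid("dim must be divisible by 4 for 2-D encoding")
  per <- positional_encoding(rows, half)
  pec <- positional_encoding(cols, half)
  PE <- matrix(0, rows * cols, dim)
  k <- 1L
  for (r in seq_len(rows)) {
    for (cc in seq_len(cols)) {
      PE[k, ] <- c(per[r, ], pec[cc, ])
      k <- k + 1L
    }
  }
  PE
}

#' Scaled dot-product self-attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V` with `Q = E W_Q`, `K = E W_K`,
#' `V = E W_V` over one token sequence.  The N x N attention-weight matrix is
#' row-stochastic and returned alongside the output.
#'
#' @param E N x D embedding matrix.
#' @param params List with `W_Q`, `W_K`, `W_V` (D x d_k matrices).
#' @return List with `output` (N x d_k) and `weights` (N x N).
#' @export
self_attention <- function(E, params) {
  cross_attention(E, E, params)
}

#' Scaled dot-product cross-attention
#'
#' Same operation as [self_attention()] but queries come from `E_query`
#' while keys and values come from `E_context`; with
#' `E_context = E_query` it reduces to self-attention exactly.
#'
#' @param E_query N_q x D matrix providing queries.
#' @param E_context N_c x D matrix providing keys and values.
#' @param params List with `W_Q`, `W_K`, `W_V` (D x d_k matrices).
#' @return List with `output` (N_q x d_k) and `weights` (N_q x N_c).
#' @export
cross_attention <- function(E_query, E_context, params) {
  if (!is.matrix(E_query) || !is.matrix(E_context))
    stop_invalid("embeddings must be matrices")
  if (ncol(E_query) != nrow(params$W_Q) || ncol(E_context) != nrow(params$W_K))
    stop_invalid("embedding column dimension does not match W_Q/W_K rows")
  d_k <- ncol(params$W_Q)
  if (is.null(d_k) || d_k == 0L) stop_invalid("d_k must be positive")
  Q <- E_query %*% params$W_Q
  K <- E_context %*% params$W_K
  V <- E_context %*% params$W_V
  S <- Q %*% t(K) / sqrt(d_k)
  A <- softmax_rows(S)
  list(output = A %*% V, weights = A)
}

#' Softmax classification head
#'
#' `softmax(W_class %*% features + b_class)`: a C-vector of positive
#' probabilities summing to one.
#'
#' @param features Pooled feature vector (length F).
#' @param W_class C x F weight matrix.
#' @param b_class Length-C bias vector.
#' @return Probability vector of length C.
#' @export
classification_head <- function(features, W_class, b_class) {
  if (!is.matrix(W_class) || ncol(W_class) != length(features))
    stop_invalid("W_class must be C x length(features)")
  if (length(b_class) != nrow(W_class))
    stop_invalid("b_class length must equal nrow(W_class)")
  softmax_vec(as.vector(W_class %*% features) + b_class)
}

#' Affine severity head
#'
#' `sum(w_severity * features) + b_severity`: a single continuous severity
#' score.
#'
#' @param features Pooled feature vector (length F).
#' @param w_severity Length-F weight vector.
#' @param b_severity Scalar bias.
#' @return Numeric scalar.
#' @export
severity_head <- function(features, w_severity, b_severity) {
  if (length(w_severity) != length(features))
    stop_invalid("w_severity length must equal length(features)")
  sum(w_severity * features) + b_severity
}

# --- parameter initialization ------------------------------------------------

xavier <- function(nr, nc) {
  s <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -s, s), nr, nc)
}

attn_head_params <- function(D, d_k) {
  list(W_Q = xavier(D, d_k), W_K = xavier(D, d_k), W_V = xavier(D, d_k))
}

#' Initialize transformer parameters
#'
#' Draws all learnable arrays from a scaled-uniform (Xavier) distribution
#' under the given seed.  The returned nested list mirrors the architecture:
#' patch projection, per-layer per-head attention matrices and feed-forward
#' weights, optional cross-attention block, and the two heads.
#'
#' @param config A [vit_config()].
#' @param seed Integer RNG seed.
#' @return Nested parameter list (class `vit_params`).
#' @export
vit_init <- function(config, seed = 1L) {
  D <- config$embed_dim; d_k <- config$d_k; P <- config$patch_size
  hid <- D * config$mlp_mult
  with_seed(seed, {
    params <- list(
      patch_proj = xavier(P * P, D),
      patch_bias = numeric(D),
      layers = lapply(seq_len(config$depth), function(l) list(
        heads = lapply(seq_len(config$heads), function(h) attn_head_params(D, d_k)),
        W1 = xavier(D, hid), b1 = numeric(hid),
        W2 = xavier(hid, D), b2 = numeric(D)
      )),
      W_class = xavier(config$n_classes, D),
      b_class = numeric(config$n_classes),
      w_severity = as.vector(xavier(D, 1L)),
      b_severity = 0
    )
    if (config$cross_attention && config$depth > 0L) {
      params$cross <- list(
        heads = lapply(seq_len(config$heads), function(h) attn_head_params(D, d_k))
      )
    }
    structure(params, class = "vit_params")
  })
}

# Multi-head attention used inside encoder blocks: per-head scaled dot-product
# attention, outputs concatenated back to D channels (heads = 1 is exactly the
# single-head equation).  Returns cache needed for the backward pass.
mha_forward <- function(U_q, U_c, head_params, d_k) {
  hs <- lapply(head_params, function(hp) {
    Q <- U_q %*% hp$W_Q; K <- U_c %*% hp$W_K; V <- U_c %*% hp$W_V
    A <- softmax_rows(Q %*% t(K) / sqrt(d_k))
    list(Q = Q, K = K, V = V, A = A, O = A %*% V)
  })
  M <- do.call(cbind, lapply(hs, `[[`, "O"))
  Abar <- Reduce(`+`, lapply(hs, `[[`, "A")) / length(hs)
  list(M = M, heads = hs, Abar = Abar)
}

ln_rows <- function(X, eps = 1e-5) {
  mu <- rowMeans(X)
  Xc <- X - mu
  sig <- sqrt(rowMeans(Xc^2) + eps)
  list(Y = Xc / sig, sig = sig)
}

#' Run the transformer forward pass on one image
#'
#' Pipeline: patchify -> linear embedding -> (+ positional encoding) ->
#' `depth` pre-norm encoder blocks (multi-head self-attention and a
#' ReLU feed-forward, each with a residual connection) -> optional
#' cross-attention block (queries from the final layer, keys/values from
#' layer `cross_source`) -> mean pooling over tokens -> classification and
#' severity heads.
#'
#' @param params `vit_params` from [vit_init()].
#' @param img Image matrix matching `config$image_size`.
#' @param config The [vit_config()] the parameters were built for.
#' @param keep_cache Keep all intermediate activations (needed for the
#'   backward pass).
#' @return List with `class_probs` (length C, sums to 1), `severity`
#'   (scalar), `logits`, `features`, `attention` (per-layer head-averaged
#'   N x N weight matrices) and, if requested, `cache`.
#' @export
vit_forward <- function(params, img, config, keep_cache = FALSE) {
  assert_image(img)
  if (nrow(img) != config$image_size[1] || ncol(img) != config$image_size[2])
    stop_invalid("image shape does not match config$image_size")
  P <- config$patch_size; D <- config$embed_dim
  grid <- patchify(img, P)
  N <- nrow(grid$patches)
  E <- embed_patches(grid, params$patch_proj, params$patch_bias)
  PE <- switch(config$pos_encoding,
               "1d" = positional_encoding(N, D),
               "2d" = positional_encoding_2d(grid$rows, grid$cols, D),
               "none" = NULL)
  if (!is.null(PE)) E <- E + PE
  cache <- list(X = grid$patches, E0 = E, blocks = list(), layer_out = list())
  attn <- list()
  for (l in seq_len(config$depth)) {
    blk <- params$layers[[l]]
    E_in <- E
    ln1 <- ln_rows(E_in)
    if (config$attention == "identity") {
      M <- ln1$Y
      mh <- NULL
      attn[[l]] <- diag(N)
    } else {
      mh <- mha_forward(ln1$Y, ln1$Y, blk$heads, config$d_k)
      M <- mh$M
      attn[[l]] <- mh$Abar
    }
    E_mid <- E_in + M
    ln2 <- ln_rows(E_mid)
    H1 <- ln2$Y %*% blk$W1 + matrix(blk$b1, N, length(blk$b1), byrow = TRUE)
    R <- pmax(H1, 0)
    FF <- R %*% blk$W2 + matrix(blk$b2, N, D, byrow = TRUE)
    E <- E_mid + FF
    cache$blocks[[l]] <- list(E_in = E_in, ln1 = ln1, mh = mh, M = M,
                              E_mid = E_mid, ln2 = ln2, H1 = H1, R = R)
    cache$layer_out[[l]] <- E
  }
  if (config$cross_attention && config$depth > 0L) {
    E_src <- cache$layer_out[[config$cross_source]]
    lnq <- ln_rows(E)
    lnc <- ln_rows(E_src)
    mh <- mha_forward(lnq$Y, lnc$Y, params$cross$heads, config$d_k)
    cache$cross <- list(E_q_in = E, lnq = lnq, lnc = lnc, mh = mh)
    attn[[length(attn) + 1L]] <- mh$Abar
    E <- E + mh$M
  }
  cache$E_final <- E
  feat <- colMeans(E)
  logits <- as.vector(params$W_class %*% feat) + params$b_class
  probs <- softmax_vec(logits)
  sev <- sum(params$w_severity * feat) + params$b_severity
  out <- list(class_probs = probs, severity = sev, logits = logits,
              features = feat, attention = attn, n_tokens = N,
              patch_rows = grid$rows, patch_cols = grid$cols)
  if (keep_cache) out$cache <- cache
  out
}
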