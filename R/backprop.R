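# Analytic reverse-mode gradients for the transformer.  Every path below is
# verified against central finite differences in the test suite.

# LayerNorm backward.  Forward: Y = (X - mu) / sig, sig = sqrt(var + eps),
# statistics taken per row.  Given dY and the cached (Y, sig):
#   dX = (dY - rowMeans(dY) - Y * rowMeans(dY * Y)) / sig
ln_backward <- function(dY, ln) {
  (dY - rowMeans(dY) - ln$Y * rowMeans(dY * ln$Y)) / ln$sig
}

# Single-head attention backward.  Cache from mha_forward; returns parameter
# gradients and gradients w.r.t. the (normed) query/context inputs.
attn_head_backward <- function(dO, hc, hp, U_q, U_c, d_k) {
  dV <- t(hc$A) %*% dO
  dA <- dO %*% t(hc$V)
  dS <- hc$A * (dA - rowSums(dA * hc$A))
  dQ <- dS %*% hc$K / sqrt(d_k)
  dK <- t(dS) %*% hc$Q / sqrt(d_k)
  list(
    W_Q = t(U_q) %*% dQ, W_K = t(U_c) %*% dK, W_V = t(U_c) %*% dV,
    dU_q = dQ %*% t(hp$W_Q),
    dU_c = dK %*% t(hp$W_K) + dV %*% t(hp$W_V)
  )
}

mha_backward <- function(dM, mh, head_params, U_q, U_c, d_k) {
  n_heads <- length(head_params)
  dU_q <- matrix(0, nrow(U_q), ncol(U_q))
  dU_c <- matrix(0, nrow(U_c), ncol(U_c))
  g_heads <- vector("list", n_heads)
  for (h in seq_len(n_heads)) {
    cols <- ((h - 1L) * d_k + 1L):(h * d_k)
    g <- attn_head_backward(dM[, cols, drop = FALSE], mh$heads[[h]],
                            head_params[[h]], U_q, U_c, d_k)
    g_heads[[h]] <- list(W_Q = g$W_Q, W_K = g$W_K, W_V = g$W_V)
    dU_q <- dU_q + g$dU_q
    dU_c <- dU_c + g$dU_c
  }
  list(heads = g_heads, dU_q = dU_q, dU_c = dU_c)
}

#' Gradients of the composite loss for one sample
#'
#' Backpropagates the per-sample loss
#' `-log(class_probs[y_class + 1]) + lambda * (severity - y_severity)^2`
#' through the entire network.  The returned gradient list mirrors the
#' parameter list structure exactly.
#'
#' @param params `vit_params`.
#' @param out Result of [vit_forward()] with `keep_cache = TRUE`.
#' @param config The matching [vit_config()].
#' @param y_class True class index (0-based).
#' @param y_severity True severity score.
#' @param lambda Severity-loss weight (>= 0).
#' @return List with `grads` (same shape as `params`), `loss_class`,
#'   `loss_severity`.
#' @export
vit_backward <- function(params, out, config, y_class, y_severity, lambda) {
  cache <- out$cache
  if (is.null(cache)) stop_invalid("forward pass must be run with keep_cache = TRUE")
  N <- out$n_tokens; D <- config$embed_dim
  probs <- out$class_probs
  d_logits <- probs
  d_logits[y_class + 1L] <- d_logits[y_class + 1L] - 1
  d_sev <- 2 * lambda * (out$severity - y_severity)

  feat <- out$features
  g <- list(
    patch_proj = NULL, patch_bias = NULL, layers = vector("list", config$depth),
    W_class = outer(d_logits, feat),
    b_class = d_logits,
    w_severity = d_sev * feat,
    b_severity = d_sev
  )
  dfeat <- as.vector(t(params$W_class) %*% d_logits) + d_sev * params$w_severity
  dE <- matrix(dfeat, N, D, byrow = TRUE) / N

  dE_extra <- vector("list", config$depth)  # gradient fan-in from cross block
  if (config$cross_attention && config$depth > 0L) {
    cc <- cache$cross
    gb <- mha_backward(dE, cc$mh, params$cross$heads, cc$lnq$Y, cc$lnc$Y, config$d_k)
    g$cross <- list(heads = gb$heads)
    dE <- dE + ln_backward(gb$dU_q, cc$lnq)      # residual + query path
    dE_extra[[config$cross_source]] <- ln_backward(gb$dU_c, cc$lnc)
  }

  for (l in rev(seq_len(config$depth))) {
    if (!is.null(dE_extra[[l]])) dE <- dE + dE_extra[[l]]
    blk <- params$layers[[l]]
    bc <- cache$blocks[[l]]
    # feed-forward sub-block
    dFF <- dE
    gW2 <- t(bc$R) %*% dFF
    gb2 <- colSums(dFF)
    dR <- dFF %*% t(blk$W2)
    dH1 <- dR * (bc$H1 > 0)
    gW1 <- t(bc$ln2$Y) %*% dH1
    gb1 <- colSums(dH1)
    dE_mid <- dE + ln_backward(dH1 %*% t(blk$W1), bc$ln2)
    # attention sub-block
    dM <- dE_mid
    if (config$attention == "identity") {
      dY1 <- dM
      g_heads <- lapply(blk$heads, function(hp)
        list(W_Q = hp$W_Q * 0, W_K = hp$W_K * 0, W_V = hp$W_V * 0))
    } else {
      gb_ <- mha_backward(dM, bc$mh, blk$heads, bc$ln1$Y, bc$ln1$Y, config$d_k)
      dY1 <- gb_$dU_q + gb_$dU_c
      g_heads <- gb_$heads
    }
    dE <- dE_mid + ln_backward(dY1, bc$ln1)
    g$layers[[l]] <- list(heads = g_heads, W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2)
  }

  g$patch_proj <- t(cache$X) %*% dE
  g$patch_bias <- colSums(dE)

  # keep field order identical to vit_init (cross appended last when present)
  ordered <- list(patch_proj = g$patch_proj, patch_bias = g$patch_bias,
                  layers = g$layers, W_class = g$W_class, b_class = g$b_class,
                  w_severity = g$w_severity, b_severity = g$b_severity)
  if (!is.null(params$cross)) ordered$cross <- g$cross
  list(grads = ordered,
       loss_class = -log(max(probs[y_class + 1L], 1e-12)),
       loss_severity = (out$severity - y_severity)^2)
}
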