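# Patchify/embedding/positional encoding/attention/heads/forward pass.

test_that("patchify produces the forced patch count and exact round trips", {
  big <- matrix(runif(224^2), 224, 224)
  expect_identical(nrow(patchify(big, 16)$patches), 196L)
  img <- matrix(1:16, 4, 4, byrow = TRUE)
  g <- patchify(img, 2)
  expect_equal(g$patches[1, ], c(1, 2, 5, 6))      # row-major flattening
  expect_equal(g$patches[2, ], c(3, 4, 7, 8))
  rnd <- matrix(runif(32^2), 32, 32)
  expect_identical(unpatchify(patchify(rnd, 8)), rnd)
  for (P in c(1, 2, 4, 8, 16, 32))
    expect_identical(nrow(patchify(rnd, P)$patches), as.integer((32 / P)^2))
  expect_error(patchify(rnd, 5), "divide")
})

test_that("patch embedding is the affine map it claims to be", {
  g <- patchify(matrix(runif(64), 8, 8), 4)
  D <- ncol(g$patches)
  expect_equal(embed_patches(g, diag(D)), g$patches)   # identity projection
  proj <- matrix(rnorm(16 * 5), 16, 5)
  bias <- rnorm(5)
  E <- embed_patches(g, proj, bias)
  expect_identical(dim(E), c(4L, 5L))
  # independent flatten-then-multiply oracle, one row at a time
  for (i in 1:4)
    expect_equal(E[i, ], as.vector(g$patches[i, ] %*% proj) + bias,
                 tolerance = 1e-12)
  expect_error(embed_patches(g, matrix(0, 15, 5)), "P\\^2")
})

test_that("sinusoidal positional encoding has the defining entries", {
  PE <- positional_encoding(10, 8)
  expect_equal(PE[1, c(1, 3, 5, 7)], rep(0, 4))   # sin(0)
  expect_equal(PE[1, c(2, 4, 6, 8)], rep(1, 4))   # cos(0)
  expect_equal(PE[3, 1], sin(2), tolerance = 1e-12)
  expect_equal(PE[3, 2], cos(2), tolerance = 1e-12)
  expect_equal(PE[5, 3], sin(4 / 10000^(2 / 8)), tolerance = 1e-12)
  expect_true(all(PE >= -1 & PE <= 1))
  big <- positional_encoding(512, 64)
  expect_false(any(duplicated(round(big, 12))))   # all positions distinct
  expect_error(positional_encoding(4, 7), "even")
})

test_that("self-attention handles the degenerate single-token and zero-weight cases", {
  p <- list(W_Q = matrix(rnorm(8), 4, 2), W_K = matrix(rnorm(8), 4, 2),
            W_V = matrix(rnorm(8), 4, 2))
  E1 <- matrix(rnorm(4), 1, 4)
  r1 <- self_attention(E1, p)
  expect_equal(r1$weights, matrix(1, 1, 1))
  expect_equal(r1$output, E1 %*% p$W_V)
  E <- matrix(rnorm(12), 3, 4)
  pz <- p; pz$W_Q <- matrix(0, 4, 2)
  rz <- self_attention(E, pz)
  expect_equal(rz$weights, matrix(1 / 3, 3, 3))
  V <- E %*% p$W_V
  for (i in 1:3) expect_equal(rz$output[i, ], colMeans(V), tolerance = 1e-12)
})

test_that("self- and cross-attention match the direct-evaluation oracle", {
  set.seed(31)
  p <- list(W_Q = matrix(rnorm(8), 4, 2), W_K = matrix(rnorm(8), 4, 2),
            W_V = matrix(rnorm(8), 4, 2))
  E <- matrix(rnorm(12), 3, 4)
  got <- self_attention(E, p)
  want <- attn_oracle(E, E, p$W_Q, p$W_K, p$W_V)
  expect_equal(got$output, want$output, tolerance = 1e-10)
  expect_equal(got$weights, want$weights, tolerance = 1e-10)
  Ec <- matrix(rnorm(20), 5, 4)
  gotx <- cross_attention(E, Ec, p)
  wantx <- attn_oracle(E, Ec, p$W_Q, p$W_K, p$W_V)
  expect_equal(gotx$output, wantx$output, tolerance = 1e-10)
  # context = query reduces to self-attention
  expect_equal(cross_attention(E, E, p)$output, got$output)
  # single-token context: every output row is that token's value vector
  E1 <- matrix(rnorm(4), 1, 4)
  r <- cross_attention(E, E1, p)
  for (i in 1:3) expect_equal(r$output[i, ], as.vector(E1 %*% p$W_V))
  expect_error(cross_attention(E, matrix(0, 2, 3), p), "dimension")
})

test_that("attention weights are row-stochastic throughout a forward pass", {
  cfg <- vit_config(image_size = c(16, 16), patch_size = 4, embed_dim = 16,
                    depth = 3, heads = 4, n_classes = 3,
                    cross_attention = TRUE, cross_source = 2)
  params <- vit_init(cfg, seed = 2)
  out <- vit_forward(params, matrix(runif(256), 16, 16), cfg)
  expect_length(out$attention, 4L)   # 3 encoder layers + cross block
  for (A in out$attention) {
    expect_true(all(A >= 0))
    expect_equal(rowSums(A), rep(1, nrow(A)), tolerance = 1e-9)
  }
  expect_equal(sum(out$class_probs), 1, tolerance = 1e-12)
  expect_true(all(out$class_probs > 0))
})

test_that("classification head reproduces the worked-example probabilities", {
  we <- worked_example(quiet = TRUE)
  expect_equal(round(we$class_probs, 3), c(0.273, 0.021, 0.706))
  expect_equal(we$logits, c(0.75, -1.80, 1.70), tolerance = 1e-12)
  # zero weights: uniform distribution
  expect_equal(classification_head(c(1, 2), matrix(0, 3, 2), rep(0, 3)),
               rep(1 / 3, 3))
  # softmax shift invariance
  x <- rnorm(4); W <- matrix(rnorm(12), 3, 4); b <- rnorm(3)
  expect_equal(classification_head(x, W, b),
               classification_head(x, W, b + 7), tolerance = 1e-12)
  expect_error(classification_head(c(1, 2), W, b), "W_class")
})

test_that("severity head is the stated affine form", {
  we <- worked_example(quiet = TRUE)
  expect_equal(we$severity, 2.05, tolerance = 1e-12)
  expect_equal(severity_head(rnorm(5), rep(0, 5), 0.2), 0.2)
  set.seed(9)
  for (i in 1:5) {
    x <- rnorm(6); w <- rnorm(6); b <- rnorm(1)
    expect_identical(severity_head(x, w, b), sum(w * x) + b)
  }
  expect_error(severity_head(c(1, 2), c(1, 2, 3), 0), "length")
})

test_that("a depth-0 trunk with engineered embedding reduces to the worked example", {
  we <- worked_example(quiet = TRUE)
  cfg <- vit_config(image_size = c(2, 2), patch_size = 2, embed_dim = 3,
                    depth = 0, heads = 1, n_classes = 3, pos_encoding = "none")
  params <- vit_init(cfg, seed = 1)
  params$patch_proj <- matrix(0, 4, 3)
  params$patch_bias <- we$features        # single token = the pooled feature
  params$W_class <- we$W_class
  params$b_class <- we$b_class
  params$w_severity <- we$w_severity
  params$b_severity <- we$b_severity
  out <- vit_forward(params, matrix(0.5, 2, 2), cfg)
  expect_equal(out$features, we$features)
  expect_equal(out$class_probs, we$class_probs, tolerance = 1e-12)
  expect_equal(out$severity, 2.05, tolerance = 1e-12)
})

test_that("forward pass is deterministic for a fixed seed", {
  cfg <- vit_config(image_size = c(16, 16), patch_size = 4, embed_dim = 16,
                    depth = 2, heads = 2, n_classes = 4)
  img <- matrix(runif(256), 16, 16)
  o1 <- vit_forward(vit_init(cfg, seed = 5), img, cfg)
  o2 <- vit_forward(vit_init(cfg, seed = 5), img, cfg)
  expect_identical(o1$class_probs, o2$class_probs)
  expect_identical(o1$severity, o2$severity)
  o3 <- vit_forward(vit_init(cfg, seed = 6), img, cfg)
  expect_false(identical(o1$class_probs, o3$class_probs))
})

test_that("token permutation symmetry holds without positional encoding only", {
  # swapping two patch blocks of the image permutes tokens; with mean pooling
  # and no positional encoding the head outputs must be unchanged
  img <- matrix(runif(64), 8, 8)
  img2 <- img
  img2[1:4, 1:4] <- img[5:8, 5:8]
  img2[5:8, 5:8] <- img[1:4, 1:4]
  for (enc in c("none", "1d")) {
    cfg <- vit_config(image_size = c(8, 8), patch_size = 4, embed_dim = 8,
                      depth = 2, heads = 2, n_classes = 3, pos_encoding = enc)
    params <- vit_init(cfg, seed = 3)
    a <- vit_forward(params, img, cfg)
    b <- vit_forward(params, img2, cfg)
    if (enc == "none") {
      expect_equal(a$class_probs, b$class_probs, tolerance = 1e-12)
      expect_equal(a$severity, b$severity, tolerance = 1e-12)
    } else {
      expect_false(isTRUE(all.equal(a$class_probs, b$class_probs,
                                    tolerance = 1e-8)))
    }
  }
})
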