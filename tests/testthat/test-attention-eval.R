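# Attention rollout and the attention-alignment metric battery.

test_that("rollout degenerates to uniform at depth 0 and to one layer's average", {
  cfg0 <- vit_config(image_size = c(8, 8), patch_size = 4, embed_dim = 8,
                     depth = 0, heads = 1, n_classes = 2)
  att0 <- extract_attention_map(vit_init(cfg0, seed = 1),
                                matrix(runif(64), 8, 8), cfg0)
  expect_equal(att0$map, matrix(1 / 64, 8, 8))
  expect_equal(sum(att0$map), 1)

  cfg1 <- vit_config(image_size = c(8, 8), patch_size = 4, embed_dim = 8,
                     depth = 1, heads = 2, n_classes = 2)
  params <- vit_init(cfg1, seed = 2)
  img <- matrix(runif(64), 8, 8)
  att1 <- extract_attention_map(params, img, cfg1)
  A <- vit_forward(params, img, cfg1)$attention[[1]]
  Ahat <- (A + diag(4)) / 2
  Ahat <- Ahat / rowSums(Ahat)
  want <- colMeans(Ahat); want <- want / sum(want)
  expect_equal(att1$token_scores, want, tolerance = 1e-12)
  expect_true(all(att1$map >= 0))
  expect_equal(sum(att1$map), 1, tolerance = 1e-12)
})

test_that("centre-of-gravity shift recovers the 3-4-5 distance", {
  att <- matrix(0, 6, 6); att[1, 1] <- 1          # centroid (0, 0)
  ann <- matrix(FALSE, 6, 6); ann[4, 5] <- TRUE   # centroid (3, 4)
  expect_equal(cog_shift(att, ann), 5)
  # attention concentrated at the centroid of a symmetric mask
  ann2 <- matrix(FALSE, 7, 7); ann2[3:5, 3:5] <- TRUE
  att2 <- matrix(0, 7, 7); att2[4, 4] <- 2.5
  expect_equal(cog_shift(att2, ann2), 0)
  expect_error(cog_shift(att, matrix(FALSE, 6, 6)), "empty")
})

test_that("weighted centroids match a double-loop oracle", {
  set.seed(21)
  for (i in 1:5) {
    w <- matrix(runif(48), 6, 8)
    expect_equal(fetalvit:::grid_centroid(w), centroid_oracle(w),
                 tolerance = 1e-9)
  }
  att <- matrix(runif(48), 6, 8)
  ann <- matrix(runif(48) > 0.6, 6, 8)
  if (any(ann)) {
    ca <- centroid_oracle(att); cr <- centroid_oracle(ann * 1)
    expect_equal(cog_shift(att, ann), sqrt(sum((ca - cr)^2)), tolerance = 1e-9)
  }
})

test_that("attention focus ratio counts the thresholded area inside the region", {
  att <- matrix(0.001, 8, 8)
  att[cbind(c(2, 2, 7, 7), c(2, 3, 6, 7))] <- 1   # 4-pixel attention area
  ann <- matrix(FALSE, 8, 8); ann[1:3, 1:3] <- TRUE  # contains 2 of the 4
  expect_equal(afr(att, ann), 50)
  ann_all <- matrix(TRUE, 8, 8)
  expect_equal(afr(att, ann_all), 100)
  ann_out <- matrix(FALSE, 8, 8); ann_out[5, 1] <- TRUE
  expect_equal(afr(att, ann_out), 0)
})

test_that("weighted relevance score follows its Gaussian kernel", {
  ann <- matrix(FALSE, 9, 9); ann[4:6, 4:6] <- TRUE  # centroid (4, 4)
  att <- matrix(0, 9, 9); att[5, 5] <- 3             # all mass at the centroid
  expect_equal(wrs(att, ann), 1)
  # all mass at one off-centroid pixel: score is the kernel value at that
  # distance, recomputed here from the definition
  att2 <- matrix(0, 9, 9); att2[5, 8] <- 1
  sigma <- sqrt(9 / pi)
  expect_equal(wrs(att2, ann), exp(-3^2 / (2 * sigma^2)), tolerance = 1e-12)
  # random map: weighted-mean oracle
  set.seed(4)
  att3 <- matrix(runif(81), 9, 9)
  num <- 0
  for (i in 1:9) for (j in 1:9)
    num <- num + att3[i, j] * exp(-((i - 5)^2 + (j - 5)^2) / (2 * sigma^2))
  expect_equal(wrs(att3, ann), num / sum(att3), tolerance = 1e-9)
})

test_that("attention energy distribution partitions energy exactly", {
  ann <- matrix(FALSE, 4, 4); ann[1:2, ] <- TRUE
  inside <- matrix(0, 4, 4); inside[1, ] <- 1
  expect_equal(aed(inside, ann), 0)
  outside <- matrix(0, 4, 4); outside[4, ] <- 1
  expect_equal(aed(outside, ann), 100)
  half <- matrix(0, 4, 4); half[2, 1] <- 1; half[3, 1] <- 1
  expect_equal(aed(half, ann), 50)
  # complement identity for arbitrary maps
  set.seed(12)
  for (i in 1:5) {
    att <- matrix(runif(64), 8, 8)
    m <- matrix(runif(64) > 0.5, 8, 8)
    expect_equal(aed(att, m) + aed(att, !m), 100, tolerance = 1e-9)
  }
})

test_that("moving attention mass into the region helps AFR and hurts AED", {
  ann <- matrix(FALSE, 8, 8); ann[3:6, 3:6] <- TRUE
  att <- matrix(1 / 64, 8, 8)
  prev_afr <- afr(att, ann); prev_aed <- aed(att, ann)
  out_px <- which(!ann & att > 0)[1:6]
  in_px <- which(ann)
  for (k in 1:6) {
    att[out_px[k]] <- att[out_px[k]] - 1 / 64
    att[in_px[k]] <- att[in_px[k]] + 1 / 64
    cur_afr <- afr(att, ann); cur_aed <- aed(att, ann)
    expect_gte(cur_afr, prev_afr - 1e-9)
    expect_lte(cur_aed, prev_aed + 1e-9)
    prev_afr <- cur_afr; prev_aed <- cur_aed
  }
})

test_that("IoU and DSC agree with their definitions and conventions", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(iou_dsc(a, a), c(iou = 100, dsc = 100))
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(iou_dsc(a, b), c(iou = 0, dsc = 0))
  # |A| = |B| = 4 with overlap 2
  c2 <- matrix(FALSE, 4, 4); c2[1:2, 2:3] <- TRUE
  got <- iou_dsc(a, c2)
  expect_equal(got[["iou"]], 100 * 2 / 6, tolerance = 1e-12)
  expect_equal(got[["dsc"]], 50)
  expect_equal(iou_dsc(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)),
               c(iou = 100, dsc = 100))
  expect_error(iou_dsc(a, matrix(FALSE, 3, 3)), "shape")
})

test_that("DSC equals 2 IoU / (100 + IoU) * 100 on every 3x3 mask pair", {
  pairs <- all_3x3_pairs()
  expect_equal(pairs$dsc, 2 * pairs$iou / (100 + pairs$iou) * 100,
               tolerance = 1e-9)
  # spot-check the iou_dsc() function against the vectorized enumeration
  set.seed(33)
  for (k in 1:200) {
    i <- sample(512, 1); j <- sample(512, 1)
    got <- iou_dsc(matrix(pairs$M[i, ], 3), matrix(pairs$M[j, ], 3))
    expect_equal(got[["iou"]], pairs$iou[i, j], tolerance = 1e-9)
    expect_equal(got[["dsc"]], pairs$dsc[i, j], tolerance = 1e-9)
  }
})

test_that("cog_shift is symmetric for binary grids", {
  set.seed(8)
  for (k in 1:5) {
    a <- matrix(runif(36) > 0.5, 6, 6)
    b <- matrix(runif(36) > 0.5, 6, 6)
    if (any(a) && any(b))
      expect_equal(cog_shift(a * 1, b), cog_shift(b * 1, a))
  }
})

test_that("ODM averages per-frame IoU", {
  # build two frames with known per-frame IoUs, then compare to the mean
  mk <- function(seed) {
    set.seed(seed)
    att <- matrix(runif(64), 8, 8)
    ann <- matrix(runif(64) > 0.5, 8, 8)
    list(att = att, ann = ann,
         iou = iou_dsc(fetalvit:::binarize_attention(att), ann)[["iou"]])
  }
  f1 <- mk(1); f2 <- mk(2)
  expect_equal(odm(list(f1$att), list(f1$ann)), f1$iou)
  expect_equal(odm(list(f1$att, f2$att), list(f1$ann, f2$ann)),
               mean(c(f1$iou, f2$iou)))
  expect_equal(odm(rep(list(f1$att), 4), rep(list(f1$ann), 4)), f1$iou)
  expect_error(odm(list(f1$att), list(f1$ann, f2$ann)), "length")
})

test_that("planted attention sharpening drives WRS up and AED down", {
  s <- generate_phantom(phantom_spec(height = 32, width = 32,
                                     class = "severe", seed = 10))
  expect_true(any(s$mask))
  sharp <- c(0, 1, 2, 4, 8)
  aeds <- numeric(length(sharp)); wrss <- numeric(length(sharp))
  for (i in seq_along(sharp)) {
    m <- plant_attention_target(s, sharp[i])
    aeds[i] <- aed(m, s$mask)
    wrss[i] <- wrs(m, s$mask)
  }
  expect_true(all(diff(aeds) < 0))
  expect_true(all(diff(wrss) > 0))
  # sharpness 0 is uniform: wasted energy is the complement area fraction
  expect_equal(aeds[1], 100 * (1 - sum(s$mask) / (32 * 32)), tolerance = 1e-9)
})

test_that("overlay blends a colour ramp and vanishes at alpha 0", {
  img <- matrix(runif(64), 8, 8)
  att <- matrix(runif(64), 8, 8)
  ov <- render_overlay(img, att, alpha = 0.5)
  expect_identical(dim(ov), c(8L, 8L, 3L))
  expect_true(all(ov >= 0 & ov <= 1))
  ov0 <- render_overlay(img, att, alpha = 0)
  for (ch in 1:3) expect_equal(ov0[, , ch], img)
  # uniform attention: one colour everywhere
  ovu <- render_overlay(matrix(0.5, 8, 8), matrix(1, 8, 8), alpha = 1)
  for (ch in 1:3) expect_equal(length(unique(as.vector(ovu[, , ch]))), 1L)
  expect_error(render_overlay(img, matrix(0, 4, 4)), "shape")
})

test_that("improvement table reproduces hand-computed before/after changes", {
  before <- data.frame(class = c("mild", "mild"), metric = c("iou", "f1"),
                       value = c(65, 77))
  after <- data.frame(class = c("mild", "mild"), metric = c("iou", "f1"),
                      value = c(70, 82))
  tab <- attention_improvement_table(before, after)
  expect_equal(tab$improvement_pct[tab$metric == "iou"], 7.7)
  expect_equal(tab$improvement_pct[tab$metric == "f1"], 6.5)
  same <- attention_improvement_table(before, before)
  expect_true(all(same$improvement_pct == 0))
  z <- before; z$value[1] <- 0
  flagged <- attention_improvement_table(z, after)
  expect_true(is.na(flagged$improvement_pct[flagged$metric == "iou"]))
})

test_that("the per-sample report carries the full metric column set", {
  s <- generate_phantom(phantom_spec(height = 32, width = 32,
                                     class = "moderate", seed = 3))
  att <- plant_attention_target(s, 4)
  rep <- attention_eval_report(att, s$mask)
  expect_identical(names(rep),
                   c("cog_shift", "afr", "wrs", "aed", "odm", "iou", "dsc"))
  expect_true(rep$afr >= 0 && rep$afr <= 100)
  expect_true(rep$wrs > 0 && rep$wrs <= 1)
  expect_true(rep$aed >= 0 && rep$aed <= 100)
  expect_gte(rep$cog_shift, 0)
})
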