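# Attention-rollout saliency maps and the attention-alignment metric set:
# centre-of-gravity shift, attention focus ratio, weighted relevance score,
# attention energy distribution, overlap dynamics, IoU and DSC.

as_attention_matrix <- function(att) {
  if (inherits(att, "attention_map")) att <- att$map
  if (!is.matrix(att) || !is.numeric(att))
    stop_invalid("attention map must be a numeric matrix")
  if (any(att < 0)) stop_invalid("attention weights must be non-negative")
  att
}

as_mask_matrix <- function(ann) {
  if (is.list(ann) && !is.null(ann$mask)) ann <- ann$mask
  if (!is.matrix(ann)) stop_invalid("annotation mask must be a matrix")
  m <- matrix(as.numeric(ann) != 0, nrow(ann), ncol(ann))
  m
}

# Intensity-weighted centroid in 0-based (row, col) pixel-center coordinates.
grid_centroid <- function(w) {
  tot <- sum(w)
  if (tot <= 0) stop_degenerate("cannot take the centroid of a zero grid")
  ri <- row(w) - 1
  ci <- col(w) - 1
  c(row = sum(ri * w) / tot, col = sum(ci * w) / tot)
}

#' Extract an attention map from a trained model
#'
#' Attention rollout: each layer's head-averaged attention matrix gets an
#' identity residual, `(A + I) / 2`, is row-renormalized, and the layers are
#' multiplied recursively; token relevance is the column mean of the rollout
#' product (the attention mass each patch receives, averaged over queries).
#' The token vector is upsampled nearest-neighbour from the patch grid to the
#' image and normalized to unit total energy.  A depth-0 model yields the
#' uniform map.
#'
#' @param params `vit_params`.
#' @param img Image matrix matching the model's input size.
#' @param config The matching [vit_config()].
#' @param method `"rollout"` (default) or `"last_layer"` (column means of the
#'   final head-averaged attention).
#' @return Object of class `attention_map`: list with `map` (H x W,
#'   non-negative, sums to 1), `token_scores` and `layers` (raw per-layer
#'   N x N weight matrices).
#' @export
extract_attention_map <- function(params, img, config,
                                  method = c("rollout", "last_layer")) {
  method <- match.arg(method)
  out <- vit_forward(params, img, config)
  N <- out$n_tokens
  layers <- out$attention
  if (length(layers) == 0L) {
    scores <- rep(1 / N, N)
  } else if (method == "last_layer") {
    scores <- colMeans(layers[[length(layers)]])
    scores <- scores / sum(scores)
  } else {
    R <- diag(N)
    for (A in layers) {
      Ahat <- (A + diag(nrow(A))) / 2
      Ahat <- Ahat / rowSums(Ahat)
      R <- Ahat %*% R
    }
    scores <- colMeans(R)
    scores <- scores / sum(scores)
  }
  P <- config$patch_size
  map <- unpatchify(structure(list(
    patches = matrix(rep(scores / (P * P), each = P * P),
                     nrow = N, ncol = P * P, byrow = TRUE),
    rows = out$patch_rows, cols = out$patch_cols, patch_size = P),
    class = "patch_grid"))
  structure(list(map = map, token_scores = scores, layers = layers),
            class = "attention_map")
}

#' Centre-of-gravity shift
#'
#' Euclidean distance (pixels) between the intensity-weighted centroid of the
#' attention map and the (uniform) centroid of the annotated region.
#'
#' @param att Attention map (H x W non-negative matrix or `attention_map`).
#' @param ann Binary annotation mask (non-empty).
#' @return Non-negative distance in pixels.
#' @export
cog_shift <- function(att, ann) {
  att <- as_attention_matrix(att)
  ann <- as_mask_matrix(ann)
  if (!any(ann)) stop_degenerate("annotation mask is empty")
  ca <- grid_centroid(att)
  cr <- grid_centroid(ann * 1)
  sqrt(sum((ca - cr)^2))
}

binarize_attention <- function(att, area_quantile = 0.9) {
  att <- as_attention_matrix(att)
  thr <- stats::quantile(att, probs = area_quantile, names = FALSE)
  A <- att > thr
  if (!any(A)) A <- att >= thr & att > 0   # plateau at the top quantile
  A
}

#' Attention focus ratio (percent)
#'
#' Binarizes the attention map by keeping the pixels above the
#' `area_quantile` weight quantile (default: top 10% of pixels by weight)
#' and returns the percentage of that attention area lying inside the
#' annotated region: `100 * |A intersect R| / |A|`.
#'
#' @param att Attention map.
#' @param ann Binary annotation mask (non-empty).
#' @param area_quantile Quantile defining the attention area (default 0.9).
#' @return Percentage in \[0, 100\].
#' @export
afr <- function(att, ann, area_quantile = 0.9) {
  ann <- as_mask_matrix(ann)
  if (!any(ann)) stop_degenerate("annotation mask is empty")
  A <- binarize_attention(att, area_quantile)
  if (!any(A)) stop_degenerate("thresholding left an empty attention area")
  100 * sum(A & ann) / sum(A)
}

#' Weighted relevance score
#'
#' Attention-mass-weighted mean of a Gaussian kernel of the distance to the
#' annotation centroid, `w(p) = exp(-d(p)^2 / (2 sigma^2))` with
#' `sigma = sqrt(|R| / pi)` (the equivalent circle radius of the region), so
#' the maximum attainable score is 1 when all attention sits on the centroid.
#'
#' @param att Attention map with positive total energy.
#' @param ann Binary annotation mask (non-empty).
#' @return Score in (0, 1\].
#' @export
wrs <- function(att, ann) {
  att <- as_attention_matrix(att)
  ann <- as_mask_matrix(ann)
  if (!any(ann)) stop_degenerate("annotation mask is empty")
  tot <- sum(att)
  if (tot <= 0) stop_degenerate("attention map has zero energy")
  ctr <- grid_centroid(ann * 1)
  sigma <- sqrt(sum(ann) / pi)
  d2 <- (row(att) - 1 - ctr["row"])^2 + (col(att) - 1 - ctr["col"])^2
  sum(att * exp(-d2 / (2 * sigma^2))) / tot
}

#' Attention energy distribution (percent wasted)
#'
#' Percentage of the total attention energy that falls outside the annotated
#' region; the inside and outside percentages sum to exactly 100.
#'
#' @param att Attention map with positive total energy.
#' @param ann Binary annotation mask.
#' @return Percentage in \[0, 100\].
#' @export
aed <- function(att, ann) {
  att <- as_attention_matrix(att)
  ann <- as_mask_matrix(ann)
  tot <- sum(att)
  if (tot <= 0) stop_degenerate("attention map has zero energy")
  100 * sum(att[!ann]) / tot
}

#' Intersection-over-union and Dice coefficient (percent)
#'
#' `IoU = 100 |A & B| / |A | B|`, `DSC = 100 * 2|A & B| / (|A| + |B|)`.
#' Two empty masks agree perfectly and return `(100, 100)` by convention.
#'
#' @param a,b Binary matrices of identical shape.
#' @return Named vector `c(iou = ..., dsc = ...)`.
#' @export
iou_dsc <- function(a, b) {
  a <- as_mask_matrix(a); b <- as_mask_matrix(b)
  if (!all(dim(a) == dim(b))) stop_invalid("masks must have the same shape")
  inter <- sum(a & b)
  uni <- sum(a | b)
  if (uni == 0) return(c(iou = 100, dsc = 100))
  c(iou = 100 * inter / uni, dsc = 100 * 2 * inter / (sum(a) + sum(b)))
}

#' Overlap dynamics metric (percent)
#'
#' Mean over sequential frames of the IoU between each frame's binarized
#' attention map and its annotation mask.  With `per_frame_pairs = FALSE`
#' the alternative reading — mean IoU between consecutive binarized maps —
#' is computed instead.
#'
#' @param att_sequence List of attention maps.
#' @param ann_sequence List of matching annotation masks (same length).
#' @param area_quantile Threshold quantile for binarization.
#' @param per_frame_pairs Score (map, mask) pairs per frame (default) or
#'   frame-to-frame map overlap.
#' @return Mean IoU percentage.
#' @export
odm <- function(att_sequence, ann_sequence, area_quantile = 0.9,
                per_frame_pairs = TRUE) {
  if (!per_frame_pairs) {
    if (length(att_sequence) < 2L)
      stop_invalid("frame-to-frame mode needs at least two frames")
    bins <- lapply(att_sequence, binarize_attention, area_quantile = area_quantile)
    ious <- vapply(seq_len(length(bins) - 1L), function(i)
      iou_dsc(bins[[i]], bins[[i + 1L]])[["iou"]], numeric(1))
    return(mean(ious))
  }
  if (length(att_sequence) == 0L ||
      length(att_sequence) != length(ann_sequence))
    stop_invalid("attention and annotation sequences must be non-empty and equal length")
  ious <- mapply(function(att, ann)
    iou_dsc(binarize_attention(att, area_quantile), ann)[["iou"]],
    att_sequence, ann_sequence)
  mean(ious)
}

#' Score one (attention map, annotation) pair on the full metric set
#'
#' @param att Attention map.
#' @param ann Binary annotation mask (non-empty).
#' @param area_quantile Threshold quantile for AFR/IoU/DSC binarization.
#' @return One-row `data.frame` with columns `cog_shift`, `afr`, `wrs`,
#'   `aed`, `odm`, `iou`, `dsc` (ODM for a single frame equals its IoU).
#' @export
attention_eval_report <- function(att, ann, area_quantile = 0.9) {
  id <- iou_dsc(binarize_attention(att, area_quantile), ann)
  data.frame(cog_shift = cog_shift(att, ann),
             afr = afr(att, ann, area_quantile),
             wrs = wrs(att, ann),
             aed = aed(att, ann),
             odm = id[["iou"]],
             iou = id[["iou"]], dsc = id[["dsc"]])
}

#' Overlay an attention map on a grayscale image
#'
#' The attention map is min-max normalized, mapped through a blue-to-red
#' colour ramp, and alpha-blended onto the image; `alpha = 0` returns the
#' original image replicated over three channels.
#'
#' @param img Grayscale image in \[0, 1\].
#' @param att Attention map of the same shape.
#' @param alpha Blend weight of the colour layer in \[0, 1\].
#' @return H x W x 3 array in \[0, 1\].
#' @export
render_overlay <- function(img, att, alpha = 0.5) {
  assert_image(img)
  att <- as_attention_matrix(att)
  if (!all(dim(img) == dim(att))) stop_invalid("image and map shapes differ")
  rng <- max(att) - min(att)
  a01 <- if (rng > 0) (att - min(att)) / rng else att * 0 + 0.5
  ramp <- grDevices::colorRamp(c("blue", "cyan", "yellow", "red"))
  cols <- ramp(as.vector(a01)) / 255
  out <- array(0, c(nrow(img), ncol(img), 3L))
  for (ch in 1:3)
    out[, , ch] <- (1 - alpha) * img + alpha * matrix(cols[, ch], nrow(img))
  out
}

#' Before/after attention-metric improvement table
#'
#' Joins two long-format metric tables (columns `class`, `metric`, `value`)
#' and appends the percent improvement
#' `100 * (after - before) / before`, rounded to one decimal.  A zero
#' baseline is flagged with `NA` instead of a value.
#'
#' @param before,after `data.frame`s with columns `class`, `metric`,
#'   `value`, covering the same (class, metric) keys.
#' @return `data.frame` with `class`, `metric`, `before`, `after`,
#'   `improvement_pct`.
#' @export
attention_improvement_table <- function(before, after) {
  need <- c("class", "metric", "value")
  if (!all(need %in% names(before)) || !all(need %in% names(after)))
    stop_invalid("inputs need columns class, metric, value")
  m <- merge(before, after, by = c("class", "metric"),
             suffixes = c("_before", "_after"))
  if (nrow(m) != nrow(before) || nrow(m) != nrow(after))
    stop_invalid("before and after tables must cover the same (class, metric) keys")
  out <- data.frame(class = m$class, metric = m$metric,
                    before = m$value_before, after = m$value_after)
  out$improvement_pct <- ifelse(
    out$before == 0, NA_real_,
    round2(100 * (out$after - out$before) / out$before, 1))
  out
}
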