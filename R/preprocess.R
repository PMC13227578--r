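# Image preprocessing: resizing, min-max normalization, seeded augmentation.
#
# Coordinate convention used throughout: row-major numeric matrices, 0-based
# pixel indices, origin at the top-left, pixel centers at integer coordinates.

# Reflect an arbitrary real coordinate into [0, n-1] (mirror padding without
# repeating the border sample, i.e. ... 2 1 0 1 2 ... n-2 n-1 n-2 ...).
reflect_coord <- function(x, n) {
  if (n == 1L) return(rep(0, length(x)))
  period <- 2 * (n - 1)
  x <- abs(x) %% period
  ifelse(x > (n - 1), period - x, x)
}

# Bilinear sampler: look up real-valued source coordinates (r, c), 0-based,
# with reflect padding.  `r` and `c` are equal-length vectors; returns values.
sample_bilinear <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- reflect_coord(r, H)
  c <- reflect_coord(c, W)
  r0 <- floor(r); c0 <- floor(c)
  r1 <- pmin(r0 + 1, H - 1); c1 <- pmin(c0 + 1, W - 1)
  fr <- r - r0; fc <- c - c0
  idx <- function(ri, ci) img[cbind(ri + 1, ci + 1)]
  (1 - fr) * (1 - fc) * idx(r0, c0) +
    (1 - fr) * fc * idx(r0, c1) +
    fr * (1 - fc) * idx(r1, c0) +
    fr * fc * idx(r1, c1)
}

sample_nearest <- function(img, r, c) {
  H <- nrow(img); W <- ncol(img)
  r <- round(reflect_coord(r, H))
  c <- round(reflect_coord(c, W))
  img[cbind(r + 1, c + 1)]
}

#' Resize a grayscale image
#'
#' Resamples an image to a new (height, width) using bilinear interpolation
#' (default) or nearest-neighbour lookup.  Output pixel centers map linearly
#' onto input pixel centers: output index `i` samples input coordinate
#' `i * (H_in - 1) / (H_out - 1)` (the image corners are aligned), so resizing
#' an image to its own shape is the identity.
#'
#' @param img Numeric matrix of intensities.
#' @param target_h,target_w Target dimensions in pixels (>= 1).
#' @param method `"bilinear"` or `"nearest"`.
#' @return A `target_h` x `target_w` numeric matrix.
#' @examples
#' img <- matrix(runif(64), 8, 8)
#' dim(resize_image(img, 4, 4))
#' @export
resize_image <- function(img, target_h, target_w, method = c("bilinear", "nearest")) {
  assert_image(img)
  method <- match.arg(method)
  if (length(target_h) != 1L || length(target_w) != 1L ||
      !is.finite(target_h) || !is.finite(target_w) ||
      target_h < 1 || target_w < 1)
    stop_invalid("target dimensions must be positive integers")
  target_h <- as.integer(target_h); target_w <- as.integer(target_w)
  H <- nrow(img); W <- ncol(img)
  src_r <- if (target_h == 1L) rep((H - 1) / 2, 1L) else
    (0:(target_h - 1)) * (H - 1) / (target_h - 1)
  src_c <- if (target_w == 1L) rep((W - 1) / 2, 1L) else
    (0:(target_w - 1)) * (W - 1) / (target_w - 1)
  rr <- rep(src_r, times = target_w)
  cc <- rep(src_c, each = target_h)
  vals <- if (method == "bilinear") sample_bilinear(img, rr, cc)
          else sample_nearest(img, rr, cc)
  matrix(vals, target_h, target_w)
}

#' Min-max normalize an image to [0, 1]
#'
#' Subtracts the minimum intensity and divides by the intensity range, so the
#' output spans exactly \[0, 1\].  Rank order of pixels is preserved and the
#' operation is idempotent.  Constant images have zero range and are rejected.
#'
#' @param img Numeric matrix of intensities.
#' @return Numeric matrix with `min == 0` and `max == 1`.
#' @export
normalize_image <- function(img) {
  assert_image(img)
  lo <- min(img); hi <- max(img)
  if (hi <= lo)
    stop_degenerate("cannot normalize a constant image (max == min)")
  (img - lo) / (hi - lo)
}

#' Augmentation specification
#'
#' Bundles the augmentation operators applied during training: rotation,
#' horizontal flip, zoom, shift, brightness and contrast scaling.  With
#' `random = TRUE` the rotation angle is drawn uniformly from
#' `[-rotation_deg, +rotation_deg]` and the flip is Bernoulli(`hflip_prob`);
#' with `random = FALSE` the rotation uses the fixed angle and the flip is
#' applied iff `hflip_prob >= 1`, giving a fully deterministic operator.
#'
#' @param rotation_deg Maximum rotation angle theta in degrees.
#' @param hflip_prob Horizontal-flip probability p in \[0, 1\].
#' @param zoom_factor Zoom factor z > 0; the image is resized to
#'   `round(z * dim)` and center-cropped (z > 1) or padded by reflection
#'   (z < 1) back to its original shape.
#' @param shift_x,shift_y Shift in pixels (x: rightwards, y: downwards;
#'   negative `shift_y` moves the content up).  Vacated pixels are filled
#'   with 0.
#' @param brightness Multiplicative brightness factor beta > 0.
#' @param contrast Contrast factor > 0; intensities are scaled about the
#'   image mean: `(x - mean) * contrast + mean`.
#' @param seed Integer seed making the random draws reproducible, or `NULL`.
#' @param random Draw rotation/flip at random (training mode) or apply them
#'   deterministically.
#' @return An object of class `augment_spec`.
#' @export
augment_spec <- function(rotation_deg = 20, hflip_prob = 0.5, zoom_factor = 1.1,
                         shift_x = 10, shift_y = -5, brightness = 1.2,
                         contrast = 1.5, seed = NULL, random = TRUE) {
  if (hflip_prob < 0 || hflip_prob > 1) stop_invalid("hflip_prob must lie in [0, 1]")
  if (zoom_factor <= 0) stop_invalid("zoom_factor must be > 0")
  if (brightness <= 0) stop_invalid("brightness must be > 0")
  if (contrast <= 0) stop_invalid("contrast must be > 0")
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 zoom_factor = zoom_factor, shift_x = shift_x, shift_y = shift_y,
                 brightness = brightness, contrast = contrast,
                 seed = if (is.null(seed)) NULL else as.integer(seed),
                 random = isTRUE(random)),
            class = "augment_spec")
}

rotate_image <- function(img, angle_deg) {
  if (angle_deg == 0) return(img)
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cy <- (H - 1) / 2; cx <- (W - 1) / 2
  out_r <- rep(0:(H - 1), times = W) - cy
  out_c <- rep(0:(W - 1), each = H) - cx
  # inverse mapping: rotate output coordinates by -theta to find the source
  src_r <- cos(th) * out_r + sin(th) * out_c + cy
  src_c <- -sin(th) * out_r + cos(th) * out_c + cx
  matrix(sample_bilinear(img, src_r, src_c), H, W)
}

zoom_image <- function(img, z) {
  if (z == 1) return(img)
  H <- nrow(img); W <- ncol(img)
  ch <- max(1L, as.integer(round(H * z)))
  cw <- max(1L, as.integer(round(W * z)))
  canvas <- resize_image(img, ch, cw)
  if (z >= 1) {
    r0 <- floor((ch - H) / 2); c0 <- floor((cw - W) / 2)
    canvas[(r0 + 1):(r0 + H), (c0 + 1):(c0 + W), drop = FALSE]
  } else {
    # zoom out: resample the small canvas back up (reflect padding inside)
    resize_image(canvas, H, W)
  }
}

shift_image <- function(img, dx, dy) {
  H <- nrow(img); W <- ncol(img)
  out <- matrix(0, H, W)
  src_r <- (0:(H - 1)) - dy
  src_c <- (0:(W - 1)) - dx
  ok_r <- src_r >= 0 & src_r <= H - 1
  ok_c <- src_c >= 0 & src_c <= W - 1
  out[ok_r, ok_c] <- img[src_r[ok_r] + 1, src_c[ok_c] + 1]
  out
}

hflip_image <- function(img) img[, rev(seq_len(ncol(img))), drop = FALSE]

#' Apply a seeded augmentation pipeline to a normalized image
#'
#' Applies, in order: rotation, horizontal flip, zoom (with crop/pad back to
#' the original shape), shift, brightness scaling and contrast scaling.  The
#' output has the same shape as the input and is clipped to \[0, 1\].  Given
#' the same `augment_spec` seed the output is bit-identical across calls.
#'
#' @param img Numeric matrix, normalized to \[0, 1\].
#' @param spec An [augment_spec()].
#' @return Augmented image matrix, same shape, values in \[0, 1\].
#' @export
augment_image <- function(img, spec) {
  assert_normalized(img)
  if (!inherits(spec, "augment_spec")) stop_invalid("spec must be an augment_spec")
  with_seed(spec$seed, {
    angle <- if (spec$random) stats::runif(1, -spec$rotation_deg, spec$rotation_deg)
             else spec$rotation_deg
    do_flip <- if (spec$random) stats::runif(1) < spec$hflip_prob
               else spec$hflip_prob >= 1
    out <- rotate_image(img, angle)
    if (do_flip) out <- hflip_image(out)
    out <- zoom_image(out, spec$zoom_factor)
    out <- shift_image(out, spec$shift_x, spec$shift_y)
    out <- out * spec$brightness
    m <- mean(out)
    out <- (out - m) * spec$contrast + m
    pmin(pmax(out, 0), 1)
  })
}

#' Expand a sample set by augmentation
#'
#' Produces `factor` augmented copies per input sample (the originals are
#' kept), mirroring the 500 -> 2500 training-set expansion used with the
#' default factor of 5 (1 original + 4 augmented copies).
#'
#' @param samples List of samples, each a list with at least `image`.
#' @param spec An [augment_spec()]; its seed (combined with the copy index)
#'   drives the random draws.
#' @param factor Total expansion factor (>= 1).
#' @return List of `factor * length(samples)` samples.
#' @export
augment_samples <- function(samples, spec, factor = 5) {
  if (factor < 1) stop_invalid("factor must be >= 1")
  base_seed <- spec$seed %||% 0L
  out <- vector("list", length(samples) * factor)
  k <- 1L
  for (i in seq_along(samples)) {
    out[[k]] <- samples[[i]]; k <- k + 1L
    for (j in seq_len(factor - 1L)) {
      s2 <- spec
      s2$seed <- as.integer((base_seed + i * 131L + j) %% .Machine$integer.max)
      aug <- samples[[i]]
      aug$image <- augment_image(samples[[i]]$image, s2)
      out[[k]] <- aug; k <- k + 1L
    }
  }
  out
}
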