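# Synthetic ultrasound phantom generator: fan-shaped speckled grayscale
# images with four health classes, a continuous severity score in [0, 3],
# and exact per-image anomaly masks.  A documented stand-in for clinical
# data, not a physical acoustics simulation.

phantom_classes <- c("healthy", "mild", "moderate", "severe")

# Severity bands per class: healthy [0, 0.5), mild [0.5, 1.5),
# moderate [1.5, 2.5), severe [2.5, 3].
severity_band <- function(class) {
  switch(class,
         healthy = c(0, 0.5), mild = c(0.5, 1.5),
         moderate = c(1.5, 2.5), severe = c(2.5, 3),
         stop_invalid("unknown class: ", class))
}

severity_to_class <- function(severity) {
  phantom_classes[findInterval(severity, c(0.5, 1.5, 2.5)) + 1L]
}

#' Phantom specification
#'
#' @param height,width Image size in pixels.
#' @param class One of `"healthy"`, `"mild"`, `"moderate"`, `"severe"`.
#' @param severity Continuous severity in the class band (healthy < 0.5,
#'   mild \[0.5, 1.5), moderate \[1.5, 2.5), severe >= 2.5), or `NULL` to
#'   draw one uniformly from the band.
#' @param speckle_sigma Rayleigh scale of the multiplicative speckle; the
#'   default `sqrt(2/pi)` gives the speckle unit mean.
#' @param fan_angle_deg Full opening angle of the imaging sector.
#' @param flat_tissue Replace the smooth tissue texture by a constant (used
#'   to expose the raw speckle distribution).
#' @param normalize Min-max normalize the final image to \[0, 1\].
#' @param seed Integer seed; fully determines the output.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(height = 128L, width = 128L, class = "healthy",
                         severity = NULL, speckle_sigma = sqrt(2 / pi),
                         fan_angle_deg = 60, flat_tissue = FALSE,
                         normalize = TRUE, seed = 1L) {
  class <- match.arg(class, phantom_classes)
  if (!is.null(severity)) {
    band <- severity_band(class)
    if (severity < band[1] || (class != "severe" && severity >= band[2]) ||
        severity > 3)
      stop_invalid("severity ", severity, " is outside the ", class,
                   " band [", band[1], ", ", band[2], ")")
  }
  if (height < 8L || width < 8L) stop_invalid("phantom must be at least 8x8")
  structure(list(height = as.integer(height), width = as.integer(width),
                 class = class, severity = severity,
                 speckle_sigma = speckle_sigma,
                 fan_angle_deg = fan_angle_deg,
                 flat_tissue = isTRUE(flat_tissue),
                 normalize = isTRUE(normalize), seed = as.integer(seed)),
            class = "phantom_spec")
}

# Boolean sector mask: apex slightly above the top edge at the image
# mid-line, opening downward.
fan_mask <- function(H, W, angle_deg) {
  apex_r <- -0.05 * H
  apex_c <- (W - 1) / 2
  dr <- row(matrix(0, H, W)) - 1 - apex_r
  dc <- col(matrix(0, H, W)) - 1 - apex_c
  radius <- sqrt(dr^2 + dc^2)
  theta <- atan2(dc, dr)              # 0 points straight down
  abs(theta) <= (angle_deg / 2) * pi / 180 &
    radius >= 0.10 * H & radius <= 1.08 * H
}

# Smooth tissue texture: low-resolution uniform noise upsampled bilinearly.
smooth_field <- function(H, W, cells = 8L) {
  g <- matrix(stats::runif((cells + 2L)^2), cells + 2L, cells + 2L)
  resize_image(g, H, W)
}

ellipse_mask <- function(H, W, ctr_r, ctr_c, a, b, phi) {
  dr <- row(matrix(0, H, W)) - 1 - ctr_r
  dc <- col(matrix(0, H, W)) - 1 - ctr_c
  u <- dr * cos(phi) + dc * sin(phi)
  v <- -dr * sin(phi) + dc * cos(phi)
  (u / a)^2 + (v / b)^2 <= 1
}

#' Generate one ultrasound phantom
#'
#' The image is a smooth tissue texture multiplied by Rayleigh-distributed
#' speckle, masked to a fan-shaped sector.  Non-healthy classes add 1-3
#' hypoechoic (dark) elliptical lesions whose number, area and contrast all
#' increase monotonically with severity; the returned mask marks lesion
#' pixels exactly.  Healthy phantoms have an empty mask and severity drawn
#' in \[0, 0.5).  The same spec (same seed) reproduces the output
#' bit-for-bit.
#'
#' @param spec A [phantom_spec()].
#' @return List (class `phantom_sample`) with `image` (H x W in \[0, 1\]),
#'   `mask` (logical H x W), `class`, `class_index` (0-based), `severity`
#'   and `spec`.
#' @export
generate_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stop_invalid("spec must be a phantom_spec")
  H <- spec$height; W <- spec$width
  with_seed(spec$seed, {
    severity <- spec$severity
    if (is.null(severity)) {
      band <- severity_band(spec$class)
      severity <- stats::runif(1, band[1], band[2] - 1e-9)
    }
    tissue <- if (spec$flat_tissue) matrix(0.5, H, W)
              else 0.35 + 0.4 * smooth_field(H, W)
    speckle <- matrix(spec$speckle_sigma * sqrt(-2 * log(stats::runif(H * W))),
                      H, W)
    img <- tissue * speckle
    fan <- fan_mask(H, W, spec$fan_angle_deg)
    mask <- matrix(FALSE, H, W)
    if (spec$class != "healthy") {
      n_lesions <- min(3L, 1L + as.integer(floor(severity / 1.2)))
      rad_base <- min(H, W) * (0.05 + 0.08 * severity / 3)
      contrast <- 0.35 + 0.5 * severity / 3
      inside <- which(fan & row(fan) > 0.25 * H & row(fan) < 0.9 * H)
      for (k in seq_len(n_lesions)) {
        ctr <- inside[sample.int(length(inside), 1L)]
        ctr_r <- (ctr - 1L) %% H
        ctr_c <- (ctr - 1L) %/% H
        a <- rad_base * stats::runif(1, 0.8, 1.2)
        b <- rad_base * stats::runif(1, 0.8, 1.2)
        phi <- stats::runif(1, 0, pi)
        les <- ellipse_mask(H, W, ctr_r, ctr_c, a, b, phi) & fan
        img[les] <- img[les] * (1 - contrast)
        mask <- mask | les
      }
    }
    img[!fan] <- 0
    if (spec$normalize) img <- normalize_image(img)
    structure(list(image = img, mask = mask, class = spec$class,
                   class_index = match(spec$class, phantom_classes) - 1L,
                   severity = severity, spec = spec),
              class = "phantom_sample")
  })
}

#' Generate a phantom dataset with a manifest
#'
#' Draws `n` phantoms with the requested class mix (largest-remainder
#' rounding), assigns stratified train/val/test split tags, and, when `dir`
#' is given, writes images and masks as PNG plus a `manifest.csv` and a JSON
#' sidecar echoing the generation parameters.  With `dir = NULL` everything
#' stays in memory.
#'
#' @param n Number of phantoms (default 500).
#' @param class_proportions Named or positional proportions over
#'   healthy/mild/moderate/severe; must sum to 1.
#' @param seed Master seed; per-image seeds are derived from it.
#' @param height,width Phantom size in pixels.
#' @param split_fracs Proportions for the train/val/test tags.
#' @param dir Output directory, or `NULL` to skip writing.
#' @return List with `manifest` (`data.frame`: path, class, class_index,
#'   severity, mask_path, split) and `samples` (list of `phantom_sample`).
#' @export
generate_dataset <- function(n = 500L,
                             class_proportions = c(healthy = 0.25, mild = 0.25,
                                                   moderate = 0.25, severe = 0.25),
                             seed = 1L, height = 128L, width = 128L,
                             split_fracs = c(train = 0.7, val = 0.15, test = 0.15),
                             dir = NULL) {
  if (abs(sum(class_proportions) - 1) > 1e-8)
    stop_invalid("class_proportions must sum to 1")
  if (abs(sum(split_fracs) - 1) > 1e-8)
    stop_invalid("split_fracs must sum to 1")
  # largest-remainder apportionment of n over the four classes
  raw <- n * class_proportions
  counts <- floor(raw)
  rem <- n - sum(counts)
  if (rem > 0) {
    extra <- order(raw - counts, decreasing = TRUE)[seq_len(rem)]
    counts[extra] <- counts[extra] + 1L
  }
  classes <- rep(phantom_classes, times = counts)
  seeds <- with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
  samples <- vector("list", n)
  split <- character(n)
  for (cl in phantom_classes) {
    idx <- which(classes == cl)
    k <- length(idx)
    if (k == 0L) next
    n_tr <- round(split_fracs[[1]] * k)
    n_va <- round(split_fracs[[2]] * k)
    tags <- c(rep("train", n_tr), rep("val", n_va),
              rep("test", k - n_tr - n_va))
    split[idx] <- tags[seq_len(k)]
  }
  for (i in seq_len(n)) {
    samples[[i]] <- generate_phantom(phantom_spec(
      height = height, width = width, class = classes[i], seed = seeds[i]))
  }
  manifest <- data.frame(
    path = sprintf("img_%04d.png", seq_len(n)),
    class = classes,
    class_index = match(classes, phantom_classes) - 1L,
    severity = vapply(samples, `[[`, numeric(1), "severity"),
    mask_path = ifelse(classes == "healthy", "",
                       sprintf("mask_%04d.png", seq_len(n))),
    split = split, stringsAsFactors = FALSE)
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir)
    for (i in seq_len(n)) {
      write_gray_image(samples[[i]]$image, file.path(dir, manifest$path[i]))
      if (manifest$mask_path[i] != "")
        write_gray_image(samples[[i]]$mask * 1, file.path(dir, manifest$mask_path[i]))
    }
    write_manifest(manifest, file.path(dir, "manifest.csv"))
    jsonlite::write_json(
      list(n = n, class_proportions = as.list(class_proportions),
           seed = seed, height = height, width = width,
           split_fracs = as.list(split_fracs)),
      file.path(dir, "generation.json"), auto_unbox = TRUE, pretty = TRUE)
  }
  list(manifest = manifest, samples = samples)
}

#' Plant a synthetic attention target on a sample
#'
#' Builds an attention map whose mass concentrates on the sample's lesion
#' mask by a known analytic rule: unnormalized weight `exp(sharpness)` on
#' mask pixels and 1 elsewhere, normalized to unit total energy.  With
#' `sharpness = 0` the map is uniform (so the energy wasted outside the
#' region is exactly `100 * (1 - |R| / (H W))`); as `sharpness` grows the
#' wasted energy tends to 0 and the focus ratio to 100.  An empty mask
#' yields the uniform map.
#'
#' @param sample A `phantom_sample` (or any list with `mask`).
#' @param sharpness Non-negative concentration parameter.
#' @return H x W attention map summing to 1.
#' @export
plant_attention_target <- function(sample, sharpness = 5) {
  mask <- as_mask_matrix(sample$mask %||% sample)
  w <- matrix(1, nrow(mask), ncol(mask))
  w[mask] <- exp(sharpness)
  w / sum(w)
}

#' Convert phantom samples to plain model samples
#'
#' @param samples List of `phantom_sample`s.
#' @param binary_severe Relabel as a 2-class healthy-vs-severe problem
#'   (classes 0/1); other classes are rejected.
#' @return List of lists with `image`, `class` (0-based), `severity`, `mask`.
#' @export
as_model_samples <- function(samples, binary_severe = FALSE) {
  lapply(samples, function(s) {
    cls <- s$class_index
    if (binary_severe) {
      if (!s$class %in% c("healthy", "severe"))
        stop_invalid("binary_severe mode expects only healthy/severe samples")
      cls <- if (s$class == "severe") 1L else 0L
    }
    list(image = s$image, class = cls, severity = s$severity, mask = s$mask)
  })
}
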