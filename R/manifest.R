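# Dataset manifest: CSV with one row per sample.

manifest_columns <- c("path", "class", "class_index", "severity",
                      "mask_path", "split")

#' Read a dataset manifest
#'
#' Expects a CSV with header columns `path`, `class`, `class_index`,
#' `severity`, `mask_path`, `split`.  `severity` is parsed as a real number
#' and class indices are 0-based.  An empty `mask_path` marks a sample
#' without an annotation (attention metrics are skipped for it).
#'
#' @param path Path to `manifest.csv`.
#' @return `data.frame` with the manifest columns.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(manifest_columns, names(df))
  if (length(missing))
    stop("manifest is missing column(s): ", paste(missing, collapse = ", "))
  df$severity <- as.numeric(df$severity)
  df$class_index <- as.integer(df$class_index)
  df$mask_path <- as.character(df$mask_path)
  df$mask_path[is.na(df$mask_path)] <- ""
  df[manifest_columns]
}

#' Write a dataset manifest
#'
#' @param manifest `data.frame` with the manifest columns.
#' @param path Destination CSV path.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  missing <- setdiff(manifest_columns, names(manifest))
  if (length(missing))
    stop_invalid("manifest is missing column(s): ", paste(missing, collapse = ", "))
  utils::write.csv(manifest[manifest_columns], path, row.names = FALSE)
  invisible(path)
}

#' Load the samples referenced by a manifest
#'
#' Reads each image (and mask, when present) relative to `base_dir`.
#'
#' @param manifest Manifest `data.frame` (from [read_manifest()]).
#' @param base_dir Directory that `path`/`mask_path` are relative to.
#' @param split Optional split tag filter (`"train"`, `"val"`, `"test"`).
#' @return List of samples (`image`, `class` 0-based, `severity`, `mask` or
#'   `NULL`).
#' @export
load_samples <- function(manifest, base_dir = ".", split = NULL) {
  if (!is.null(split)) manifest <- manifest[manifest$split %in% split, ]
  lapply(seq_len(nrow(manifest)), function(i) {
    row <- manifest[i, ]
    img_path <- file.path(base_dir, row$path)
    if (!file.exists(img_path))
      stop("manifest row ", i, ": image not found: ", img_path)
    mask <- NULL
    if (nzchar(row$mask_path)) {
      mp <- file.path(base_dir, row$mask_path)
      if (!file.exists(mp)) stop("manifest row ", i, ": mask not found: ", mp)
      mask <- read_gray_image(mp) > 0.5
    }
    list(image = read_gray_image(img_path),
         class = as.integer(row$class_index),
         severity = as.numeric(row$severity), mask = mask)
  })
}
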