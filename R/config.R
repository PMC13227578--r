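# Run configuration: defaults, schema validation, YAML/JSON round trip.

#' Default run configuration
#'
#' All tunables of the pipeline in one named list: model geometry, loss
#' weight, optimizer, early stopping, augmentation operators, phantom
#' generation and attention-metric options.  See the methods vignette for
#' the rationale behind each default.
#'
#' @return Named list of class `run_config`.
#' @export
default_config <- function() {
  structure(list(
    image_height = 224L, image_width = 224L,
    patch_size = 16L, embed_dim = 64L, depth = 4L, heads = 4L,
    n_classes = 3L, mlp_mult = 4L,
    pos_encoding = "1d", cross_attention = FALSE, cross_source = 1L,
    attention = "standard",
    lambda = 0.5, learning_rate = 1e-3, weight_decay = 1e-4,
    batch_size = 16L, max_epochs = 50L, patience = 5L, min_delta = 1e-4,
    val_fraction = 0.2, seed = 1L,
    severity_min = 0, severity_max = 3,
    afr_quantile = 0.9, overlay_alpha = 0.5,
    augment = list(rotation_deg = 20, hflip_prob = 0.5, zoom_factor = 1.1,
                   shift_x = 10, shift_y = -5, brightness = 1.2,
                   contrast = 1.5, expansion_factor = 5L),
    phantom = list(n = 500L, height = 128L, width = 128L,
                   proportions = list(healthy = 0.25, mild = 0.25,
                                      moderate = 0.25, severe = 0.25))
  ), class = "run_config")
}

config_check <- function(cond, key, msg) {
  if (!cond) stop(structure(
    class = c("fetalvit_config_error", "error", "condition"),
    list(message = sprintf("config key '%s': %s", key, msg), call = NULL)))
}

#' Validate (and complete) a run configuration
#'
#' Fills missing keys with defaults, rejects unknown keys, and checks types
#' and ranges; errors name the offending key.
#'
#' @param config Named list of overrides (possibly partial).
#' @return Complete validated `run_config`.
#' @export
validate_config <- function(config = list()) {
  def <- default_config()
  config <- unclass(config)
  unknown <- setdiff(names(config), names(def))
  config_check(length(unknown) == 0, paste(unknown, collapse = ", "),
               "unknown key")
  for (sub in c("augment", "phantom")) {
    if (!is.null(config[[sub]])) {
      bad <- setdiff(names(config[[sub]]), names(def[[sub]]))
      config_check(length(bad) == 0,
                   paste0(sub, ".", paste(bad, collapse = ", ")), "unknown key")
      def[[sub]][names(config[[sub]])] <- config[[sub]]
    }
  }
  flat <- setdiff(names(config), c("augment", "phantom"))
  def[flat] <- config[flat]
  cfg <- def
  num1 <- function(key, lo = -Inf, hi = Inf, integer = FALSE) {
    v <- cfg[[key]]
    config_check(is.numeric(v) && length(v) == 1L && is.finite(v), key,
                 "must be a single finite number")
    config_check(v >= lo && v <= hi, key,
                 sprintf("must lie in [%s, %s]", lo, hi))
    # normalize storage type so save/load round trips are exact
    cfg[[key]] <<- if (integer) as.integer(v) else as.numeric(v)
  }
  num1("image_height", 1, Inf, TRUE); num1("image_width", 1, Inf, TRUE)
  num1("patch_size", 1, Inf, TRUE); num1("embed_dim", 2, Inf, TRUE)
  num1("depth", 0, Inf, TRUE); num1("heads", 1, Inf, TRUE)
  num1("n_classes", 2, Inf, TRUE); num1("mlp_mult", 1, Inf, TRUE)
  num1("cross_source", 1, Inf, TRUE)
  num1("lambda", 0); num1("learning_rate", 1e-12)
  num1("weight_decay", 0); num1("batch_size", 1, Inf, TRUE)
  num1("max_epochs", 1, Inf, TRUE); num1("patience", 1, Inf, TRUE)
  num1("min_delta", 0); num1("val_fraction", 0, 0.95); num1("seed", 0, 2^31 - 1, TRUE)
  num1("severity_min"); num1("severity_max")
  num1("afr_quantile", 0, 1); num1("overlay_alpha", 0, 1)
  config_check(cfg$severity_max > cfg$severity_min, "severity_max",
               "must exceed severity_min")
  config_check(cfg$image_height %% cfg$patch_size == 0 &&
                 cfg$image_width %% cfg$patch_size == 0, "patch_size",
               "must divide image_height and image_width")
  config_check(cfg$embed_dim %% cfg$heads == 0, "embed_dim",
               "must be divisible by heads")
  config_check(cfg$pos_encoding %in% c("1d", "2d", "none"), "pos_encoding",
               "must be one of 1d/2d/none")
  config_check(is.logical(cfg$cross_attention) || cfg$cross_attention %in% c(0, 1),
               "cross_attention", "must be logical")
  cfg$cross_attention <- as.logical(cfg$cross_attention)
  config_check(cfg$attention %in% c("standard", "identity"), "attention",
               "must be standard or identity")
  for (k in c("rotation_deg", "hflip_prob", "zoom_factor", "shift_x",
              "shift_y", "brightness", "contrast"))
    cfg$augment[[k]] <- as.numeric(cfg$augment[[k]])
  cfg$augment$expansion_factor <- as.integer(cfg$augment$expansion_factor)
  cfg$phantom$n <- as.integer(cfg$phantom$n)
  cfg$phantom$height <- as.integer(cfg$phantom$height)
  cfg$phantom$width <- as.integer(cfg$phantom$width)
  cfg$phantom$proportions <- lapply(cfg$phantom$proportions, as.numeric)
  a <- cfg$augment
  config_check(a$hflip_prob >= 0 && a$hflip_prob <= 1, "augment.hflip_prob",
               "must lie in [0, 1]")
  config_check(a$zoom_factor > 0, "augment.zoom_factor", "must be > 0")
  config_check(a$brightness > 0, "augment.brightness", "must be > 0")
  config_check(a$contrast > 0, "augment.contrast", "must be > 0")
  config_check(a$expansion_factor >= 1, "augment.expansion_factor",
               "must be >= 1")
  p <- cfg$phantom
  config_check(p$n >= 1, "phantom.n", "must be >= 1")
  config_check(abs(sum(unlist(p$proportions)) - 1) < 1e-6,
               "phantom.proportions", "must sum to 1")
  class(cfg) <- "run_config"
  cfg
}

#' Load a run configuration from YAML or JSON
#'
#' Missing keys take their defaults; unknown keys, type mismatches and
#' out-of-range values raise a config error naming the key.  An empty file
#' yields the full default configuration.
#'
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return Validated `run_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  raw <- if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
         else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
         else stop("config must be .yaml/.yml or .json, got .", ext)
  validate_config(raw %||% list())
}

#' Save a run configuration to YAML or JSON
#'
#' `load_config(save_config(cfg, path))` round-trips exactly.
#'
#' @param config A (validated) `run_config`.
#' @param path Destination path ending in `.yaml`/`.yml` or `.json`.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  config <- validate_config(config)
  ext <- tolower(tools::file_ext(path))
  x <- unclass(config)
  if (ext %in% c("yaml", "yml")) yaml::write_yaml(x, path)
  else if (ext == "json")
    jsonlite::write_json(x, path, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  else stop("config must be .yaml/.yml or .json, got .", ext)
  invisible(path)
}
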