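# Model checkpointing: named-array archive (RDS) + JSON config sidecar.

#' Save model parameters and configuration
#'
#' Writes the parameter arrays to `<path>` (RDS, bit-exact on reload) and
#' the run configuration to `<path>.json` so a checkpoint is
#' self-describing.  No executable state is stored.
#'
#' @param params `vit_params`.
#' @param config The run (or model) configuration used to build them.
#' @param path Destination path (conventionally `checkpoint.rds`).
#' @return `path`, invisibly.
#' @export
save_checkpoint <- function(params, config, path) {
  saveRDS(unclass(params), path)
  jsonlite::write_json(unclass(config), paste0(path, ".json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a checkpoint
#'
#' @param path Path given to [save_checkpoint()].
#' @return List with `params` (bit-identical to what was saved) and
#'   `config`.
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  params <- structure(readRDS(path), class = "vit_params")
  sidecar <- paste0(path, ".json")
  config <- if (file.exists(sidecar))
    jsonlite::read_json(sidecar, simplifyVector = TRUE) else NULL
  list(params = params, config = config)
}
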