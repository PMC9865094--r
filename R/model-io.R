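#' Save a trained model to a single-file archive
#'
#' Serializes the spec, fitted weights and normalization statistics into
#' one file so training and evaluation can run as separate stages.
#'
#' @param model A trained `gait_model`.
#' @param path Output file path.
#' @return The path, invisibly.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "gait_model"))
  saveRDS(model, path, version = 2)
  invisible(path)
}

#' Load a model archive written by [save_model()]
#'
#' @param path File path.
#' @return The `gait_model`.
#' @export
load_model <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  model <- readRDS(path)
  if (!inherits(model, "gait_model"))
    stop("not a gait model archive: ", path, call. = FALSE)
  model
}
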