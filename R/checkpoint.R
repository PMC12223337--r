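#' Save / load model checkpoints
#'
#' Checkpoints are versioned serialized files embedding the architecture
#' spec, the preprocessing configuration and all parameters (including
#' batch-norm running statistics), so a loaded model classifies images
#' without further context.
#'
#' @param model a `tv_model`.
#' @param path checkpoint file path.
#' @return `path` (invisibly) for `save_checkpoint`; the model for
#'   `load_checkpoint`.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "tv_model"))
  obj <- list(format = "trichovision_checkpoint", version = 1L, model = model)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "trichovision_checkpoint")) {
    stop("not a trichovision checkpoint: ", path)
  }
  if (obj$version > 1L) {
    stop("checkpoint version ", obj$version, " is newer than this package")
  }
  obj$model
}
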