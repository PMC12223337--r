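#' Preprocessing configuration
#'
#' Images are rescaled with bicubic (Catmull-Rom) interpolation before
#' entering a classifier.  The whole-image classifiers use per-axis factors
#' (0.25 for the basic CNN: 4096 x 1710 -> 1024 x 428; 0.125 for the DLA:
#' -> 512 x 214); the patch classifier uses a fixed 256 x 256 target.
#' Target sizes derived from a factor use round-half-away-from-zero
#' (1710 * 0.25 = 427.5 -> 428).
#'
#' @param rescale_factor per-axis scale factor, used when `target_size` is
#'   `NULL`.
#' @param target_size exact output `c(width, height)`, overriding the
#'   factor.
#' @param interpolation only `"bicubic"` is supported.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(rescale_factor = 0.25, target_size = NULL,
                              interpolation = "bicubic") {
  interpolation <- match.arg(interpolation, "bicubic")
  if (is.null(target_size) && (!is.numeric(rescale_factor) || rescale_factor <= 0)) {
    stop("rescale_factor must be positive")
  }
  structure(list(rescale_factor = rescale_factor,
                 target_size = if (is.null(target_size)) NULL else as.integer(target_size),
                 interpolation = interpolation),
            class = "preprocess_config")
}

#' Rescale an image for a classifier
#'
#' Bicubic resampling to `config$target_size` when set, otherwise to
#' `round_half_away(original size * rescale_factor)` per axis.  Channel
#' values are clamped to \[0,1\].
#'
#' @param image numeric array (H, W, 3) or matrix (expanded to 3 channels)
#'   with values in \[0,1\].
#' @param config a [preprocess_config()].
#' @return numeric array (out_h, out_w, 3).
#' @export
preprocess <- function(image, config = preprocess_config()) {
  if (is.matrix(image)) image <- array(rep(image, 3), c(dim(image), 3))
  d <- dim(image)
  if (length(d) != 3 || any(d[1:2] < 1)) stop("image must be a nonempty (H, W, C) array")
  if (is.null(config$target_size)) {
    out_w <- as.integer(round_half_away(d[2] * config$rescale_factor))
    out_h <- as.integer(round_half_away(d[1] * config$rescale_factor))
  } else {
    out_w <- config$target_size[1]; out_h <- config$target_size[2]
  }
  if (out_w < 1 || out_h < 1) stop("rescaled size collapses to zero")
  out <- if (out_h == d[1] && out_w == d[2]) image else
    cv_resize_bicubic(image, out_h, out_w)
  out[out < 0] <- 0; out[out > 1] <- 1
  out
}
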