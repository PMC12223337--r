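#' Cascade configuration
#'
#' The composite method resolves an image through up to three stages.
#' Two-stage: a detector decides; if it finds nothing, a whole-image
#' classifier decides.  Three-stage: a high-threshold detector decides; if
#' it finds nothing, a lower-threshold detector proposes boxes whose
#' patches are classified and aggregated; if that also finds nothing, the
#' whole-image classifier decides.  A cascade never returns
#' `"no_detection"`.
#'
#' @param strategy `"two_stage"` or `"three_stage"`.
#' @param stage1 [detector_config()] for the first stage.
#' @param stage2 lower-threshold [detector_config()] (three-stage only);
#'   defaults to `stage1` with half its confidence threshold.
#' @param patch_size side of the square patch cropped around each stage-2
#'   detection (default 512).
#' @param whole_image_classifier a `tv_model` (or a `function(image)`
#'   returning a [classify()]-style list).
#' @param patch_classifier classifier applied to cropped patches
#'   (three-stage only); its preprocessing rescales patches to its input
#'   size (256 x 256 for the default patch protocol).
#' @param aggregation `"majority_vote"` (optionally confidence-weighted via
#'   `weighted = TRUE`).
#' @param weighted weight patch votes by their class probability.
#' @return an object of class `cascade_config`.
#' @export
cascade_config <- function(strategy = c("two_stage", "three_stage"),
                           stage1 = detector_config("classical"),
                           stage2 = NULL,
                           patch_size = 512L,
                           whole_image_classifier = NULL,
                           patch_classifier = NULL,
                           aggregation = "majority_vote",
                           weighted = FALSE) {
  strategy <- match.arg(strategy)
  stopifnot(patch_size > 0)
  if (strategy == "three_stage") {
    if (is.null(stage2)) {
      stage2 <- stage1
      stage2$confidence_threshold <- stage1$confidence_threshold / 2
    }
    if (stage2$confidence_threshold >= stage1$confidence_threshold) {
      stop("stage2 threshold must be lower than stage1 threshold")
    }
  }
  structure(list(strategy = strategy, stage1 = stage1, stage2 = stage2,
                 patch_size = as.integer(patch_size),
                 whole_image_classifier = whole_image_classifier,
                 patch_classifier = patch_classifier,
                 aggregation = match.arg(aggregation, "majority_vote"),
                 weighted = weighted),
            class = "cascade_config")
}

#' Pixel window of a patch centered on a detection
#'
#' Pure geometry: the `patch_size` window centered on `(cx, cy)` (0-based
#' pixels), shifted minimally so it lies fully inside a `width` x `height`
#' frame.  Requires the frame to be at least `patch_size` in each
#' dimension.
#'
#' @param cx,cy patch center in pixels (vectors allowed).
#' @param width,height frame size.
#' @param patch_size window side.
#' @return matrix with columns `x0`, `y0` (inclusive 0-based start) and
#'   `x1`, `y1` (exclusive end); `x1 - x0 == y1 - y0 == patch_size`.
#' @export
patch_window <- function(cx, cy, width, height, patch_size = 512L) {
  if (width < patch_size || height < patch_size) {
    stop("frame smaller than patch_size", call. = FALSE)
  }
  half <- patch_size / 2
  x0 <- pmin(pmax(round_half_away(cx - half), 0), width - patch_size)
  y0 <- pmin(pmax(round_half_away(cy - half), 0), height - patch_size)
  cbind(x0 = x0, y0 = y0, x1 = x0 + patch_size, y1 = y0 + patch_size)
}

#' Crop a fixed-size patch centered on a detection
#'
#' Crops the `patch_size` square centered on the detection's box center,
#' shifted minimally to stay inside the frame.  If the image is smaller
#' than `patch_size` in a dimension, it is first padded symmetrically by
#' edge replication (with a warning).
#'
#' @param image numeric array (H, W, 3).
#' @param det one detection row (or any list with the pixel box fields).
#' @param patch_size output side length (default 512).
#' @return numeric array `(patch_size, patch_size, 3)`.
#' @export
crop_patch <- function(image, det, patch_size = 512L) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (H < patch_size || W < patch_size) {
    warning("image smaller than patch_size; padding by edge replication")
    pad_h <- max(0, patch_size - H)
    pad_w <- max(0, patch_size - W)
    top <- pad_h %/% 2; left <- pad_w %/% 2
    ri <- pmin(pmax(seq_len(H + pad_h) - top, 1), H)
    ci <- pmin(pmax(seq_len(W + pad_w) - left, 1), W)
    image <- image[ri, ci, , drop = FALSE]
    d <- dim(image); H <- d[1]; W <- d[2]
  }
  cx <- (det$x_min + det$x_max) / 2
  cy <- (det$y_min + det$y_max) / 2
  win <- patch_window(cx, cy, W, H, patch_size)
  image[(win[1, "y0"] + 1):win[1, "y1"], (win[1, "x0"] + 1):win[1, "x1"], ,
        drop = FALSE]
}

#' Build a patch dataset from low-threshold detections
#'
#' Runs the (deliberately low-threshold) detector over each record's image
#' and crops one patch per detection.  Every patch inherits the
#' ground-truth label of its source image — not the detection's own class
#' label — mirroring how patch-classifier training data is labeled when
#' only image-level ground truth is chemically verified.  Overlapping
#' detections of the same hair are kept as duplicates.
#'
#' @param records list of [image_record()]s.
#' @param detector a [detector_config()].
#' @param patch_size patch side length.
#' @param images optional named list of in-memory images keyed by image id.
#' @return list of patch records: each a list with `source_image_id`,
#'   `patch` (array) and `gt_label`.
#' @export
build_patch_dataset <- function(records, detector, patch_size = 512L,
                                images = NULL) {
  out <- list()
  for (rec in records) {
    img <- if (!is.null(images)) images[[rec$image_id]] else load_image(rec)
    dets <- detect(img, detector, rec)
    for (i in seq_len(nrow(dets))) {
      out[[length(out) + 1L]] <- list(
        source_image_id = rec$image_id,
        patch = crop_patch(img, dets[i, ], patch_size),
        gt_label = rec$gt_label)
    }
  }
  out
}

#' Aggregate patch-classifier predictions into one label
#'
#' Unweighted majority vote over predicted labels; a vote tie goes to the
#' class with the higher mean probability; a further tie goes to `"real"`.
#' With `weighted = TRUE` each vote counts its class probability instead
#' of 1.
#'
#' @param outputs a list of [classify()] outputs, or a `data.frame` with
#'   columns `real`, `fake`, `predicted_label`.
#' @param weighted confidence-weighted voting.
#' @return `"real"` or `"fake"`.
#' @export
aggregate_patch_predictions <- function(outputs, weighted = FALSE) {
  if (is.data.frame(outputs)) {
    probs <- as.matrix(outputs[, CLASS_LEVELS])
    labels <- outputs$predicted_label
  } else {
    if (length(outputs) == 0) stop("cannot aggregate an empty prediction list")
    probs <- do.call(rbind, lapply(outputs, function(o) o$probabilities[CLASS_LEVELS]))
    labels <- vapply(outputs, function(o) o$predicted_label, character(1))
  }
  if (nrow(probs) == 0) stop("cannot aggregate an empty prediction list")
  votes <- if (weighted) {
    c(real = sum(probs[labels == "real", "real"]),
      fake = sum(probs[labels == "fake", "fake"]))
  } else {
    c(real = sum(labels == "real"), fake = sum(labels == "fake"))
  }
  if (votes["real"] != votes["fake"]) {
    return(names(votes)[which.max(votes)])
  }
  means <- colMeans(probs)
  if (means["real"] >= means["fake"]) "real" else "fake"
}

run_classifier_ref <- function(clf, image) {
  if (is.function(clf)) clf(image) else classify(clf, image)
}

#' Run the composite cascade on one image
#'
#' Applies the configured strategy (see [cascade_config()]).  The result
#' always carries a class label: the whole-image classifier backstops every
#' path, so `"no_detection"` cannot leak out.
#'
#' @param image numeric array (H, W, 3).
#' @param config a [cascade_config()].
#' @param record optional [image_record()] (required by the mock detector
#'   backend).
#' @return list with `label`, `deciding_stage` (`"detector"`,
#'   `"patch_classifier"` or `"whole_image"`), and `n_detections` at the
#'   deciding stage.
#' @export
run_cascade <- function(image, config, record = NULL) {
  d1 <- detect(image, config$stage1, record)
  if (nrow(d1) > 0) {
    dec <- decide_from_detections(d1)
    return(list(label = dec$label, deciding_stage = "detector",
                n_detections = nrow(d1)))
  }
  if (config$strategy == "three_stage") {
    d2 <- detect(image, config$stage2, record)
    if (nrow(d2) > 0) {
      if (is.null(config$patch_classifier)) {
        stop("three-stage cascade reached stage 3 but no patch classifier is configured")
      }
      outs <- lapply(seq_len(nrow(d2)), function(i) {
        run_classifier_ref(config$patch_classifier,
                           crop_patch(image, d2[i, ], config$patch_size))
      })
      return(list(label = aggregate_patch_predictions(outs,
                                                      weighted = config$weighted),
                  deciding_stage = "patch_classifier",
                  n_detections = nrow(d2)))
    }
  }
  if (is.null(config$whole_image_classifier)) {
    stop("cascade reached the whole-image stage but no classifier is configured")
  }
  out <- run_classifier_ref(config$whole_image_classifier, image)
  list(label = out$predicted_label, deciding_stage = "whole_image",
       n_detections = 0L)
}
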