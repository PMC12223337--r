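#' Construct a table of detections
#'
#' A detection is what an object-detector backend emits for one candidate
#' trichome: a pixel bounding box, a class label and a confidence in
#' \[0,1\].
#'
#' @param x_min,y_min,x_max,y_max 0-based pixel box corners
#'   (`x_min < x_max`, `y_min < y_max`).
#' @param class_label `"real"` / `"fake"` per detection.
#' @param confidence detector confidence in \[0,1\].
#' @return a `data.frame` with one row per detection.
#' @export
detection <- function(class_label, confidence, x_min = 0, y_min = 0,
                      x_max = 1, y_max = 1) {
  check_class_label(class_label)
  if (any(confidence < 0 | confidence > 1)) stop("confidence must be in [0, 1]")
  if (any(x_min >= x_max) || any(y_min >= y_max)) {
    stop("detection boxes must have positive area")
  }
  data.frame(class_label = as.character(class_label),
             confidence = as.numeric(confidence),
             x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             stringsAsFactors = FALSE)
}

empty_detections <- function() {
  detection(character(), numeric(), numeric(), numeric(), numeric(),
            numeric())
}

#' Detector backend configuration
#'
#' Backends implement a common contract: given an image they return a
#' detection table, already filtered at `confidence_threshold`.  External
#' YOLO-style and DETR-style detectors are consumed through their result
#' files (they are never trained or run by this package); the `"classical"`
#' backend is a self-contained curvature-based detector for synthetic
#' scenes; the `"mock"` backend perturbs ground-truth boxes and exists for
#' controlled experiments.
#'
#' Default confidence thresholds follow the two detector families: 0.05 for
#' YOLO-style backends and 0.3 for DETR-style backends (0.5 for the
#' classical and mock backends).
#'
#' @param backend one of `"classical"`, `"mock"`, `"external_yolo"`,
#'   `"external_detr"`.
#' @param confidence_threshold minimum retained confidence in \[0,1\].
#' @param options named list of backend options.  Classical:
#'   `curvature_cut` (1/px; real at or above the cut), `margin_scale`,
#'   `min_area`, `min_aspect`.  Mock: `miss_prob`, `flip_prob`,
#'   `jitter_frac`, `conf_range`, `seed`.  External: `results_file` (path),
#'   `image_id`.
#' @return an object of class `detector_config`.
#' @export
detector_config <- function(backend = c("classical", "mock", "external_yolo",
                                        "external_detr"),
                            confidence_threshold = NULL,
                            options = list()) {
  backend <- match.arg(backend)
  if (is.null(confidence_threshold)) {
    confidence_threshold <- switch(backend,
                                   external_yolo = 0.05,
                                   external_detr = 0.3,
                                   0.5)
  }
  if (confidence_threshold < 0 || confidence_threshold > 1) {
    stop("confidence_threshold must be in [0, 1]")
  }
  structure(list(backend = backend,
                 confidence_threshold = confidence_threshold,
                 options = options),
            class = "detector_config")
}

#' Keep detections at or above a confidence threshold
#'
#' Order-preserving subset; idempotent, and monotone in the threshold.
#'
#' @param dets detection `data.frame`.
#' @param threshold minimum confidence.
#' @return filtered detection `data.frame`.
#' @export
filter_by_threshold <- function(dets, threshold) {
  dets[dets$confidence >= threshold, , drop = FALSE]
}

#' Run a detector backend on one image
#'
#' Dispatches on the configured backend and filters the result at the
#' configured confidence threshold.
#'
#' The classical backend grayscales the image, thresholds it (Otsu),
#' extracts connected components, keeps sufficiently large, elongated
#' components, and scores each by an arc-curvature statistic (quadratic fit
#' in the component's principal frame): components whose curvature is at or
#' above `curvature_cut` are labeled `"real"`, the rest `"fake"`, with
#' confidence mapped from the margin to the cut through a logistic.
#'
#' The mock backend requires the ground-truth `record`: each annotated box
#' is dropped with probability `miss_prob`, its label flipped with
#' probability `flip_prob`, corners jittered by `jitter_frac` of the box
#' size, and confidence drawn uniformly from `conf_range` (default
#' `c(0.5, 1)`), optionally under `options$seed`.
#'
#' External backends parse a results listing (one detection per line:
#' `image_id class_label confidence x_min y_min x_max y_max`) and return
#' the rows for `record$image_id` (or `options$image_id`).
#'
#' @param image numeric array (H, W, 3) in \[0,1\] (may be `NULL` for
#'   external backends).
#' @param config a [detector_config()].
#' @param record the image's [image_record()]; required by the mock
#'   backend, used for the image id by external backends.
#' @return detection `data.frame` with `confidence >=
#'   config$confidence_threshold`.
#' @export
detect <- function(image, config, record = NULL) {
  dets <- switch(config$backend,
                 classical = detect_classical(image, config$options),
                 mock = detect_mock(image, config$options, record),
                 external_yolo = ,
                 external_detr = detect_external(config$options, record),
                 stop("unknown detector backend: ", config$backend))
  filter_by_threshold(dets, config$confidence_threshold)
}

detect_classical <- function(image, opts) {
  if (is.null(image)) stop("classical backend needs pixel data")
  gray <- (image[, , 1] + image[, , 2] + image[, , 3]) / 3
  W <- ncol(gray); H <- nrow(gray)
  cut <- opts$curvature_cut %||% (6 / W)
  scale <- opts$margin_scale %||% (2 / W)
  min_area <- opts$min_area %||% max(20, 2.5e-4 * W * H)
  min_aspect <- opts$min_aspect %||% 2.5
  # smooth away pixel noise before thresholding so components are hairs,
  # not speckle
  gray <- cv_gauss_blur(gray, max(1, W / 800))
  th <- EBImage::otsu(gray, range = c(0, 1))
  bw <- gray > th
  if (!any(bw)) return(empty_detections())
  lab <- EBImage::bwlabel(bw)
  n_comp <- max(lab)
  out <- empty_detections()
  for (k in seq_len(n_comp)) {
    idx <- which(lab == k, arr.ind = TRUE)
    if (nrow(idx) < min_area) next
    ys <- idx[, 1] - 1; xs <- idx[, 2] - 1
    ctr <- c(mean(xs), mean(ys))
    cc <- cbind(xs - ctr[1], ys - ctr[2])
    ev <- eigen(crossprod(cc) / nrow(cc), symmetric = TRUE)
    if (ev$values[2] <= 1e-9) next
    aspect <- sqrt(ev$values[1] / ev$values[2])
    if (aspect < min_aspect) next
    # principal-frame coordinates: t along the axis, s across it
    tt <- cc %*% ev$vectors[, 1]
    ss <- cc %*% ev$vectors[, 2]
    if (diff(range(tt)) < 4) next
    fit <- lm(ss ~ tt + I(tt^2))
    curv <- 2 * abs(coef(fit)[3])
    if (is.na(curv)) next
    label <- if (curv >= cut) "real" else "fake"
    # margin-to-cut mapped to [0, 1): zero margin means an uninformative
    # detection with confidence 0
    conf <- 2 * plogis(abs(curv - cut) / scale) - 1
    out <- rbind(out, detection(label, conf,
                                x_min = min(xs), y_min = min(ys),
                                x_max = max(xs) + 1, y_max = max(ys) + 1))
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

detect_mock <- function(image, opts, record) {
  if (is.null(record)) stop("mock backend needs the ground-truth record")
  run <- function() {
    boxes <- record$boxes
    if (nrow(boxes) == 0) return(empty_detections())
    miss <- opts$miss_prob %||% 0
    flip <- opts$flip_prob %||% 0
    jit <- opts$jitter_frac %||% 0.02
    cr <- opts$conf_range %||% c(0.5, 1)
    px <- denormalize_box(boxes, record$width, record$height)
    keep <- runif(nrow(boxes)) >= miss
    flipped <- runif(nrow(boxes)) < flip
    lab <- ifelse(flipped, ifelse(boxes$class_label == "real", "fake", "real"),
                  boxes$class_label)
    conf <- runif(nrow(boxes), cr[1], cr[2])
    jx <- rnorm(nrow(boxes), 0, jit) * (px[, "x_max"] - px[, "x_min"])
    jy <- rnorm(nrow(boxes), 0, jit) * (px[, "y_max"] - px[, "y_min"])
    if (!any(keep)) return(empty_detections())
    x_min <- pmax(0, px[keep, "x_min"] + jx[keep])
    x_max <- pmin(record$width, px[keep, "x_max"] + jx[keep])
    y_min <- pmax(0, px[keep, "y_min"] + jy[keep])
    y_max <- pmin(record$height, px[keep, "y_max"] + jy[keep])
    detection(lab[keep], conf[keep], x_min, y_min,
              pmax(x_max, x_min + 1), pmax(y_max, y_min + 1))
  }
  if (is.null(opts$seed)) run() else with_seed(opts$seed, run())
}

detect_external <- function(opts, record) {
  file <- opts$results_file
  if (is.null(file) || !file.exists(file)) {
    stop("external backend needs a readable options$results_file", call. = FALSE)
  }
  id <- opts$image_id %||% (if (!is.null(record)) record$image_id else NULL)
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  out <- empty_detections()
  for (i in seq_along(lines)) {
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) != 7L) {
      stop(sprintf("results line %d: expected 7 fields, got %d", i,
                   length(toks)), call. = FALSE)
    }
    if (!is.null(id) && toks[1] != id) next
    suppressWarnings(vals <- as.numeric(toks[3:7]))
    if (any(is.na(vals))) {
      stop(sprintf("results line %d: non-numeric field", i), call. = FALSE)
    }
    out <- rbind(out, detection(toks[2], vals[1], vals[2], vals[3], vals[4],
                                vals[5]))
  }
  out
}

#' Decide an image label from its detections
#'
#' The detection-count decision scheme: with no detections the image is
#' `"no_detection"`; otherwise the class with strictly more detections
#' wins; on equal counts the class of the single highest-confidence
#' detection wins.  When both classes tie in count *and* in maximum
#' confidence, the class of the earliest such detection in input order is
#' taken (callers wanting full order-independence should sort detections by
#' confidence descending, then x, then y, beforehand).
#'
#' @param dets detection `data.frame`.
#' @return an object of class `image_decision`: list with `label`
#'   (`"real"`, `"fake"` or `"no_detection"`) and `supporting_detections`.
#' @export
decide_from_detections <- function(dets) {
  if (is.null(dets) || nrow(dets) == 0) {
    return(structure(list(label = "no_detection",
                          supporting_detections = empty_detections()),
                     class = "image_decision"))
  }
  n_real <- sum(dets$class_label == "real")
  n_fake <- sum(dets$class_label == "fake")
  label <- if (n_real > n_fake) {
    "real"
  } else if (n_fake > n_real) {
    "fake"
  } else {
    dets$class_label[which.max(dets$confidence)]
  }
  structure(list(label = label, supporting_detections = dets),
            class = "image_decision")
}

#' @export
print.image_decision <- function(x, ...) {
  cat(sprintf("<image_decision> %s (%d supporting detections)\n",
              x$label, nrow(x$supporting_detections)))
  invisible(x)
}

#' Image-level accuracy of detector decisions
#'
#' Fraction of decisions whose label equals the ground truth;
#' `"no_detection"` never matches and therefore always counts as an error.
#'
#' @param decisions list of [decide_from_detections()] results (or a
#'   character vector of labels).
#' @param gt character vector of ground-truth labels.
#' @return fraction in \[0,1\].
#' @export
detector_image_accuracy <- function(decisions, gt) {
  labels <- if (is.character(decisions)) decisions else
    vapply(decisions, function(d) d$label, character(1))
  if (length(labels) != length(gt)) stop("length mismatch")
  mean(labels == gt)
}

#' IoU-matched per-box detection metrics
#'
#' For synthetic data, where ground-truth boxes exist, detections are
#' matched greedily (by descending confidence) to unmatched ground-truth
#' boxes at IoU >= `iou_min`; a matched detection is a true positive only
#' if its label equals the box label.
#'
#' @param dets detection `data.frame` (pixel boxes).
#' @param record the [image_record()] with ground-truth boxes.
#' @param iou_min minimum intersection-over-union for a match.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`.
#' @export
detection_box_metrics <- function(dets, record, iou_min = 0.5) {
  gt <- record$boxes
  if (nrow(gt) == 0) {
    return(list(tp = 0L, fp = nrow(dets), fn = 0L,
                precision = if (nrow(dets)) 0 else NA_real_, recall = NA_real_))
  }
  gtpx <- denormalize_box(gt, record$width, record$height)
  used <- logical(nrow(gt))
  tp <- 0L
  ord <- order(-dets$confidence)
  for (i in ord) {
    ious <- vapply(seq_len(nrow(gt)), function(j) {
      if (used[j]) return(0)
      box_iou(unlist(dets[i, c("x_min", "y_min", "x_max", "y_max")]),
              gtpx[j, ])
    }, numeric(1))
    j <- which.max(ious)
    if (length(j) && ious[j] >= iou_min) {
      used[j] <- TRUE
      if (dets$class_label[i] == gt$class_label[j]) tp <- tp + 1L
    }
  }
  fp <- nrow(dets) - tp
  fn <- sum(!used)
  list(tp = tp, fp = fp, fn = fn,
       precision = if (nrow(dets)) tp / nrow(dets) else NA_real_,
       recall = tp / nrow(gt))
}

box_iou <- function(a, b) {
  ix <- max(0, min(a[3], b[3]) - max(a[1], b[1]))
  iy <- max(0, min(a[4], b[4]) - max(a[2], b[2]))
  inter <- ix * iy
  ua <- (a[3] - a[1]) * (a[4] - a[2]) + (b[3] - b[1]) * (b[4] - b[2]) - inter
  if (ua <= 0) 0 else inter / ua
}
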