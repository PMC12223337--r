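#' Construct a table of normalized bounding boxes
#'
#' Boxes follow the YOLO annotation convention: a class label plus the box
#' center (`cx`, `cy`) and size (`w`, `h`), all expressed as fractions of the
#' image width/height.  Boxes are stored as given; clamping to the image
#' frame happens only at denormalization, so files that carry slightly
#' out-of-range coordinates round-trip unchanged.
#'
#' @param class_label character vector of `"real"` / `"fake"` labels.
#' @param cx,cy box center as a fraction of image width / height.
#' @param w,h box width / height as a fraction of image width / height
#'   (must be positive).
#' @return a `data.frame` with columns `class_label`, `cx`, `cy`, `w`, `h`.
#' @examples
#' bounding_box("real", 0.5, 0.5, 0.1, 0.2)
#' @export
bounding_box <- function(class_label, cx, cy, w, h) {
  check_class_label(class_label)
  if (any(!is.finite(c(cx, cy, w, h)))) stop("box coordinates must be finite")
  if (any(w <= 0) || any(h <= 0)) stop("box width and height must be positive")
  data.frame(class_label = as.character(class_label),
             cx = as.numeric(cx), cy = as.numeric(cy),
             w = as.numeric(w), h = as.numeric(h),
             stringsAsFactors = FALSE)
}

empty_boxes <- function() {
  data.frame(class_label = character(), cx = numeric(), cy = numeric(),
             w = numeric(), h = numeric(), stringsAsFactors = FALSE)
}

#' Default class index mapping for annotation files
#'
#' Index 0 is the genuine-cannabis ("real") class, index 1 the non-cannabis
#' ("fake") class.
#'
#' @return named integer vector mapping class label to file index.
#' @export
default_label_map <- function() c(real = 0L, fake = 1L)

#' Read a YOLO-format annotation file
#'
#' Each non-empty line holds five whitespace-separated tokens: an integer
#' class index followed by the normalized center and size
#' (`<index> <cx> <cy> <w> <h>`).  Values are parsed as written; nothing is
#' clamped at parse time.
#'
#' @param file path to an annotation file, or a length-1 character string of
#'   annotation text when `text = TRUE`.
#' @param label_map named integer vector mapping class labels to file
#'   indices (default [default_label_map()]).
#' @param text if `TRUE`, `file` is the annotation text itself.
#' @return a bounding-box `data.frame` (see [bounding_box()]), one row per
#'   line in file order.
#' @examples
#' read_annotation_file("0 0.5 0.5 0.1 0.2", text = TRUE)
#' @export
read_annotation_file <- function(file, label_map = default_label_map(),
                                 text = FALSE) {
  lines <- if (text) strsplit(file, "\n", fixed = TRUE)[[1]] else readLines(file)
  keep <- nzchar(trimws(lines))
  out <- vector("list", sum(keep))
  k <- 0L
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    toks <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
    if (length(toks) != 5L) {
      stop(sprintf("annotation line %d: expected 5 tokens, got %d",
                   i, length(toks)), call. = FALSE)
    }
    suppressWarnings(vals <- as.numeric(toks))
    if (any(is.na(vals))) {
      stop(sprintf("annotation line %d: non-numeric token", i), call. = FALSE)
    }
    idx <- vals[1]
    if (idx != round(idx) || !(idx %in% label_map)) {
      stop(sprintf("annotation line %d: unknown class index %s", i, toks[1]),
           call. = FALSE)
    }
    lab <- names(label_map)[match(idx, label_map)]
    k <- k + 1L
    out[[k]] <- data.frame(class_label = lab, cx = vals[2], cy = vals[3],
                           w = vals[4], h = vals[5], stringsAsFactors = FALSE)
  }
  if (k == 0L) return(empty_boxes())
  do.call(rbind, out[seq_len(k)])
}

#' Write bounding boxes as YOLO-format annotation text
#'
#' The inverse of [read_annotation_file()]: coordinates are printed with six
#' decimal places, so reading back what was written reproduces the boxes to
#' that precision.
#'
#' @param boxes a bounding-box `data.frame`.
#' @param file optional path; when `NULL` the text is returned invisibly
#'   without writing.
#' @param label_map named integer vector mapping class labels to file indices.
#' @return the annotation text (invisibly when written to `file`).
#' @export
write_annotation_file <- function(boxes, file = NULL,
                                  label_map = default_label_map()) {
  check_class_label(boxes$class_label)
  if (nrow(boxes) == 0) {
    txt <- ""
  } else {
    idx <- label_map[boxes$class_label]
    txt <- paste0(sprintf("%d %.6f %.6f %.6f %.6f", idx,
                          boxes$cx, boxes$cy, boxes$w, boxes$h),
                  collapse = "\n")
  }
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}

#' Convert a normalized box to pixel coordinates
#'
#' Corners are computed as `round(center +/- size/2)` in pixels using
#' round-half-away-from-zero, then clamped to the frame `[0, width - 1]` x
#' `[0, height - 1]` (0-based pixel indices).
#'
#' @param boxes a bounding-box `data.frame` (one or more rows).
#' @param width,height image size in pixels.
#' @return a matrix with columns `x_min`, `y_min`, `x_max`, `y_max`, one row
#'   per box.
#' @examples
#' denormalize_box(bounding_box("real", 0.5, 0.5, 0.25, 0.5), 4096, 1710)
#' @export
denormalize_box <- function(boxes, width, height) {
  stopifnot(width > 0, height > 0)
  x_min <- pmin(pmax(round_half_away((boxes$cx - boxes$w / 2) * width), 0), width - 1)
  x_max <- pmin(pmax(round_half_away((boxes$cx + boxes$w / 2) * width), 0), width - 1)
  y_min <- pmin(pmax(round_half_away((boxes$cy - boxes$h / 2) * height), 0), height - 1)
  y_max <- pmin(pmax(round_half_away((boxes$cy + boxes$h / 2) * height), 0), height - 1)
  if (any(x_min >= x_max) || any(y_min >= y_max)) {
    stop("box clamps to zero pixel area", call. = FALSE)
  }
  cbind(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max)
}

#' Construct an image record
#'
#' The unit the pipeline operates on: one microscope image with its
#' ground-truth label, its plant grouping key (all images of one physical
#' plant share a `plant_id` and must land in the same dataset subset), and
#' its annotated boxes.
#'
#' @param image_id unique image identifier (typically the file stem).
#' @param plant_id grouping key for plant-level splitting.
#' @param width,height image size in pixels.
#' @param gt_label ground-truth image label, `"real"` or `"fake"`.
#' @param boxes bounding-box `data.frame` (possibly empty).
#' @param image_path optional path to the image file.
#' @return an object of class `image_record`.
#' @export
image_record <- function(image_id, plant_id, width, height, gt_label,
                         boxes = empty_boxes(), image_path = NA_character_) {
  stopifnot(width > 0, height > 0)
  check_class_label(gt_label, "gt_label")
  if (nrow(boxes) > 0) {
    check_class_label(boxes$class_label)
    if (any(boxes$w <= 0) || any(boxes$h <= 0)) {
      stop("all boxes must have positive size")
    }
  }
  structure(list(image_id = as.character(image_id),
                 plant_id = as.character(plant_id),
                 width = as.integer(width), height = as.integer(height),
                 gt_label = gt_label, boxes = boxes,
                 image_path = image_path),
            class = "image_record")
}

#' @export
print.image_record <- function(x, ...) {
  cat(sprintf("<image_record> %s (plant %s, %dx%d px, %s, %d boxes)\n",
              x$image_id, x$plant_id, x$width, x$height, x$gt_label,
              nrow(x$boxes)))
  invisible(x)
}

#' Derive a plant grouping key from an image file name
#'
#' Real-world file naming is lab-specific, so the key is extracted with a
#' configurable regular expression whose first capture group is the plant
#' identifier; files that do not match fall back to their own stem (each such
#' image becomes its own plant).
#'
#' @param paths character vector of image paths or names.
#' @param pattern regular expression with one capture group.
#' @return character vector of plant ids.
#' @examples
#' plant_id_from_filename(c("plantA_img1.jpg", "plantA_img2.jpg"))
#' @export
plant_id_from_filename <- function(paths, pattern = "^([^_]+)_.*$") {
  stems <- tools::file_path_sans_ext(basename(paths))
  out <- sub(pattern, "\\1", stems)
  out[!grepl(pattern, stems)] <- stems[!grepl(pattern, stems)]
  out
}

#' Split image records at the plant level
#'
#' Partitions records into train/validation/test subsets such that all
#' images of one plant land in the same subset (no plant-level leakage).
#' Plants are shuffled with the given seed and assigned greedily to the
#' subset with the largest remaining image-count deficit relative to its
#' target ratio, so achieved fractions are within one plant's worth of
#' images of the request.
#'
#' @param records list of [image_record()] objects.
#' @param ratios three positive fractions (train, validation, test) summing
#'   to 1.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return an object of class `dataset_split`: a list with elements `train`,
#'   `validation`, `test` (lists of records), plus the `ratios` and `seed`.
#' @export
plant_level_split <- function(records, ratios = c(0.8, 0.1, 0.1), seed = 1L) {
  stopifnot(length(ratios) == 3, all(ratios > 0))
  if (abs(sum(ratios) - 1) > 1e-8) stop("ratios must sum to 1")
  plant <- vapply(records, function(r) r$plant_id, character(1))
  plants <- unique(plant)
  if (length(plants) < 3) {
    stop("need at least 3 distinct plant_ids to form 3 subsets", call. = FALSE)
  }
  n_by_plant <- table(plant)[plants]
  total <- length(records)
  target <- ratios * total
  order_idx <- with_seed(seed, sample.int(length(plants)))
  assigned <- integer(length(plants))
  names(assigned) <- plants
  count <- c(0, 0, 0)
  for (p in plants[order_idx]) {
    deficit <- target - count
    s <- which.max(deficit)
    assigned[p] <- s
    count[s] <- count[s] + n_by_plant[[p]]
  }
  subset_of <- assigned[plant]
  out <- structure(list(train = records[subset_of == 1],
                        validation = records[subset_of == 2],
                        test = records[subset_of == 3],
                        ratios = ratios, seed = seed),
                   class = "dataset_split")
  out
}

#' @export
print.dataset_split <- function(x, ...) {
  n <- vapply(x[c("train", "validation", "test")], length, integer(1))
  cat(sprintf("<dataset_split> train %d / validation %d / test %d images (seed %d)\n",
              n[1], n[2], n[3], x$seed))
  invisible(x)
}

#' Summarize a set of image records
#'
#' Per-class image and bounding-box counts with percentages (one decimal),
#' plus a total row, in the style of a dataset-statistics table.
#'
#' @param records list of [image_record()] objects.
#' @return a `data.frame` with rows `real`, `fake`, `total` and columns
#'   `n_images`, `pct_images`, `n_boxes`, `pct_boxes`.
#' @export
dataset_stats <- function(records) {
  gt <- vapply(records, function(r) r$gt_label, character(1))
  nb <- vapply(records, function(r) {
    if (nrow(r$boxes) == 0) c(real = 0L, fake = 0L) else
      c(real = sum(r$boxes$class_label == "real"),
        fake = sum(r$boxes$class_label == "fake"))
  }, integer(2))
  n_img <- c(sum(gt == "real"), sum(gt == "fake"))
  n_box <- if (length(records)) c(sum(nb["real", ]), sum(nb["fake", ])) else c(0L, 0L)
  tot_img <- sum(n_img); tot_box <- sum(n_box)
  pct <- function(n, tot) if (tot == 0) rep(0, length(n)) else round(100 * n / tot, 1)
  data.frame(row.names = c("real", "fake", "total"),
             n_images = c(n_img, tot_img),
             pct_images = c(pct(n_img, tot_img), if (tot_img == 0) 0 else 100),
             n_boxes = c(n_box, tot_box),
             pct_boxes = c(pct(n_box, tot_box), if (tot_box == 0) 0 else 100))
}

#' Write a dataset manifest
#'
#' Tab-delimited text with columns `image_path`, `plant_id`, `gt_label` (and
#' `width`, `height` so records can be rebuilt without decoding images).
#'
#' @param records list of [image_record()] objects.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_manifest <- function(records, file) {
  df <- data.frame(
    image_path = vapply(records, function(r)
      if (is.na(r$image_path)) r$image_id else r$image_path, character(1)),
    plant_id = vapply(records, function(r) r$plant_id, character(1)),
    gt_label = vapply(records, function(r) r$gt_label, character(1)),
    width = vapply(records, function(r) r$width, integer(1)),
    height = vapply(records, function(r) r$height, integer(1)),
    stringsAsFactors = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}

#' Read a dataset manifest
#'
#' Rebuilds [image_record()] objects from a manifest written by
#' [write_manifest()] (or hand-assembled in the same layout).  When a
#' YOLO-format annotation file with the same stem and extension `.txt` sits
#' next to an image, its boxes are attached.
#'
#' @param file manifest path.
#' @param label_map named integer vector mapping class labels to annotation
#'   file indices.
#' @param read_annotations whether to look for sibling annotation files.
#' @return list of [image_record()] objects.
#' @export
read_manifest <- function(file, label_map = default_label_map(),
                          read_annotations = TRUE) {
  df <- read.delim(file, stringsAsFactors = FALSE)
  need <- c("image_path", "plant_id", "gt_label")
  if (!all(need %in% names(df))) {
    stop("manifest must have columns image_path, plant_id, gt_label")
  }
  base <- dirname(file)
  lapply(seq_len(nrow(df)), function(i) {
    path <- df$image_path[i]
    full <- if (file.exists(path)) path else file.path(base, path)
    boxes <- empty_boxes()
    if (read_annotations) {
      ann <- paste0(tools::file_path_sans_ext(full), ".txt")
      if (file.exists(ann)) boxes <- read_annotation_file(ann, label_map)
    }
    image_record(image_id = tools::file_path_sans_ext(basename(path)),
                 plant_id = df$plant_id[i],
                 width = if ("width" %in% names(df)) df$width[i] else 1L,
                 height = if ("height" %in% names(df)) df$height[i] else 1L,
                 gt_label = df$gt_label[i], boxes = boxes, image_path = full)
  })
}
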