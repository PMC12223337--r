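# Shared fixture builders: everything is generated in code at test time.

# n image records with one plant each (1 image per plant) and simple boxes
make_records <- function(n, label = "real", images_per_plant = 1L,
                         width = 100L, height = 80L, n_boxes = 1L) {
  out <- list()
  plant <- 0L
  i <- 0L
  while (i < n) {
    plant <- plant + 1L
    for (j in seq_len(min(images_per_plant, n - i))) {
      i <- i + 1L
      boxes <- if (n_boxes > 0) {
        bounding_box(rep(label, n_boxes),
                     cx = seq(0.3, 0.7, length.out = n_boxes),
                     cy = 0.5, w = 0.2, h = 0.2)
      } else {
        trichovision:::empty_boxes()
      }
      out[[i]] <- image_record(sprintf("%s_img%03d", label, i),
                               sprintf("%s_plant%03d", label, plant),
                               width, height, label, boxes)
    }
  }
  out
}

# a flat, noise-free scene configuration so painted hair pixels can be
# recovered by thresholding
clean_scene_config <- function(class_label, n_hairs, seed,
                               image_size = c(256, 107)) {
  scene_config(class_label, image_size = image_size, n_hairs = n_hairs,
               background = list(base = c(0.3, 0.3, 0.3), noise_sd = 0,
                                 gradient_amp = 0),
               blur_sigma = 0, seed = seed)
}

# independent brute-force reimplementation of the detection decision rule,
# written against the stated rule text rather than the package internals
oracle_decide <- function(labels, confs) {
  if (length(labels) == 0) return("no_detection")
  counts <- c(real = 0, fake = 0)
  for (l in labels) counts[l] <- counts[l] + 1
  if (counts["real"] != counts["fake"]) {
    return(if (counts["real"] > counts["fake"]) "real" else "fake")
  }
  best <- 1
  for (i in seq_along(confs)) if (confs[i] > confs[best]) best <- i
  labels[best]
}

# all multisets of detections of size <= max_n with confidences on a 0.1
# grid, enumerated by choosing combinations with repetition from the 20
# (label, confidence) atoms
enumerate_detection_multisets <- function(max_n) {
  atoms <- expand.grid(label = c("real", "fake"),
                       conf = seq(0.1, 1, by = 0.1),
                       stringsAsFactors = FALSE)
  out <- list(list(labels = character(0), confs = numeric(0)))
  n_atoms <- nrow(atoms)
  for (k in seq_len(max_n)) {
    combs <- utils::combn(n_atoms + k - 1, k)
    for (j in seq_len(ncol(combs))) {
      idx <- combs[, j] - seq_len(k) + 1  # stars-and-bars decode
      out[[length(out) + 1L]] <- list(labels = atoms$label[idx],
                                      confs = atoms$conf[idx])
    }
  }
  out
}
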