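#' Configuration for one synthetic microscope scene
#'
#' The generator emulates the gross morphology that separates the two
#' classes under a microscope: genuine cannabis non-glandular trichomes are
#' strongly curved ("bear-claw"), relatively wide at the base, sparser, and
#' may carry a bright basal cystolith; non-cannabis trichomes are nearly
#' straight needles, narrower, and more densely distributed.  Hairs are
#' rendered as tapered quadratic-Bezier strokes on a noisy, unevenly lit
#' background, then slightly blurred to mimic lens focus.
#'
#' Geometric defaults are expressed relative to the image width so that the
#' same configuration produces comparable scenes at any rendering scale.
#' Curvature is the reciprocal radius (1/px) of the rendered arc.
#'
#' @param class_label `"real"` or `"fake"`.
#' @param image_size `c(width, height)` in pixels.  The default, 1024 x 428,
#'   is the whole-image classifier's working resolution; pass
#'   `c(4096, 1710)` for full microscope scale.
#' @param n_hairs number of hairs; `NULL` (default) draws it per scene from
#'   a Poisson with class-specific mean (`density_mean`), at least 1.
#' @param density_mean mean hair count; defaults to 4 for `"real"` and 14
#'   for `"fake"` (denser non-cannabis material).
#' @param curvature_mean,curvature_sd distribution of unsigned arc curvature
#'   (1/px); defaults scale with width: 12/width vs 2.5/width.
#' @param width_mean,width_sd distribution of basal hair width (px);
#'   defaults 0.011 vs 0.0035 of image width.
#' @param length_mean,length_sd hair length distribution (px).
#' @param cystolith_probability probability that a hair carries a basal
#'   cystolith; forced to 0 for the `"fake"` class.
#' @param background list with `base` (RGB background tone), `noise_sd`
#'   (per-pixel Gaussian noise) and `gradient_amp` (amplitude of a random
#'   low-frequency illumination gradient).
#' @param blur_sigma Gaussian blur sigma in pixels applied to the final
#'   scene.
#' @param seed integer seed; rendering is bit-identical given the seed.
#' @return an object of class `scene_config`.
#' @export
scene_config <- function(class_label,
                         image_size = c(1024L, 428L),
                         n_hairs = NULL,
                         density_mean = NULL,
                         curvature_mean = NULL, curvature_sd = NULL,
                         width_mean = NULL, width_sd = NULL,
                         length_mean = NULL, length_sd = NULL,
                         cystolith_probability = NULL,
                         background = list(base = c(0.50, 0.52, 0.38),
                                           noise_sd = 0.04,
                                           gradient_amp = 0.08),
                         blur_sigma = 0.8,
                         seed = NULL) {
  check_class_label(class_label)
  stopifnot(length(image_size) == 2, all(image_size >= 16))
  W <- as.numeric(image_size[1])
  real <- class_label == "real"
  cfg <- list(
    class_label = class_label,
    image_size = as.integer(image_size),
    n_hairs = n_hairs,
    density_mean = if (is.null(density_mean)) (if (real) 4 else 14) else density_mean,
    curvature_mean = if (is.null(curvature_mean)) (if (real) 12 / W else 2.5 / W) else curvature_mean,
    curvature_sd = if (is.null(curvature_sd)) (if (real) 3 / W else 1 / W) else curvature_sd,
    width_mean = if (is.null(width_mean)) (if (real) 0.011 * W else 0.0035 * W) else width_mean,
    width_sd = if (is.null(width_sd)) (if (real) 0.002 * W else 0.001 * W) else width_sd,
    length_mean = if (is.null(length_mean)) (if (real) 0.14 * W else 0.12 * W) else length_mean,
    length_sd = if (is.null(length_sd)) 0.025 * W else length_sd,
    cystolith_probability = if (!real) 0 else
      if (is.null(cystolith_probability)) 0.8 else cystolith_probability,
    background = background,
    blur_sigma = blur_sigma,
    seed = seed)
  if (!is.null(cfg$n_hairs) && cfg$n_hairs < 0) stop("n_hairs must be >= 0")
  if (cfg$blur_sigma < 0) stop("blur_sigma must be >= 0")
  if (cfg$cystolith_probability < 0 || cfg$cystolith_probability > 1) {
    stop("cystolith_probability must be in [0, 1]")
  }
  structure(cfg, class = "scene_config")
}

#' Sample hair shape parameters
#'
#' Draws per-hair morphology from the class-conditional distributions of a
#' [scene_config()]: unsigned curvature and basal width are normal draws
#' (truncated at a small positive floor), curvature sign and orientation are
#' uniform, and a cystolith is present with `cystolith_probability` (never
#' for the `"fake"` class).
#'
#' @param config a [scene_config()].
#' @param n number of hairs to sample.
#' @param seed optional seed; `NULL` uses (and advances) the current RNG
#'   state.
#' @return a `data.frame` with columns `arc_curvature` (signed, 1/px),
#'   `length`, `base_width`, `tip_taper`, `cystolith_radius` (0 = absent)
#'   and `orientation` (radians).
#' @export
sample_hair <- function(config, n = 1L, seed = NULL) {
  stopifnot(inherits(config, "scene_config"))
  draw <- function() {
    len <- pmax(8, rnorm(n, config$length_mean, config$length_sd))
    bw <- pmax(1.2, rnorm(n, config$width_mean, config$width_sd))
    curv <- pmax(1e-5, rnorm(n, config$curvature_mean, config$curvature_sd)) *
      sample(c(-1, 1), n, replace = TRUE)
    taper <- runif(n, 0.15, 0.35)
    cyst <- ifelse(runif(n) < config$cystolith_probability,
                   bw * runif(n, 0.9, 1.3), 0)
    data.frame(arc_curvature = curv, length = len, base_width = bw,
               tip_taper = taper, cystolith_radius = cyst,
               orientation = runif(n, 0, 2 * pi))
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

# Quadratic Bezier control points realizing a chord of given length,
# orientation and arc curvature (sagitta = curvature * length^2 / 8).
bezier_points <- function(x0, y0, hair, t) {
  th <- hair$orientation
  dx <- cos(th); dy <- sin(th)
  px <- -dy; py <- dx
  L <- hair$length
  x2 <- x0 + L * dx; y2 <- y0 + L * dy
  sag <- hair$arc_curvature * L^2 / 8
  # control point at twice the sagitta off the chord midpoint
  x1 <- (x0 + x2) / 2 + 2 * sag * px
  y1 <- (y0 + y2) / 2 + 2 * sag * py
  u <- 1 - t
  list(x = u^2 * x0 + 2 * u * t * x1 + t^2 * x2,
       y = u^2 * y0 + 2 * u * t * y1 + t^2 * y2)
}

# Paint filled disks of varying radius along a point track into `canvas`
# (H x W numeric in [0,1] coverage).  Returns the updated canvas.
paint_track <- function(canvas, xs, ys, radii) {
  H <- nrow(canvas); W <- ncol(canvas)
  for (k in seq_along(xs)) {
    r <- radii[k]
    x <- xs[k]; y <- ys[k]
    x0 <- max(1, floor(x - r + 1)); x1 <- min(W, ceiling(x + r + 1))
    y0 <- max(1, floor(y - r + 1)); y1 <- min(H, ceiling(y + r + 1))
    if (x0 > x1 || y0 > y1) next
    ddx <- ((x0:x1) - 1 - x)^2
    ddy <- ((y0:y1) - 1 - y)^2
    hit <- outer(ddy, ddx, "+") <= r^2
    canvas[y0:y1, x0:x1][hit] <- 1
  }
  canvas
}

#' Render one synthetic scene
#'
#' Draws the background (base tone, random illumination gradient, pixel
#' noise), paints each sampled hair as a tapered curved stroke (with a
#' bright basal ellipse when a cystolith is present), blurs the result, and
#' returns the image together with an [image_record()] holding one tight
#' normalized bounding box per rendered hair, labeled with the scene class.
#'
#' Hair placement is retried up to 10 times to keep the whole stroke inside
#' the frame; hairs that cannot be placed are skipped and counted in the
#' `skipped` attribute (with a warning).
#'
#' @param config a [scene_config()]; its `seed` (when non-`NULL`) makes the
#'   output bit-identical across calls.
#' @param image_id,plant_id identifiers stored in the returned record.
#' @return a list with `image` (H x W x 3 array in \[0,1\]), `record` (an
#'   [image_record()]) and `hairs` (the sampled shape parameters).
#' @export
render_scene <- function(config, image_id = "scene", plant_id = image_id) {
  stopifnot(inherits(config, "scene_config"))
  render <- function() {
    W <- config$image_size[1]; H <- config$image_size[2]
    bg <- config$background
    # illumination gradient: random plane, normalized to [-1, 1] amplitude
    gx <- runif(1, -1, 1); gy <- runif(1, -1, 1)
    plane <- outer(seq(-0.5, 0.5, length.out = H) * gy,
                   seq(-0.5, 0.5, length.out = W) * gx, "+")
    plane <- plane / max(1e-9, max(abs(plane))) * bg$gradient_amp
    img <- array(0, c(H, W, 3))
    for (c in 1:3) {
      img[, , c] <- bg$base[c] + plane +
        matrix(rnorm(H * W, 0, bg$noise_sd), H, W)
    }

    n <- if (is.null(config$n_hairs)) {
      max(1L, stats::rpois(1, config$density_mean))
    } else as.integer(config$n_hairs)

    boxes <- empty_boxes()
    skipped <- 0L
    if (n > 0) {
      hairs <- sample_hair(config, n)
      for (i in seq_len(n)) {
        hair <- hairs[i, ]
        placed <- FALSE
        for (try in 1:10) {
          x0 <- runif(1, 2, W - 3); y0 <- runif(1, 2, H - 3)
          npts <- max(24L, ceiling(2 * hair$length))
          t <- seq(0, 1, length.out = npts)
          p <- bezier_points(x0, y0, hair, t)
          r <- (hair$base_width / 2) * (1 - (1 - hair$tip_taper) * t)
          pad <- max(r, hair$cystolith_radius) + 1
          if (min(p$x) - pad >= 0 && max(p$x) + pad <= W - 1 &&
              min(p$y) - pad >= 0 && max(p$y) + pad <= H - 1) {
            placed <- TRUE
            break
          }
        }
        if (!placed) { skipped <- skipped + 1L; next }
        mask <- matrix(0, H, W)
        mask <- paint_track(mask, p$x, p$y, r)
        if (hair$cystolith_radius > 0) {
          # bright ellipse at the hair base, slightly inset along the curve
          cx <- p$x[2]; cy <- p$y[2]
          a <- hair$cystolith_radius; b <- 0.7 * a
          th <- hair$orientation
          x0w <- max(1, floor(cx - a)); x1w <- min(W, ceiling(cx + a + 1))
          y0w <- max(1, floor(cy - a)); y1w <- min(H, ceiling(cy + a + 1))
          xr <- (x0w:x1w) - 1 - cx; yr <- (y0w:y1w) - 1 - cy
          u <- outer(yr * 0, xr * cos(th), "+") + outer(yr * sin(th), xr * 0, "+")
          v <- outer(yr * cos(th), -xr * sin(th), "+")
          cmask <- (u / a)^2 + (v / b)^2 <= 1
          cyst <- matrix(0, H, W)
          cyst[y0w:y1w, x0w:x1w][cmask] <- 1
          mask[cyst > 0] <- 1
          # cystoliths render brighter than the hair shaft
          for (c in 1:3) {
            ch <- img[, , c]
            ch[cyst > 0] <- 0.97
            img[, , c] <- ch
          }
        }
        shade <- runif(1, 0.9, 1.05)
        tone <- c(0.86, 0.88, 0.80) * shade
        hit <- mask > 0
        for (c in 1:3) {
          ch <- img[, , c]
          keep <- hit & ch < 0.95  # do not darken cystolith pixels
          ch[keep] <- tone[c]
          img[, , c] <- ch
        }
        ys <- which(rowSums(mask) > 0); xs <- which(colSums(mask) > 0)
        boxes <- rbind(boxes, bounding_box(
          config$class_label,
          cx = (min(xs) - 1 + max(xs) - 1 + 1) / 2 / W,
          cy = (min(ys) - 1 + max(ys) - 1 + 1) / 2 / H,
          w = (max(xs) - min(xs) + 1) / W,
          h = (max(ys) - min(ys) + 1) / H))
      }
      if (skipped > 0) {
        warning(sprintf("%d hair(s) skipped after bounded placement retries",
                        skipped))
      }
    }
    if (config$blur_sigma > 0) {
      for (c in 1:3) img[, , c] <- cv_gauss_blur(img[, , c], config$blur_sigma)
    }
    img[img < 0] <- 0; img[img > 1] <- 1
    rec <- image_record(image_id, plant_id, W, H, config$class_label, boxes)
    out <- list(image = img, record = rec, skipped = skipped)
    out
  }
  if (is.null(config$seed)) render() else with_seed(config$seed, render())
}

#' Generate an annotated synthetic dataset on disk
#'
#' Renders `n_per_class` scenes per class, writes each as a PNG plus a
#' YOLO-format annotation file, assigns synthetic plant ids such that a
#' configurable fraction of plants contributes two images (a plant
#' photographed twice), and writes a manifest.  Output is byte-identical
#' for a fixed seed.
#'
#' @param n_per_class number of scenes per class (>= 1).
#' @param out_dir output directory (created if missing); `NULL` keeps
#'   everything in memory and writes nothing.
#' @param base_config named list of [scene_config()] overrides applied to
#'   both classes (e.g. `list(image_size = c(256, 107))`).
#' @param seed integer master seed.
#' @param twice_fraction fraction of plants photographed twice.
#' @return list of [image_record()] objects (invisibly carries the rendered
#'   images in attribute `"images"` when `out_dir` is `NULL`).
#' @export
generate_dataset <- function(n_per_class, out_dir = NULL, base_config = list(),
                             seed = 1L, twice_fraction = 0.3) {
  stopifnot(n_per_class >= 1)
  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok && !dir.exists(out_dir)) stop("cannot create output directory: ", out_dir)
  }
  records <- list()
  images <- list()
  plan <- with_seed(seed, {
    lapply(CLASS_LEVELS, function(cl) {
      # plant sizes: 2 images with probability twice_fraction, else 1
      sizes <- integer(0); tot <- 0L
      while (tot < n_per_class) {
        s <- if (runif(1) < twice_fraction) 2L else 1L
        s <- min(s, n_per_class - tot)
        sizes <- c(sizes, s); tot <- tot + s
      }
      list(class = cl, sizes = sizes,
           seeds = sample.int(.Machine$integer.max - 1L, n_per_class))
    })
  })
  for (p in plan) {
    img_i <- 0L
    for (pl in seq_along(p$sizes)) {
      plant_id <- sprintf("%s_plant%04d", p$class, pl)
      for (j in seq_len(p$sizes[pl])) {
        img_i <- img_i + 1L
        image_id <- sprintf("%s_%04d", p$class, img_i)
        cfg <- do.call(scene_config, c(list(class_label = p$class,
                                            seed = p$seeds[img_i]),
                                       base_config))
        sc <- render_scene(cfg, image_id = image_id, plant_id = plant_id)
        rec <- sc$record
        if (!is.null(out_dir)) {
          img_path <- file.path(out_dir, paste0(image_id, ".png"))
          png::writePNG(sc$image, img_path)
          write_annotation_file(rec$boxes,
                                file.path(out_dir, paste0(image_id, ".txt")))
          rec$image_path <- img_path
        } else {
          images[[image_id]] <- sc$image
        }
        records[[length(records) + 1L]] <- rec
      }
    }
  }
  if (!is.null(out_dir)) {
    write_manifest(records, file.path(out_dir, "manifest.tsv"))
  } else {
    attr(records, "images") <- images
  }
  records
}

#' Load the pixel data for an image record
#'
#' Reads the PNG/JPEG behind a record as an H x W x 3 array in \[0,1\];
#' grayscale images are expanded to three identical channels.
#'
#' @param record an [image_record()] with a readable `image_path`.
#' @return numeric array (H, W, 3).
#' @export
load_image <- function(record) {
  path <- if (inherits(record, "image_record")) record$image_path else record
  if (is.na(path) || !file.exists(path)) stop("image file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  if (dim(img)[3] > 3) img <- img[, , 1:3, drop = FALSE]
  img
}
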