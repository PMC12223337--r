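test_that("annotation text parses in file order with labels mapped", {
  expect_equal(nrow(read_annotation_file("", text = TRUE)), 0)

  one <- read_annotation_file("0 0.5 0.5 0.1 0.2", text = TRUE)
  expect_equal(one$class_label, "real")
  expect_equal(unlist(one[, c("cx", "cy", "w", "h")], use.names = FALSE),
               c(0.5, 0.5, 0.1, 0.2))

  two <- read_annotation_file("1 0.25 0.75 0.05 0.05\n0 0.5 0.5 0.2 0.2",
                              text = TRUE)
  expect_equal(two$class_label, c("fake", "real"))
  expect_equal(two$cx, c(0.25, 0.5))
})

test_that("malformed annotation lines report their line number", {
  expect_error(read_annotation_file("0 0.5 0.5 0.1", text = TRUE), "line 1")
  expect_error(read_annotation_file("0 0.5 0.5 0.1 0.2\n0 a 0.5 0.1 0.2",
                                    text = TRUE), "line 2")
  expect_error(read_annotation_file("7 0.5 0.5 0.1 0.2", text = TRUE),
               "class index")
})

test_that("write/read round-trips boxes at 6-decimal precision", {
  expect_equal(write_annotation_file(trichovision:::empty_boxes()), "")
  expect_equal(write_annotation_file(bounding_box("real", 0.5, 0.5, 0.1, 0.2)),
               "0 0.500000 0.500000 0.100000 0.200000")

  set.seed(31)
  boxes <- bounding_box(sample(c("real", "fake"), 100, replace = TRUE),
                        cx = round(runif(100), 6), cy = round(runif(100), 6),
                        w = round(runif(100, 0.01, 1), 6),
                        h = round(runif(100, 0.01, 1), 6))
  back <- read_annotation_file(write_annotation_file(boxes), text = TRUE)
  expect_equal(back, boxes)

  tmp <- withr::local_tempfile(fileext = ".txt")
  write_annotation_file(boxes, tmp)
  expect_equal(read_annotation_file(tmp), boxes)
})

test_that("denormalization rounds half away from zero and clamps to frame", {
  expect_equal(
    drop(denormalize_box(bounding_box("real", 0.5, 0.5, 0.25, 0.5), 4096, 1710)),
    c(x_min = 1536, y_min = 428, x_max = 2560, y_max = 1283))
  expect_equal(
    drop(denormalize_box(bounding_box("real", 0.5, 0.5, 1, 1), 640, 480)),
    c(x_min = 0, y_min = 0, x_max = 639, y_max = 479))
  expect_equal(
    drop(denormalize_box(bounding_box("real", 0, 0, 0.5, 0.5), 100, 100)),
    c(x_min = 0, y_min = 0, x_max = 25, y_max = 25))
  # a box entirely off-frame clamps to zero area
  expect_error(denormalize_box(bounding_box("real", 1.5, 0.5, 0.1, 0.1),
                               100, 100), "zero pixel area")
})

test_that("plant-level split keeps plants together and honors ratios", {
  recs <- make_records(10)
  sp <- plant_level_split(recs, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(vapply(sp[c("train", "validation", "test")], length,
                      integer(1)), c(train = 8, validation = 1, test = 1))

  # grouping invariant: all 5 images of one plant land together
  grouped <- c(make_records(5, images_per_plant = 5),
               make_records(4, label = "fake"))
  sp2 <- plant_level_split(grouped, seed = 2)
  plant_sets <- lapply(sp2[c("train", "validation", "test")], function(s)
    unique(vapply(s, function(r) r$plant_id, character(1))))
  expect_length(Reduce(intersect, plant_sets), 0)
  one_plant <- vapply(grouped[1:5], function(r) r$plant_id, character(1))
  holds <- vapply(sp2[c("train", "validation", "test")], function(s)
    sum(vapply(s, function(r) r$plant_id, character(1)) %in% one_plant),
    numeric(1))
  expect_true(any(holds == 5) && sum(holds) == 5)

  # determinism
  expect_identical(plant_level_split(recs, seed = 9),
                   plant_level_split(recs, seed = 9))

  expect_error(plant_level_split(make_records(2), seed = 1), "at least 3")
})

test_that("every record lands in exactly one subset across random splits", {
  for (seed in 1:5) {
    recs <- c(make_records(7 + seed, images_per_plant = 2),
              make_records(6, label = "fake"))
    sp <- plant_level_split(recs, c(0.6, 0.2, 0.2), seed = seed)
    ids <- unlist(lapply(sp[c("train", "validation", "test")], function(s)
      vapply(s, function(r) r$image_id, character(1))))
    expect_setequal(ids, vapply(recs, function(r) r$image_id, character(1)))
    expect_equal(anyDuplicated(ids), 0)
  }
})

test_that("dataset statistics reproduce printed per-class arithmetic", {
  # reference corpus composition: per-class image and box counts
  recs <- c(make_records(1286, "real", n_boxes = 0),
            make_records(1540, "fake", n_boxes = 0))
  recs[[1]]$boxes <- bounding_box(rep("real", 1461), 0.5, 0.5, 0.1, 0.1)
  recs[[2]]$boxes <- bounding_box(rep("fake", 1697), 0.5, 0.5, 0.1, 0.1)
  st <- dataset_stats(recs)
  expect_equal(st["total", "n_images"], 2826)
  expect_equal(st["real", "pct_images"], 45.5)
  expect_equal(st["fake", "pct_images"], 54.5)
  expect_equal(st["total", "n_boxes"], 3158)
  expect_equal(st["real", "n_boxes"], 1461)
  # totals equal the sum of per-class entries
  expect_equal(st["total", "n_images"], sum(st[c("real", "fake"), "n_images"]))

  empty <- dataset_stats(list())
  expect_true(all(empty == 0))
})

test_that("manifests round-trip records with their annotations", {
  dir <- withr::local_tempdir()
  recs <- generate_dataset(2, dir, base_config = list(image_size = c(64, 48)),
                           seed = 3)
  back <- read_manifest(file.path(dir, "manifest.tsv"))
  expect_equal(length(back), length(recs))
  expect_equal(vapply(back, function(r) r$gt_label, character(1)),
               vapply(recs, function(r) r$gt_label, character(1)))
  expect_equal(back[[1]]$boxes, recs[[1]]$boxes, tolerance = 1e-5)
})

test_that("plant ids derive from filename prefixes with fallback", {
  expect_equal(plant_id_from_filename(c("p12_a.jpg", "p12_b.jpg", "odd.jpg")),
               c("p12", "p12", "odd"))
})
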