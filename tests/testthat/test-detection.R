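test_that("detector configs carry the family-specific default thresholds", {
  expect_equal(detector_config("external_yolo")$confidence_threshold, 0.05)
  expect_equal(detector_config("external_detr")$confidence_threshold, 0.3)
  expect_error(detector_config("classical", 1.2), "\\[0, 1\\]")
})

test_that("threshold filtering is order-preserving, idempotent and monotone", {
  dets <- detection(c("real", "fake", "real"), c(0.18, 0.97, 0.4))
  expect_identical(filter_by_threshold(dets, 0), dets)
  expect_equal(nrow(filter_by_threshold(dets, 1)), 0)
  # the reported example confidences: 0.3 keeps only the 0.97 detection
  kept <- filter_by_threshold(detection(c("real", "fake"), c(0.18, 0.97)), 0.3)
  expect_equal(kept$confidence, 0.97)

  expect_identical(filter_by_threshold(filter_by_threshold(dets, 0.3), 0.3),
                   filter_by_threshold(dets, 0.3))
  for (th in seq(0, 1, 0.25)) {
    expect_true(all(filter_by_threshold(dets, th + 0.2)$confidence %in%
                      filter_by_threshold(dets, th)$confidence))
  }
})

test_that("decision scheme follows count, then confidence, then order", {
  expect_equal(decide_from_detections(NULL)$label, "no_detection")
  expect_equal(decide_from_detections(
    trichovision:::empty_detections())$label, "no_detection")
  expect_equal(decide_from_detections(
    detection(c("real", "real", "fake"), c(0.3, 0.2, 0.9)))$label, "real")
  expect_equal(decide_from_detections(
    detection(c("real", "fake"), c(0.4, 0.7)))$label, "fake")
  # tie in count and max confidence: earliest in input order
  expect_equal(decide_from_detections(
    detection(c("fake", "real"), c(0.5, 0.5)))$label, "fake")
})

test_that("decision scheme matches the brute-force oracle on small multisets", {
  cases <- enumerate_detection_multisets(3)
  for (cs in cases) {
    dets <- if (length(cs$labels)) detection(cs$labels, cs$confs) else
      trichovision:::empty_detections()
    expect_identical(decide_from_detections(dets)$label,
                     oracle_decide(cs$labels, cs$confs))
  }
})

test_that("decisions are permutation-invariant and monotone in support", {
  set.seed(17)
  for (i in 1:40) {
    k <- sample(1:6, 1)
    labs <- sample(c("real", "fake"), k, replace = TRUE)
    confs <- sample(seq(0.1, 1, 0.1), k, replace = TRUE)
    base <- decide_from_detections(detection(labs, confs))$label
    # permutation-invariant except in the documented double-tie case
    # (equal counts and the same maximum confidence in both classes)
    n_real <- sum(labs == "real")
    double_tie <- n_real * 2 == k && n_real > 0 &&
      isTRUE(all.equal(max(confs[labs == "real"]),
                       max(confs[labs == "fake"])))
    if (!double_tie) {
      perm <- sample(k)
      expect_identical(
        decide_from_detections(detection(labs[perm], confs[perm]))$label,
        base)
    }
    # adding a detection of the winning class never flips the decision
    if (base != "no_detection") {
      more <- detection(c(labs, base), c(confs, 0.1))
      expect_identical(decide_from_detections(more)$label, base)
    }
  }
})

test_that("mock backend honors miss and flip probabilities", {
  rec <- image_record("im1", "p1", 200, 100, "real",
                      bounding_box(c("real", "real", "fake"),
                                   c(0.2, 0.5, 0.8), 0.5, 0.1, 0.2))
  exact <- detect(NULL, detector_config(
    "mock", 0, options = list(miss_prob = 0, flip_prob = 0, jitter_frac = 0,
                              seed = 5)), rec)
  expect_equal(nrow(exact), 3)
  expect_equal(exact$class_label, rec$boxes$class_label)

  none <- detect(NULL, detector_config(
    "mock", 0, options = list(miss_prob = 1, seed = 5)), rec)
  expect_equal(nrow(none), 0)

  flipped <- detect(NULL, detector_config(
    "mock", 0, options = list(miss_prob = 0, flip_prob = 1, seed = 5)), rec)
  expect_equal(flipped$class_label, c("fake", "fake", "real"))

  # deterministic under a seed
  expect_identical(
    detect(NULL, detector_config("mock", 0, options = list(seed = 9)), rec),
    detect(NULL, detector_config("mock", 0, options = list(seed = 9)), rec))
})

test_that("classical backend separates strongly curved from straight hairs", {
  dc <- detector_config("classical", 0.5)
  real_sc <- render_scene(scene_config("real", n_hairs = 5, seed = 61))
  fake_sc <- render_scene(scene_config("fake", n_hairs = 8, seed = 62))
  dr <- detect(real_sc$image, dc, real_sc$record)
  df <- detect(fake_sc$image, dc, fake_sc$record)
  expect_gt(nrow(dr), 0)
  expect_gt(nrow(df), 0)
  expect_gt(mean(dr$class_label == "real"), 0.5)
  expect_gt(mean(df$class_label == "fake"), 0.5)
})

test_that("external results files parse and filter by image id", {
  f <- withr::local_tempfile(lines = c(
    "im1 real 0.80 10 20 110 220",
    "im2 fake 0.90 5 5 50 50",
    "im1 fake 0.04 0 0 30 30"))
  cfg <- detector_config("external_yolo",
                         options = list(results_file = f, image_id = "im1"))
  dets <- detect(NULL, cfg)
  # the 0.04 detection falls below the 0.05 YOLO-style threshold
  expect_equal(nrow(dets), 1)
  expect_equal(dets$class_label, "real")
  expect_equal(dets$x_max, 110)

  bad <- withr::local_tempfile(lines = "im1 real 0.8 10 20")
  expect_error(detect(NULL, detector_config(
    "external_yolo", options = list(results_file = bad))), "7 fields")
})

test_that("image accuracy counts no_detection as an error", {
  gt <- rep(c("real", "fake"), 5)
  expect_equal(detector_image_accuracy(gt, gt), 1)
  preds <- gt; preds[4] <- "no_detection"
  expect_equal(detector_image_accuracy(preds, gt), 0.9)
  expect_equal(detector_image_accuracy(rep("no_detection", 10), gt), 0)
  expect_error(detector_image_accuracy(gt[1:3], gt), "mismatch")
})

test_that("IoU-matched box metrics count mislabeled matches as errors", {
  rec <- image_record("im", "p", 100, 100, "real",
                      bounding_box(c("real", "real"), c(0.25, 0.75), 0.5,
                                   0.2, 0.2))
  px <- denormalize_box(rec$boxes, 100, 100)
  dets <- detection(c("real", "fake"), c(0.9, 0.8),
                    px[, "x_min"], px[, "y_min"], px[, "x_max"], px[, "y_max"])
  mt <- detection_box_metrics(dets, rec)
  expect_equal(mt$tp, 1)  # second match has the wrong label
  expect_equal(mt$fp, 1)
  expect_equal(mt$precision, 0.5)
})
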