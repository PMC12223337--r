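test_that("patch windows center on detections and stay in frame", {
  # center (2048, 855) in 4096 x 1710: no shift needed
  w <- patch_window(2048, 855, 4096, 1710, 512)
  expect_equal(drop(w), c(x0 = 1792, y0 = 599, x1 = 2304, y1 = 1111))
  # near the corner: shifted minimally to (0, 0)
  w2 <- patch_window(10, 10, 4096, 1710, 512)
  expect_equal(drop(w2)[c("x0", "y0")], c(x0 = 0, y0 = 0))
  # opposite corner
  w3 <- patch_window(4090, 1705, 4096, 1710, 512)
  expect_equal(drop(w3)[c("x1", "y1")], c(x1 = 4096, y1 = 1710))
  expect_error(patch_window(10, 10, 300, 300, 512), "smaller")
})

test_that("1000 random centers all give exact in-frame 512x512 windows", {
  set.seed(23)
  cx <- c(runif(996, 0, 4095), 0, 4095, 0, 4095)
  cy <- c(runif(996, 0, 1709), 0, 1709, 1709, 0)
  w <- patch_window(cx, cy, 4096, 1710, 512)
  expect_true(all(w[, "x0"] >= 0 & w[, "y0"] >= 0))
  expect_true(all(w[, "x1"] <= 4096 & w[, "y1"] <= 1710))
  expect_true(all(w[, "x1"] - w[, "x0"] == 512))
  expect_true(all(w[, "y1"] - w[, "y0"] == 512))
})

test_that("crop_patch extracts the centered window pixels", {
  img <- array(0, c(200, 300, 3))
  img[96:105, 141:160, 2] <- 1  # bright block around center (150, 100)
  det <- detection("real", 0.9, 140, 95, 160, 105)
  p <- crop_patch(img, det, 64)
  expect_equal(dim(p), c(64, 64, 3))
  # the block center lands at the patch center
  expect_equal(p[33, 33, 2], 1)
  expect_equal(sum(p[, , 2]), sum(img[, , 2]))

  # undersized image pads by edge replication, with a warning
  small <- array(0.5, c(30, 40, 3))
  expect_warning(pp <- crop_patch(small, detection("real", 1, 10, 10, 20, 20),
                                  64), "replication")
  expect_equal(dim(pp), c(64, 64, 3))
  expect_true(all(pp == 0.5))
})

test_that("patch datasets inherit ground truth, not detector labels", {
  recs <- list(
    image_record("a", "p1", 256, 107, "real",
                 bounding_box(c("real", "real"), c(0.3, 0.7), 0.5, 0.2, 0.3)),
    image_record("b", "p2", 256, 107, "fake",
                 bounding_box("fake", 0.5, 0.5, 0.3, 0.3)),
    image_record("c", "p3", 256, 107, "real"))  # no boxes
  images <- setNames(lapply(recs, function(r)
    array(runif(107 * 256 * 3), c(107, 256, 3))),
    c("a", "b", "c"))
  # all detector labels wrong: patch labels must still be correct
  det <- detector_config("mock", 0, options = list(flip_prob = 1, seed = 3))
  patches <- build_patch_dataset(recs, det, patch_size = 64, images = images)
  expect_length(patches, 3)
  expect_equal(vapply(patches, `[[`, character(1), "gt_label"),
               c("real", "real", "fake"))
  expect_true(all(vapply(patches, function(p)
    all(dim(p$patch) == c(64, 64, 3)), logical(1))))

  none <- build_patch_dataset(recs, detector_config(
    "mock", 0, options = list(miss_prob = 1, seed = 3)),
    patch_size = 64, images = images)
  expect_length(none, 0)
})

test_that("patch vote aggregation follows majority, then mean probability", {
  out <- function(p_real) list(
    probabilities = c(real = p_real, fake = 1 - p_real),
    predicted_label = if (p_real >= 0.5) "real" else "fake")
  expect_equal(aggregate_patch_predictions(list(out(0.9), out(0.8), out(0.1))),
               "real")
  # vote tie: mean probability decides
  expect_equal(aggregate_patch_predictions(list(out(0.6), out(0.1))), "fake")
  expect_equal(aggregate_patch_predictions(list(out(0.7))), "real")
  # vote tie with a lower mean real-probability goes to fake
  expect_equal(aggregate_patch_predictions(list(out(0.5), out(0.4))), "fake")
  # exact tie in votes and mean probabilities: real wins by class order
  expect_equal(aggregate_patch_predictions(list(out(0.6), out(0.4))), "real")
  expect_error(aggregate_patch_predictions(list()), "empty")
  # permutation invariance
  set.seed(4)
  outs <- lapply(runif(7), out)
  expect_equal(aggregate_patch_predictions(outs),
               aggregate_patch_predictions(outs[sample(7)]))
})

test_that("cascades apply the staged decision rules and never abstain", {
  rec <- image_record("x", "p", 256, 107, "fake",
                      bounding_box("fake", 0.5, 0.5, 0.3, 0.4))
  img <- array(0.5, c(107, 256, 3))
  always_real <- function(image) list(
    probabilities = c(real = 0.9, fake = 0.1), predicted_label = "real")

  # stage 1 fires: classifier never consulted
  cfg1 <- cascade_config("two_stage",
                         stage1 = detector_config("mock", 0,
                                                  options = list(seed = 1)),
                         whole_image_classifier = function(image)
                           stop("must not be called"))
  r1 <- run_cascade(img, cfg1, rec)
  expect_equal(r1$label, "fake")
  expect_equal(r1$deciding_stage, "detector")

  # stage 1 empty in two-stage: whole-image classifier decides
  miss <- detector_config("mock", 0.6,
                          options = list(miss_prob = 1, seed = 1))
  cfg2 <- cascade_config("two_stage", stage1 = miss,
                         whole_image_classifier = always_real)
  r2 <- run_cascade(img, cfg2, rec)
  expect_equal(r2$label, "real")
  expect_equal(r2$deciding_stage, "whole_image")

  # three-stage: stage 2 fires, patch classifier aggregates
  stage2 <- detector_config("mock", 0.3, options = list(seed = 2))
  cfg3 <- cascade_config("three_stage", stage1 = miss, stage2 = stage2,
                         patch_size = 64,
                         whole_image_classifier = function(image)
                           stop("must not be called"),
                         patch_classifier = always_real)
  r3 <- run_cascade(img, cfg3, rec)
  expect_equal(r3$label, "real")
  expect_equal(r3$deciding_stage, "patch_classifier")

  # three-stage with both detectors empty: whole-image classifier
  miss2 <- detector_config("mock", 0.3, options = list(miss_prob = 1, seed = 1))
  cfg4 <- cascade_config("three_stage", stage1 = miss, stage2 = miss2,
                         whole_image_classifier = always_real,
                         patch_classifier = function(image)
                           stop("must not be called"))
  r4 <- run_cascade(img, cfg4, rec)
  expect_equal(r4$label, "real")
  expect_equal(r4$deciding_stage, "whole_image")
})

test_that("stage-2 threshold must undercut stage 1", {
  s1 <- detector_config("classical", 0.4)
  expect_error(cascade_config("three_stage", stage1 = s1,
                              stage2 = detector_config("classical", 0.6)),
               "lower")
  auto <- cascade_config("three_stage", stage1 = s1)
  expect_equal(auto$stage2$confidence_threshold, 0.2)
})

test_that("the cascade dominates detector-only evaluation on mock scenes", {
  set.seed(55)
  recs <- lapply(1:60, function(i) {
    cl <- if (i %% 2) "real" else "fake"
    nb <- sample(1:3, 1)
    image_record(sprintf("s%02d", i), sprintf("p%02d", i), 128, 54, cl,
                 bounding_box(rep(cl, nb),
                              cx = runif(nb, 0.2, 0.8), cy = runif(nb, 0.3, 0.7),
                              w = 0.15, h = 0.2))
  })
  gt <- vapply(recs, function(r) r$gt_label, character(1))
  img <- array(0.5, c(54, 128, 3))
  det <- detector_config("mock", 0,
                         options = list(miss_prob = 0.45, flip_prob = 0.1))
  always_real <- function(image) list(
    probabilities = c(real = 0.8, fake = 0.2), predicted_label = "real")

  set.seed(100)
  det_labels <- vapply(recs, function(r)
    decide_from_detections(detect(img, det, r))$label, character(1))
  set.seed(100)
  casc_labels <- vapply(recs, function(r)
    run_cascade(img, cascade_config("two_stage", stage1 = det,
                                    whole_image_classifier = always_real),
                r)$label, character(1))

  expect_true(any(det_labels == "no_detection"))
  expect_false(any(casc_labels == "no_detection"))
  # the cascade only changes no_detection cases, so it cannot do worse
  expect_gte(detector_image_accuracy(casc_labels, gt),
             detector_image_accuracy(det_labels, gt))
  changed <- det_labels != casc_labels
  expect_true(all(det_labels[changed] == "no_detection"))

  # an always-wrong fallback restores exact equality with detector-only
  set.seed(100)
  wrong <- mapply(function(r, g) {
    stub <- function(image) list(
      probabilities = setNames(as.numeric(c(g == "fake", g == "real")),
                               c("real", "fake")),
      predicted_label = if (g == "real") "fake" else "real")
    run_cascade(img, cascade_config("two_stage", stage1 = det,
                                    whole_image_classifier = stub), r)$label
  }, recs, gt)
  expect_equal(detector_image_accuracy(wrong, gt),
               detector_image_accuracy(det_labels, gt))

  # a perfect mock detector makes cascade accuracy exactly 1
  perfect <- detector_config("mock", 0,
                             options = list(miss_prob = 0, flip_prob = 0,
                                            seed = 1))
  perf_labels <- vapply(recs, function(r)
    run_cascade(img, cascade_config("two_stage", stage1 = perfect,
                                    whole_image_classifier = always_real),
                r)$label, character(1))
  expect_equal(detector_image_accuracy(perf_labels, gt), 1)
})
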