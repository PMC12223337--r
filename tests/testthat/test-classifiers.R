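test_that("flatten arithmetic matches the printed architecture sizes", {
  spec <- architecture_spec("basic_cnn")
  expect_equal(flattened_dim(spec), 212992)           # 128 * 26 * 64
  expect_equal(flattened_dim(spec, c(16, 16)), 128)   # 128 * 1 * 1
  expect_equal(flattened_dim(spec, c(1024, 432)), 221184)  # 128 * 27 * 64
  expect_equal(flattened_dim(spec, c(512, 512)), 131072)   # 128 * 32 * 32
  expect_error(flattened_dim(spec, c(8, 8)), "collapses")
})

test_that("flattened_dim agrees with the instantiated model", {
  # oracle equivalence: the forward pass only works if the arithmetic
  # matches the true pooled feature size feeding fc1
  set.seed(20)
  for (i in 1:20) {
    w <- sample(16:80, 1); h <- sample(16:80, 1)
    spec <- architecture_spec("basic_cnn", input_size = c(w, h),
                              fc_hidden = c(8, 4))
    m <- build_model(spec, seed = i)
    expect_equal(nrow(m$params$fc1$w), flattened_dim(spec))
    out <- classify(m, array(runif(h * w * 3), c(h, w, 3)))
    expect_length(out$probabilities, 2)
  }
})

test_that("preprocessing reproduces the stated rescale targets", {
  img <- array(runif(1710 * 4096 * 3), c(1710, 4096, 3))
  expect_equal(dim(preprocess(img, preprocess_config(0.25)))[1:2], c(428, 1024))
  expect_equal(dim(preprocess(img, preprocess_config(0.125)))[1:2], c(214, 512))
  small <- array(runif(50 * 40 * 3), c(50, 40, 3))
  expect_identical(dim(preprocess(small, preprocess_config(1.0))), c(50L, 40L, 3L))
  expect_equal(dim(preprocess(small, preprocess_config(target_size = c(256, 256))))[1:2],
               c(256, 256))
  expect_true(all(preprocess(small, preprocess_config(0.5)) >= 0))
})

test_that("classifier outputs are softmax-normalized and batch-consistent", {
  spec <- architecture_spec("basic_cnn", input_size = c(32, 24),
                            fc_hidden = c(8, 4))
  m <- build_model(spec, seed = 2)
  img <- array(runif(24 * 32 * 3), c(24, 32, 3))
  out <- classify(m, img)
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  expect_equal(out$predicted_label,
               names(which.max(out$probabilities)))

  # duplicated input in a batch gives identical outputs per copy
  x <- array(0, c(24, 32, 3, 3))
  for (k in 1:3) x[, , , k] <- img
  cb <- classify_batch(m, x)
  expect_equal(cb$real, rep(cb$real[1], 3))
  expect_equal(cb$predicted_label, rep(out$predicted_label, 3))

  expect_error(classify(m, array(runif(10 * 10 * 3), c(10, 10, 3))),
               "expects")
})

test_that("dla variant runs forward at its default and odd input sizes", {
  spec <- architecture_spec("dla", input_size = c(64, 48),
                            stem_channels = c(4, 6, 6),
                            tree_channels = c(8, 8, 12, 12))
  m <- build_model(spec, seed = 3)
  out <- classify(m, array(runif(48 * 64 * 3), c(48, 64, 3)))
  expect_equal(sum(out$probabilities), 1, tolerance = 1e-6)
  # global average pooling makes the flatten size input-independent
  expect_equal(flattened_dim(spec), 12)
  expect_equal(flattened_dim(spec, c(80, 60)), 12)
  # the fixed 4x4-kernel pooling alternative: 256x128 -> 16x8 -> 4x2
  spec4 <- architecture_spec("dla", input_size = c(256, 128),
                             stem_channels = c(4, 6, 6),
                             tree_channels = c(8, 8, 12, 12),
                             dla_pool = "kernel4")
  expect_equal(flattened_dim(spec4), 12 * 4 * 2)
  m4 <- build_model(spec4, seed = 3)
  out4 <- classify(m4, array(runif(128 * 256 * 3), c(128, 256, 3)))
  expect_equal(sum(out4$probabilities), 1, tolerance = 1e-6)
  # too small an input for the 4x4 pool is rejected
  expect_error(flattened_dim(spec4, c(48, 48)), "collapses")
})

test_that("training history, selection and determinism contracts hold", {
  set.seed(44)
  x <- array(runif(24 * 32 * 3 * 8), c(24, 32, 3, 8))
  y <- rep(c("real", "fake"), 4)
  spec <- architecture_spec("basic_cnn", input_size = c(32, 24),
                            fc_hidden = c(8, 4))
  m <- build_model(spec, seed = 5)
  cfg <- train_config(epochs = 2, batch_size = 4, augment = FALSE, seed = 10,
                      learning_rate = 1e-3)
  r1 <- train_classifier(m, list(x = x, y = y), list(x = x, y = y), cfg)
  expect_equal(nrow(r1$history), 2)
  expect_true(r1$model$best_epoch %in% 1:2)
  expect_equal(r1$history$val_accuracy[r1$model$best_epoch],
               max(r1$history$val_accuracy))

  # same seed, same data -> identical history
  r2 <- train_classifier(m, list(x = x, y = y), list(x = x, y = y), cfg)
  expect_identical(r1$history, r2$history)

  expect_error(train_classifier(m, list(x = NULL, y = character()),
                                list(x = x, y = y), cfg), "empty")
})

test_that("zero learning rate without augmentation leaves weights unchanged", {
  spec <- architecture_spec("basic_cnn", input_size = c(32, 24),
                            fc_hidden = c(8, 4))
  m <- build_model(spec, seed = 6)
  x <- array(runif(24 * 32 * 3 * 4), c(24, 32, 3, 4))
  y <- c("real", "fake", "real", "fake")
  cfg <- train_config(learning_rate = 0, epochs = 1, batch_size = 4,
                      augment = FALSE, seed = 3)
  r <- train_classifier(m, list(x = x, y = y), list(x = x, y = y), cfg)
  # tolerance covers the single-precision round-trip of the fused trainer
  for (nm in names(m$params)) {
    expect_equal(r$model$params[[nm]]$w, m$params[[nm]]$w, tolerance = 1e-6)
    expect_equal(r$model$params[[nm]]$b, m$params[[nm]]$b, tolerance = 1e-6)
  }
})

test_that("constant-input data trains to the majority-class share", {
  # degenerate pixels carry no signal, so validation accuracy settles at
  # the majority share of the validation labels
  x <- array(0.5, c(24, 32, 3, 10))
  y <- c(rep("fake", 7), rep("real", 3))
  spec <- architecture_spec("basic_cnn", input_size = c(32, 24),
                            fc_hidden = c(8, 4))
  m <- build_model(spec, seed = 7)
  cfg <- train_config(epochs = 3, batch_size = 5, augment = FALSE, seed = 8,
                      learning_rate = 1e-3)
  r <- train_classifier(m, list(x = x, y = y), list(x = x, y = y), cfg)
  expect_equal(max(r$history$val_accuracy), 0.7)
})

test_that("augmentation preserves shape and range", {
  set.seed(12)
  img <- array(runif(40 * 60 * 3), c(40, 60, 3))
  out <- augment_image(img)
  expect_identical(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("checkpoints round-trip a model", {
  spec <- architecture_spec("basic_cnn", input_size = c(32, 24),
                            fc_hidden = c(8, 4))
  m <- build_model(spec, seed = 9,
                   preprocess = preprocess_config(target_size = c(32, 24)))
  f <- withr::local_tempfile(fileext = ".rds")
  save_checkpoint(m, f)
  m2 <- load_checkpoint(f)
  img <- array(runif(24 * 32 * 3), c(24, 32, 3))
  expect_identical(classify(m, img), classify(m2, img))
})
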