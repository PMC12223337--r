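# trichovision

Vision pipeline for a forensic botany question: does a microscope image of
seized plant material show **genuine cannabis** non-glandular trichomes
("real"), or the trichomes of **non-cannabis plant material** ("fake"),
typically inert leaf matter sprayed with synthetic cannabinoids?
Genuine cannabis hairs are curved ("bear-claw") and often carry a bright
basal cystolith; non-cannabis hairs are straighter, narrower needles,
more densely packed.  The package is aimed at forensic image-analysis
groups and at anyone studying detector/classifier decision cascades on
microscopy-like data.

It provides, end to end and testable without any external dataset:

* **Annotations** — YOLO-format normalized bounding-box I/O
  (`read_annotation_file()`, `write_annotation_file()`,
  `denormalize_box()`), dataset manifests, per-class statistics
  (`dataset_stats()`), and leakage-free **plant-level** train/validation/
  test splitting (`plant_level_split()`): all images of one physical plant
  stay in the same subset.
* **Synthetic scenes** — a generator (`scene_config()`, `render_scene()`,
  `generate_dataset()`) that draws microscope-like scenes whose hair
  curvature, width, density and cystolith statistics differ by class,
  with exact ground-truth boxes; deterministic under a seed.
* **Classifiers** — a 4-block **basic CNN**
  (conv 3x3 / batch-norm / ReLU / max-pool; 16-32-64-128 maps;
  fully connected 1024-32-2 with dropout 0.25) and a
  **deep-layer-aggregation (DLA)** variant (16/32/32 stem, 64/128/256/512
  tree stages with concatenation + residual aggregation, global average
  pool).  Bicubic preprocessing (factor 0.25 to 1024 x 428, factor 0.125
  to 512 x 214, or 256 x 256 patches), class-weighted cross-entropy, Adam,
  augmentations, and best-validation-epoch selection
  (`train_classifier()`).  All compute is in the package's own compiled
  kernels; no GPU or external framework.
* **Detection** — a detector-backend contract (`detector_config()`,
  `detect()`): adapters for external YOLO-style / DETR-style result files
  (default confidence thresholds 0.05 / 0.3), a classical curvature-based
  detector, and a mock detector for controlled experiments; plus the
  decision scheme `decide_from_detections()`: majority class wins, ties go
  to the most confident detection, no detections means `"no_detection"` —
  always an error at evaluation.
* **Composite cascades** — `run_cascade()`: two-stage (detector, then
  whole-image classifier) and three-stage (detector, low-threshold
  detector + 512 x 512 patch classification with majority-vote
  aggregation, then whole-image classifier).  The cascade never abstains.
* **Evaluation** — per-split accuracy, unweighted split averaging,
  confusion counts and method comparison tables (`evaluate()`,
  `average_splits()`, `comparison_table()`).

The key arithmetic identity the implementation pins down: with same-padding
convolutions, only the four 2x2 max-pools change the spatial grid (floor
division per axis), so a 1024 x 428 input reaches the first fully
connected layer with

```
flattened_dim = 128 * floor(428 / 2^4) * floor(1024 / 2^4)
              = 128 * 26 * 64 = 212,992 features.
```

## Worked example

Generate a small annotated dataset, split it by plant, train the basic
CNN briefly, and run the two-stage cascade with the classical detector:

```r
library(trichovision)

recs <- generate_dataset(100, out_dir = NULL,
                         base_config = list(image_size = c(256, 107)),
                         seed = 1)
imgs <- attr(recs, "images")
dataset_stats(recs)
#>       n_images pct_images n_boxes pct_boxes
#> real       100         50     385      21.4
#> fake       100         50    1418      78.6
#> total      200        100    1803     100.0

sp <- plant_level_split(recs, c(0.8, 0.1, 0.1), seed = 2)
sp
#> <dataset_split> train 160 / validation 20 / test 20 images (seed 2)

pc <- preprocess_config(target_size = c(256, 107))
model <- build_model(architecture_spec("basic_cnn", input_size = c(256, 107)),
                     seed = 3, preprocess = pc)
fit <- train_classifier(model,
                        assemble_tensor(sp$train, pc, imgs),
                        assemble_tensor(sp$validation, pc, imgs),
                        train_config(learning_rate = 1e-3, epochs = 8,
                                     batch_size = 8, augment = FALSE,
                                     seed = 4))
test <- assemble_tensor(sp$test, pc, imgs)
mean(classify_batch(fit$model, test$x)$predicted_label == test$y)
#> [1] 1
```

`dataset_stats()` counts images and annotated hairs per class: the two
classes are balanced in images, but fake scenes are denser, so they
contribute most of the boxes.  The run above (about a minute on one CPU)
is a scaled-down version of the package's own verification, which trains
for 10 epochs on 400 scenes and requires at least 90% accuracy on 100
held-out scenes.

The classical detector and the decision scheme on one scene:

```r
sc <- render_scene(scene_config("real", seed = 21))
dets <- detect(sc$image, detector_config("classical", 0.5), sc$record)
dets[, c("class_label", "confidence")]
#>   class_label confidence
#> 1        real  0.6252829
#> 3        real  0.8811875
decide_from_detections(dets)
#> <image_decision> real (2 supporting detections)
```

Both detected hairs exceed the curvature cut, so both vote `"real"` and
the image is labeled `"real"`; a scene with no retained detections would
come back `"no_detection"`, which the cascade — but not a bare detector —
can still resolve.

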