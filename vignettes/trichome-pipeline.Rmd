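---
title: "Classifying cannabis trichomes: models, synthetic scenes, and the composite decision strategy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying cannabis trichomes: models, synthetic scenes, and the composite decision strategy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Forensic laboratories must distinguish genuine cannabis from inert plant
material sprayed with synthetic cannabinoids.  Under a microscope the two
differ in their non-glandular trichomes: genuine cannabis carries curved,
"bear-claw" shaped hairs, often with a bright calcium-carbonate deposit (a
cystolith) at the base, while non-cannabis material carries straighter,
narrower, more densely packed needle-like hairs.  `trichovision`
implements an image-analysis pipeline around exactly this contrast: binary
whole-image classifiers, a detector contract with a decision scheme that
turns per-hair detections into an image label, and multi-stage cascades
that combine the two.

Class conventions throughout: `"real"` is genuine cannabis, `"fake"` is
non-cannabis plant material.

## Annotations and plant-level splitting

Bounding boxes use the YOLO text convention: one line per box,
`<class index> <cx> <cy> <w> <h>`, all coordinates normalized by the image
size.  Boxes are kept exactly as parsed; clamping to the pixel frame
happens only at denormalization, with a single rounding rule used
everywhere (round half away from zero, so `1710 * 0.25 = 427.5` becomes
`428`).  Pixel coordinates are 0-based.

Because the same physical plant can be photographed more than once,
splitting by image would leak near-duplicates across subsets.
`plant_level_split()` therefore partitions *plants*: plants are shuffled
under the given seed and greedily assigned to the subset with the largest
remaining image-count deficit relative to the requested ratios (default
80/10/10).  This achieves the requested fractions to within one plant's
worth of images and is deterministic given the seed.  For real data the
plant key is extracted from file names with a configurable regular
expression, since file-naming schemes are lab-specific; synthetic data
carries explicit plant ids.

## The synthetic scene generator

The package must be testable end-to-end without the original microscope
corpus, so `render_scene()` draws scenes that reproduce the *morphological
statistics* that separate the classes rather than the appearance of any
particular microscope:

* each hair is a quadratic Bezier stroke whose sagitta realizes a target
  arc curvature, with width tapering linearly toward the tip;
* `"real"` scenes draw high curvature (mean 12/width px^-1), wide bases
  (1.1% of image width), a basal cystolith with probability 0.8 (rendered
  as a brighter ellipse), and few hairs per scene (Poisson, mean 4);
* `"fake"` scenes draw low curvature (2.5/width), narrow bases (0.35%),
  never a cystolith, and denser scenes (mean 14 hairs);
* the background is a flat tone plus a random low-frequency illumination
  gradient and per-pixel Gaussian noise, and the whole scene receives a
  mild Gaussian blur (sigma 0.8 px) to emulate imperfect focus.

Geometric defaults scale with the image width so the same configuration is
meaningful at the classifier working resolution (1024 x 428, the default)
and at full microscope scale (4096 x 1710, via `image_size`).  The
separation between the class-conditional distributions is a design
contract of the generator: defaults are chosen so that a held-out
classifier can exceed 90% accuracy on desk-scale scenes, which is what the
synthetic suite verifies.  What passing those tests shows is that the
*pipeline* recovers a known morphological signal; it does not certify
accuracy on real microscope images, whose artifacts (debris, specular
reflections, defocus gradients, stains) the generator deliberately does
not model.

Every stochastic component takes an explicit seed and rendering is
bit-identical given the seed, which the determinism tests rely on.

## Whole-image classifiers

Two trainable architectures are provided, both ending in a softmax over
the two classes with the argmax as the predicted label.

The **basic CNN** is four blocks of 3x3 convolution (same padding), batch
normalization, ReLU and 2x2 max-pooling, with 16/32/64/128 feature maps,
followed by three fully connected layers (flatten -> 1024 -> 32 -> 2) with
dropout 0.25 and ReLU between them.  Same-padding convolutions mean only
the pools change the spatial grid, each halving an axis with floor
division; at the working input 1024 x 428 the first fully connected layer
therefore receives 128 x 26 x 64 = 212,992 features.  `flattened_dim()`
exposes this arithmetic and the test suite checks it against the
instantiated network.  Layer-shape listings for this architecture
sometimes print the final pair in (out, in) order; only the 32 -> 2
reading is consistent with a 2-class softmax, and that is what is
implemented.

The **DLA variant** is a deep-layer-aggregation style network: a
three-block stem (16/32/32 maps, no pooling), then four tree stages
(64/128/256/512 maps).  Each stage downsamples by 2 and aggregates two
stacked convolution blocks through a concatenation node with a residual
skip.  Quoted pre-classifier feature sizes for DLA-style networks depend
on the assumed stride schedule and are easy to state inconsistently; this
implementation sidesteps the ambiguity with a *global* average pool after
the tree stages, which makes the fully connected head (512 -> 32 -> 2)
well defined for every input size.  The fixed 4x4-kernel average pool is
retained as a configuration option (`dla_pool = "kernel4"`).

Inputs are rescaled with bicubic (Catmull-Rom) interpolation — factor 0.25
per axis for the basic CNN (4096 x 1710 -> 1024 x 428), 0.125 for the DLA
(-> 512 x 214), and a fixed 256 x 256 for the patch classifier.  The
resampler is implemented in compiled code so that the interpolation kernel
and the rounding of target sizes are pinned down exactly.

### Training protocol

`train_classifier()` uses class-weighted cross-entropy (equal weights by
default, which reduces to plain binary cross-entropy), the Adam optimizer,
and per-epoch validation; the returned checkpoint is the epoch with the
highest validation accuracy, ties going to the earliest epoch.  Default
hyper-parameters follow the whole-image protocol (learning rate 1e-4,
batch 16, 80 epochs; the DLA uses batch 6 and the patch classifier batch
12 with learning rate 1e-5).  Augmentations are the named geometric and
texture jitters — rotation, translation, scale, horizontal flip,
brightness, hue, saturation, gamma, contrast.  Their magnitudes are a
free choice, set to mild configurable defaults (±15°, ±10%
translation, scale 0.9–1.1, ±20% brightness/contrast/saturation, hue
±0.05, gamma 0.8–1.25).

All forward/backward passes are implemented in the package's own compiled
primitives (im2col + BLAS convolutions, fused batch-norm/ReLU); the 4-block
CNN additionally has a fused single-precision training step that computes
one minibatch forward, loss and backward in a single call.  The fused path
is checked against the layered double-precision reference to float
precision in the test suite.  Runs are reproducible given the config seed;
everything is single-threaded apart from BLAS.

### Desk-scale verification sizes

The label-recovery check trains the basic CNN at input 256 x 107 on 400
generated scenes (200 per class, split at plant level) for 10 epochs with
learning rate 1e-3, batch size 8 and no augmentation, evaluating on 100
held-out scenes.  These sizes keep a from-scratch training run in the
single-digit-minute range on one CPU while leaving a clear margin above
chance; the elevated learning rate and halved batch (doubling the number
of optimization steps) compensate for the short schedule — the 1e-4 /
batch-16 protocol default is tuned for 80-epoch runs on real data, where
augmentation earns its keep.

## Detectors and the decision scheme

Object detectors return per-hair boxes with a class label and confidence.
External YOLO-style and DETR-style detectors are consumed through their
result files behind a common contract — this package never trains or runs
them — with family-specific default confidence thresholds (0.05 for
YOLO-style, 0.3 for DETR-style).  Two built-in backends make the pipeline
self-contained: a **mock** backend that perturbs ground-truth boxes with
configurable miss/flip probabilities (for controlled experiments), and a
**classical** backend that thresholds the image (Otsu, after a small
smoothing), extracts elongated connected components, fits a quadratic in
each component's principal frame, and labels a component `"real"` when the
implied arc curvature exceeds a cut (default 6/width px^-1, roughly midway
between the two class means), with confidence mapped from the margin to
the cut through a logistic squashed to [0, 1).

`decide_from_detections()` maps detections to one image label: the class
with strictly more detections wins; equal counts fall back to the class of
the single most confident detection; no detections yields
`"no_detection"`, which evaluation always counts as an error.  When both
the counts and the maximum confidences tie, the earliest detection in
input order decides; callers wanting order-independence should sort by
(confidence desc, x, y) first.  No non-maximum suppression is applied
before the decision — overlapping detections of the same hair each count —
mirroring how low-threshold detector output is treated downstream.

## The composite method

The cascade resolves images the detector leaves undecided:

* **two-stage** — if the stage-1 detector returns any detection, its
  decision stands; otherwise a whole-image classifier decides;
* **three-stage** — as above, but an empty stage 1 first triggers a
  lower-threshold stage-2 detector; its boxes are cropped to fixed
  512 x 512 patches (windows centered on each detection, shifted minimally
  to stay in frame, edge-replicated only if the image itself is smaller
  than a patch) and classified individually, the final label being an
  unweighted majority vote with a mean-probability tie-break (a
  confidence-weighted vote is available behind a flag); if stage 2 also
  returns nothing, the whole-image classifier decides.

The stage-2 threshold defaults to half the stage-1 threshold; any value
strictly below stage 1 is accepted.  Patch training data is built by
running a low-threshold detector over images with known ground-truth
labels and giving every patch the *image's* label, not the detection's —
duplicates and false patches are deliberately kept, since only the
image-level label is chemically verified.

A useful structural property follows directly from the two-stage rule:
since the cascade differs from detector-only scoring exactly on the
`no_detection` images, and those always score as errors, the cascade's
accuracy is bounded below by the detector-only accuracy whatever the
fallback classifier does.  The suite asserts this on seeded mock runs,
including the degenerate equality case where the fallback is replaced by
an always-wrong stub.

## Evaluation

`evaluate()` scores exact label matches (with `"no_detection"` always
wrong) and `average_splits()` averages per-split accuracies with equal
weight per split, regardless of test-set sizes.  Accuracies are kept at
full precision internally and truncated toward zero to two decimals only
at display time, the convention under which a split average like
(96.50 + 95.29)/2 = 95.895 is displayed as 95.89.
`comparison_table()` sorts methods by average accuracy, keeping input
order on ties.

## Numerical and design notes

* One rounding rule (half away from zero) serves denormalization, rescale
  targets and patch-window placement.
* Max-pooling uses floor division on odd axes (428 -> 214 -> 107 -> 53 ->
  26), which is what makes the printed flatten size reproducible.
* Batch normalization uses biased batch variance for normalization and
  unbiased variance for the running average (momentum 0.1, eps 1e-5).
* Degenerate inputs fail loudly: boxes that clamp to zero pixel area,
  pooling chains that collapse a dimension, empty training subsets and
  empty aggregation lists are all errors, not silent defaults.
* Model checkpoints are versioned serialized files embedding the
  architecture spec and preprocessing config.

## Known limitations

* The generator does not model glandular trichomes, debris, specular
  artifacts or focus gradients; results on synthetic scenes bound nothing
  about real-world accuracy.
* The classical detector is a baseline for synthetic scenes, not a
  competitor to trained detectors on real microscopy.
* Only binary classification is supported, and external detectors are
  integrated at the results-file level only.
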