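---
title: "Methods: automated Perugini grading of cardiac uptake on bone scintigraphy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automated Perugini grading of cardiac uptake on bone scintigraphy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The clinical problem

Transthyretin amyloidosis (ATTR) deposits misfolded transthyretin fibrils in
the myocardium. Because the fibrils bind bone-avid [99mTc] tracers, ATTR shows
up as *cardiac* uptake on ordinary bone scintigraphy — most of which is
acquired for oncologic reasons, so the finding is incidental and easily
missed. The Perugini scale grades cardiac uptake visually against bone:

* grade 0 — no cardiac uptake;
* grade 1 — uptake less than bone;
* grade 2 — uptake similar to bone;
* grade 3 — uptake greater than bone,

with grade ≥ 2 read as positive for ATTR. `scintigrade` implements an
automated pipeline for this reading: image preprocessing, two compact
convolutional networks, stratified cross-validated training under heavy class
imbalance, ROC-based evaluation, and activation-map interpretability. Since
clinical scintigraphy datasets are private, the package also contains a
first-class synthetic phantom generator so that every stage of the pipeline is
testable end to end.

## The phantom generator

`generate_whole_body()` and `generate_planar_thoracic()` draw a deterministic
parametric body — ellipses, bars and bands for skull, spine, sternum,
shoulders, ribs, pelvis, humeri and femurs — on a soft-tissue silhouette. The
generator deliberately models *count topology*, not anatomy: the downstream
networks only need plausible spatial intensity structure.

Key choices, all seeded and configurable through `phantom_config()`:

* **Grade encoding.** The cardiac ellipse adds `cardiac_ratio x
  bone_intensity` counts on top of the soft-tissue background, and skeletal
  template pixels are carved out of the ellipse. On noiseless phantoms the
  cardiac region mean is therefore *exactly* `background + ratio x bone`:
  a degenerate grade-0 interval gives background-level cardiac counts, and
  ratios above 1 exceed the sternum mean, which reproduces the visual grading
  rules quantitatively. `grade_to_ratio()` draws the ratio from per-grade
  intervals — defaults `[0, 0.15]`, `[0.3, 0.8]`, `[0.9, 1.1]`, `[1.3, 2.5]` —
  disjoint by default so phantom labels are unambiguous; overlapping
  intervals can be configured to probe the hard grade-1/2 boundary.
* **Cardiac geometry.** The ellipse sits left of the midline at 0.22 x body
  height below the crown (about 0.09 x body height below the shoulder line).
  Placed much lower it would leave the thoracic crop window that the
  preprocessing rules define, so the geometry was chosen to keep the heart
  inside the cropped matrix across the supported range of patient heights and
  positions.
* **Intensities.** Bone 100 counts/pixel, soft tissue 5 — values in a
  realistic range for a 3-hour post-injection acquisition, chosen once; the
  grading problem depends only on the cardiac-to-bone ratio, not the absolute
  scale.
* **Nuisance structure.** Poisson counting noise; injection-site hot spots in
  the arm region at 5–20 x bone intensity (the case the log transform is
  designed to defuse); optional focal bone lesions (2–4 x bone) standing in
  for metastases, assigned independently of grade; patient height fraction
  0.8–0.98 of the frame and random vertical/horizontal offsets.

What the phantoms do **not** emulate: scanner/collimator response, scatter and
attenuation, anatomical variability, bed overlap, or the subtle
grade-conditional texture of real myocardium. Passing tests on phantoms
therefore demonstrates that the pipeline's machinery is correct and that the
networks can learn intensity-ratio structure from imbalanced 2-D count data —
not that clinical-grade accuracy transfers to patients.

## Preprocessing

`preprocess_studies()` applies, deterministically:

1. **Anterior selection** — only AP views are retained.
2. **Thoracic crop to 128 x 128.** For whole-body images the patient's
   vertical extent is measured from the per-row count profile (first and last
   rows with positive sums); with patient height H and lowest body row B (both
   0-based), the window top is `round(B − 0.85 H)`, the window extends 128
   rows down and 64 columns either side of the image's vertical midline, then
   clamps to the frame. Measuring 0.85 H *upward from the feet* places the
   window on the chest; fractional coordinates round half away from zero; an
   optional flag centers columns on the patient's nonzero-column midpoint
   instead of the geometric center. Planar images are area-averaged down to
   256 x 256 when larger and centrally cropped.
3. **Log transform** `x -> ln(1 + x)` on all pixels: zeros stay zero, the map
   is strictly monotone, and hot spots are compressed (a spot 100 x brighter
   than 10-count bone retains only a ~2.9 x intensity advantage), so they
   cannot dominate normalization.
4. **Pixel-wise z-scoring** with mean and *population* standard deviation
   computed from the training fold only (`compute_norm_stats()` /
   `zscore_apply()`), with a 1e-7 floor on the standard deviation for
   never-illuminated pixels. Keeping the statistics inside the fold is the
   leakage guard that the tests assert by recomputation.

## Network architectures

`build_linear()` constructs the plain model: one stem convolution, then four
blocks of six 3 x 3 convolutions (stride 1, same padding, ReLU) with a 2 x 2
average pooling after each block, then flatten, dropout 0.2 and a softmax
head of width 2 or 4. `build_residual()` is topologically identical with
three parameter-free skip connections per block: the output two convolutions
back is added to the pre-activation of every second convolution and ReLU is
applied to the sum; where a block widens, the skip is zero-padded in
channels, so the two models always count exactly the same number of
parameters.

Two numerical conventions worth stating:

* **Pooling stride.** The average pools default to stride 2, giving the
  halving schedule 128 → 64 → 32 → 16 → 8 and a ~1.1-million-parameter model
  (1,112,644 under the default stem 16 / blocks 16-32-64-128 plan); stride 1
  is available behind a flag but inflates the flattened stage enormously.
* **Initialization.** Uniform fan-in weights (±sqrt(6/fan_in)), zero biases,
  and a zero-initialized head so training starts from exactly uniform class
  probabilities. The initialization seed is part of `model_spec()` and every
  build is reproducible.

`build_pretrained()` offers canonical VGG16, ResNet50, InceptionV3 and
MobileNet backbones with the original classifier replaced by the same
flatten/dropout/softmax head, single-channel input replicated to three
channels. Offline, weights are randomly initialized; the builders exist
primarily for architectural comparison (e.g. canonical VGG16 with its
ImageNet head counts 138,357,544 trainable parameters against ~1.1 million
for the custom models) and for checkpoint loading where pretrained weights
are available.

The package carries its own conv/pool/dense engine (im2col + BLAS through
RcppArmadillo) because no deep-learning framework is part of its dependency
set; the backward pass is validated against numerical differentiation in the
test suite at ~1e-9 relative error.

## Training and evaluation

`run_cross_validation()` reproduces the full protocol per fold: stratified
5-fold assignment (per-class counts differ by at most one study between
folds), fold-internal normalization statistics, randomized augmentation
(shifts ±10% of the image size, rotations ±20°, scalings ±20%, bilinear with
zero fill; `multiplier` augmented images per training image, default 5, so a
1066-image fold yields 5330), inverse-frequency class weights
`w_c = n / (K n_c)` (so minority grades 2 and 3 carry most of the loss), and
Adam on class-weighted sparse categorical cross-entropy — 50 epochs, batch
128, initial learning rate 1e-4 by default, 10% of the training data held out
for validation, learning rate multiplied by `lr_factor` after two epochs
without validation-loss improvement and floored at 1e-7. Three optional
stabilizers, all off by default and recorded in the run configuration: a
global gradient-norm ceiling (`clip_norm`); checkpoint-style `restore_best`,
which returns the weights of the best-validation epoch; and bounded
multi-start (`restarts`), which re-initializes and retrains when a run's
best validation loss never improved on the uniform predictor — the same
philosophy as `kmeans(nstart = )`, consulting only the validation split.

Reported metrics follow the standard definitions: binary ROC-AUC on the
positive-class probability (fixed orientation, ties counted half), macro
one-vs-rest AUC for the four-class task, total accuracy, and per-class
precision/recall with empty denominators reported as `NA` rather than zero.
Cross-validated headline numbers are computed on the *pooled* out-of-fold
predictions (each study predicted exactly once), with per-fold reports
retained; pooling is labeled in every report. The three clinical tasks are
four-class grading, positive-vs-negative detection (grade ≥ 2 positive — the
reading used by the tabulated results, preferred over the inconsistent
"grade > 2" phrasing that appears once in the training description), and
grade 3 versus the rest. `subgroup_report()` recomputes the pooled metrics
separately for studies with and without bone metastases.

### Scaled-down validation runs

The test suite exercises learning end to end on one 400-phantom dataset with
balanced grades, default (disjoint) ratio intervals, Poisson noise, 5%
planar studies and 15% metastasis prevalence: three seeded 5-fold runs of
each custom model at 10 epochs. To keep that tractable on a single CPU the
runs use a reduced working resolution (128 x 128 crops area-averaged to
32 x 32 — the cardiac ellipse spans ~10 pixels, comfortably resolvable), a
slimmer filter plan (stem 8; blocks 8/16/32/64), batch 16, learning rate
1e-3 with gradient clipping at norm 1, plateau factor 0.5, best-epoch
restoration and up to two restarts. These sizes are the package's chosen
validation scale; the defaults of `model_spec()` and `train_config()` remain
the full-scale protocol. At this scale a 25-layer unnormalized plain network
is near the edge of trainability in 10 epochs — exactly the regime where the
residual variant's skip connections visibly stabilize optimization (it
converges on every fold without ever needing a restart, while the plain
model occasionally requires one), so the learning property in the test
suite asks for success in 2 of 3 seeds.

## Interpretability

`max_activation_map()` implements the per-input reading of a "maximum
activation map": the channel-wise maximum of a layer's post-activation
feature maps, bilinearly upsampled to the input resolution and min–max
rescaled to [0, 1] (constant maps rescale to zero). Layers are selected
semantically — the first convolution of each block via
`select_block_entry_layers()` — because index-based selection is fragile
across counting conventions. The alternative reading (optimizing an input to
maximally excite a filter) is deliberately out of scope.
`cardiac_focus_score()` quantifies the qualitative claim that trained models
look at the heart: mean map value inside the cardiac mask over the mean
outside, capped when the outside mean vanishes; values above 1 indicate
cardiac focus.

## Known limitations

* Phantoms are geometric stand-ins; no claim of clinical performance
  transfers from them.
* The engine is CPU-only and double-precision; at the full 128 x 128 / 50
  epoch scale training is slow compared with GPU frameworks, and the package
  is sized for method validation rather than production training.
* Batch-norm layers in the comparison backbones use batch statistics during
  training without maintaining running averages (the custom models contain
  no batch norm; the backbones are built for structural comparison and
  inference with loaded weights).
* DICOM ingestion is out of scope for the phantom-based workflow; studies
  are exchanged as 16-bit TIFF or plain-text matrices with a CSV sidecar.
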