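---
title: "Specimen-level classification of sinking invertebrate silhouettes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Specimen-level classification of sinking invertebrate silhouettes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem and the data model

Freshwater biomonitoring produces bulk samples containing thousands of
macroinvertebrate specimens. One practical route to identifying them is to
drop each specimen into a backlit, ethanol-filled glass cuvette and
photograph it with two perpendicular cameras at a fixed frame rate while it
sinks. Each specimen then yields an ordered sequence of dark silhouette
frames from two orthogonal views; because the frame rate is constant, the
number of images per specimen is inversely proportional to its sinking
speed, ranging in practice from under twenty (dense, compact animals such as
small bivalves) to several hundred (slow-sinking larvae).

`specvote` implements the full analysis around such data:

1. **imaging** — segment the silhouette in each frame, measure it, apply
   the standard crop, and convert mean pixel area to mm².
2. **datasets** — specimen-grouped, leakage-free splits: a fixed test set,
   balanced nested training subsamples, a stratified validation carve-out,
   and grouped k-fold cross-validation.
3. **classification** — a per-image scoring model fitted with
   validation-based early stopping, emitting an unbounded score per taxon.
4. **voting** — aggregate the per-image results of one specimen into a
   single decision by majority vote or by the maximum scoring sum.
5. **evaluation / experiment** — per-taxon precision and recall, confusion
   matrices, learning curves over the number of training specimens, and
   cross-validation.
6. **synthetic data** — a silhouette-sequence generator with the
   statistical structure of the real archive, so every stage is testable
   without downloads or GPU training.

The central invariant throughout is *specimen grouping*: all frames of one
specimen belong to exactly one of training, validation, or test, so no
pixel-level information leaks between partitions. Splitting therefore always
happens at the specimen level and images inherit their specimen's
assignment.

## Silhouette measurement

Frames are grayscale matrices in $[0,1]$ with a bright backlit background
(≈0.95). `detect_blob()` thresholds the frame — Otsu's method by default,
because silhouette imaging yields a strongly bimodal histogram; a fixed
numeric threshold can be supplied instead — keeps the largest 8-connected
foreground component, and fills interior holes so translucent body parts do
not fragment the area measurement. Conventions are fixed so results are
bit-reproducible:

* connectivity: 8-connected components for the blob; a pixel belongs to the
  perimeter if at least one of its 4-neighbours lies outside the blob
  (a 10×10 square thus has perimeter 36);
* maximum diameter: the max-Feret diameter, i.e. the largest Euclidean
  distance between any two silhouette pixel centers. It is computed on the
  convex hull, which is exact because the diameter of a finite set is
  attained at hull vertices;
* coordinates are 1-based `(row, col)` with the origin at the top left, and
  bounding boxes are inclusive;
* a frame with no pixel below the threshold signals a `specvote_no_blob`
  condition; pipelines drop such frames with a logged count, and a specimen
  with zero valid frames is excluded and reported.

`crop_to_standard()` reproduces the instrument's crop: output width is
always the 496-px cuvette width; output height is 496 px, or the blob's
bounding-box height if the specimen is taller; the window is centered on the
blob's vertical center, clamped to the sensor, and padded with background
intensity if it extends beyond it. `estimate_body_size()` converts the mean
per-frame pixel area to mm² with the field-of-view calibration
$(10\,\mathrm{mm}/496\,\mathrm{px})^2 \approx 4.06\times10^{-4}\,
\mathrm{mm^2}$ per pixel.

## The per-image scorer

The classifier interface is deliberately small: a fitted model maps a frame
to a finite, *unbounded* score vector with one entry per taxon (no
probability squashing), and `predict_image()` takes the argmax with ties
going to the lowest class index. Any model with this contract can stand
behind the pipeline, including a convolutional network; the package ships a
desk-scale reference implementation that trains in seconds on a CPU.

The reference scorer is an L2-regularized multinomial logistic model over a
fixed feature map: the cropped frame is area-pooled to a 16×16 intensity
grid and concatenated with six geometric descriptors (log area, log
perimeter, log maximum diameter, bounding-box aspect ratio, bounding-box
fill fraction, and mean silhouette intensity). Features are standardized
with training-set statistics. A 224×224 bilinear resize (`resize_image()`)
is provided as the standard preprocessing step for image-space models; the
linear scorer pools directly from the crop because a further fixed linear
resampling adds computation without adding information to a linear model.

Training is full-batch gradient descent with momentum 0.9, learning rate
0.3, and weight penalty `l2 = 1e-3`, starting from zero weights — the
objective is convex, so the fit is deterministic without any RNG. After
every epoch the training loss, validation loss, and validation accuracy are
logged. The returned parameters are those of the epoch with the minimum
validation loss; training stops when *neither* the validation loss nor the
validation accuracy has improved for 10 epochs, or after at most 200
epochs. Monitoring loss for weight selection and accuracy as a secondary
plateau criterion reflects the two quantities a practitioner watches; both
appear in the returned `training_log` so the interplay is auditable. The
learning rate was chosen for stability: substantially larger steps make the
first epochs oscillate so badly that early stopping can latch onto epoch 1,
while much smaller steps fail to converge inside the 200-epoch cap at the
largest training sizes.

Because specimens yield wildly different frame counts, the experiment
harness weights each training frame by `1 / n_frames(specimen)`, so every
specimen — and hence every taxon of a specimen-balanced design — carries
equal weight in the loss. Without this, slow-sinking taxa with dozens of
frames per specimen dominate training and evaluation-by-image, which
distorts comparisons between frame-weighted and specimen-weighted metrics.

Augmentation (`augment_image()`) applies, in order, a rotation drawn within
±180°, independent axis flips with probability ½, and a shear
$(x', y') = (x + \lambda_x y,\; \lambda_y x + y)$ with
$\lambda_x, \lambda_y \in [-0.2, 0.2]$ by default (the magnitudes are
package choices; shear preserves straight lines and scales areas by
$|1-\lambda_x\lambda_y|$). All transforms use bilinear interpolation about
the image center with constant background padding, so a shear never
translates the blob off-frame. Augmentation changes pixels only — never an
image's label or specimen assignment. The reference experiments do not
augment: the linear scorer's pooled features gain little from it, while the
operations themselves are exercised by their own tests.

## Voting

Two aggregation rules turn per-frame results into one decision per
specimen:

* **majority vote** — every frame carries one equal vote; the specimen is
  assigned the class with the most votes. Vote ties are broken by the
  larger summed score among the tied classes, remaining ties by the lowest
  class index. An explicit tie rule matters because specimens with only two
  frames are common at the fast-sinking end.
* **max scoring sum** — the unbounded score vectors of all frames are
  summed element-wise and the largest total wins. Raw scores (not softmax
  probabilities) are summed deliberately: frames the model finds ambiguous
  have low scores for every class and therefore contribute little, so the
  sum weights frames by confidence.

Both rules reduce to the per-image decision for single-frame specimens, are
invariant to frame order and to adding a constant to all scores, and agree
whenever one class holds both the vote majority and the maximal score sum.

## Splits and experiments

`assign_test_split()` fixes 10 test specimens per taxon (uniformly, without
replacement) once per experiment; every model in a sweep is evaluated on
exactly the same test specimens. `subsample_balanced()` draws exactly `n`
training specimens per taxon and is *nested*: under one seed, the
subsample for size `n` is a subset of the subsample for any larger size, so
learning-curve points differ only by added data. `split_validation()`
carves out 10% of specimens for validation, stratified per taxon with a
floor of one so no taxon disappears from validation at small sizes
(rounding is half-up, stated for exact reproducibility).
`grouped_kfold()` partitions specimens into k folds stratified by taxon
(per-taxon counts differ by at most one). `run_cv()` holds out each fold in
turn and applies the same validation carve-out inside the fold.

The desk-scale reference experiment (`desk_experiment()`) uses 8 taxa × 30
specimens with sinking speeds drawn from a narrow range so each specimen
yields roughly 14–27 frames, a fixed test set of 10 specimens per taxon,
and sweep sizes {2, 5, 10, 20}; it completes in about two minutes on one
CPU. Synthetic frames for it are rendered at 496×496 px (the generator's
default sensor is 700 px tall, which also exercises the greater-height crop
branch). These sizes are the package's standard small configuration; the
same machinery scales to a 16-taxon, 60-specimen archive unchanged.

## What the generator emulates — and what it does not

`make_taxon_specs()` builds a community of parameterized taxa: body area
(log-normal across specimens, CV 0.2 by default), a superellipse body
(exponent 2.5) with elongation 1.2–3.4, up to six thin radial appendages,
silhouette darkness, texture noise, and a sinking speed. For a 16-taxon
community the sinking speeds reproduce the empirical mean image counts per
specimen of a real freshwater archive (16–360 at the default
`frames_base = 360`), and base areas are log-spaced over 0.5–25 mm², an
order-of-magnitude span.

Within a specimen's sequence, frames vary by an in-plane tumbling rotation
(random walk, step SD 10°), downward drift, per-frame sensor noise, and —
importantly — an out-of-plane tumbling phase: the apparent body width
oscillates between the full minor axis and the body thickness (0.6 of the
minor axis), with the second camera a quarter turn out of phase. This makes
viewing angle, not specimen identity, a dominant source of single-frame
ambiguity, which is exactly the regime in which voting across a specimen's
frames repairs the errors of individual images. Without it, synthetic
per-frame errors are specimen-correlated and no aggregation rule could beat
per-image accuracy — a qualitatively wrong model of the instrument.

Determinism is strict: each specimen's random stream is seeded by a stable
hash of `(master seed, specimen id)`, so output is independent of
generation order and byte-identical across runs (PNG output included). The
per-pixel noise uses the Kinderman–Ramage normal sampler, which is
considerably cheaper per draw than the default inversion method at equal
quality; the sampler choice is recorded in the seeded state.

The generator does **not** emulate: real morphology or texture (a
superellipse is not a caddisfly), optics (depth of field, motion blur),
debris and multi-specimen frames, color, or specimen damage. Tests passing
on synthetic data therefore demonstrate that the *pipeline* — measurement,
splitting, training, voting, evaluation — behaves correctly and that its
qualitative conclusions (learning curves rise; voting helps most when data
are scarce) hold in the intended regime. They do not certify accuracy
numbers on real archives, which depend on a far richer image model and a
stronger classifier behind the same interface.

## Numerical and degenerate-input choices

* Otsu's threshold maximizes between-class variance on a 256-bin histogram;
  "foreground" means strictly darker than the threshold.
* Uniform (constant) frames produce no foreground and raise
  `specvote_no_blob`; callers drop the frame and count it.
* `precision_recall()` reports a class that was never predicted as
  precision 0 with an explicit `undefined_precision` flag (and likewise for
  recall of a class absent from the test set), keeping macro means
  conservative and auditable rather than silently dropping classes.
* 95% confidence intervals on macro precision/recall are t-intervals across
  the per-taxon values, clamped to $[0,1]$. They quantify spread across
  taxa, not resampling variance — the cross-validation harness measures the
  latter.
* All argmax decisions break ties toward the lowest index; majority-vote
  ties consult summed scores first. Every such rule is deterministic.
* Validation-set sizes use round-half-up; random draws sort their candidate
  pools before sampling so results do not depend on manifest row order.

## Known limitations

The reference scorer is linear; its per-frame ceiling on strongly
foreshortened (edge-on) frames is well below what a convolutional model
achieves on real images, which is why desk-scale absolute accuracies are
far below the headline numbers attainable with a large pretrained CNN on
the real archive. The learning-curve experiment trains one model per size
(variance is assessed by the separate cross-validation harness and by
repeating the experiment across master seeds, not by resampling inside the
sweep). Frame-level dropout of failed detections is counted but not
imputed.
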