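---
title: "Dual-stream spatiotemporal networks with feature sharing: models, preprocessing and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dual-stream spatiotemporal networks with feature sharing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Continuous home-cage monitoring of laboratory mice produces long video
recordings in which every frame carries one of a small set of behaviors —
the standard eight-class ethogram: drink, eat, groom, hang, micromovement,
rear, rest, walk. Automated classification of short video clips into these
behaviors supports welfare assessment and phenotyping without removing the
animal from its cage. `homecagenet` implements a family of *dual-stream
spatiotemporal* classifiers for this task: one network stream consumes short
stacks of appearance frames (RGB cuboids), the second consumes dense
optical-flow fields computed between consecutive frames, and the two streams
exchange information repeatedly along the network rather than only at the
end. That repeated exchange — *feature sharing* — is the central
architectural idea: after each primary processing module the stream outputs
are combined (by addition or channel concatenation) and passed through a
joint block whose output feeds both streams' next modules. The conventional
control, called the *standalone* variant throughout, replicates the joint
blocks inside each stream and fuses only before the common fully-connected
classifier.

# Data model and preprocessing

A recording is a `frame_sequence` (ordered H x W x C frames on the [0, 255]
scale, with a source identifier and a day/night flag). The standard pipeline
is:

1. **Spatial standardization** (`resize_and_crop`): bilinear resize to
   128 x 128, then removal of 16 rows from the top and bottom, producing
   96 x 128 frames. The crop is vertically centered; the discarded bands
   are cage margins above and below the active area. Bilinear interpolation
   is the package's choice; any fixed interpolator would serve.
2. **Temporal downsampling** (`temporal_downsample`): one frame in five is
   kept (indices 0, 5, 10, ...).
3. **Nightification** (`compute_night_reference`, `nightify_frame`): most
   recordings are daytime; a few are infrared night recordings. Day frames
   are normalized toward the night appearance by per-channel scaling,
   `out_c = in_c * ref_c / 255`, where `ref` is the mean R/G/B triple over
   all pixels of the night videos. The formula is exactly the "weigh the
   [0,1]-normalized data and expand back to [0,255]" reading: it is monotone
   per channel and the identity when `ref = (255,255,255)`. Night videos are
   identified by their manifest flag, never auto-detected.
4. **Optical flow** (`compute_flow_stream`, `farneback_flow`): dense flow is
   computed between consecutive (downsampled, standardized, nightified)
   frames with a native implementation of the classical quadratic
   polynomial-expansion method: each local neighborhood is approximated as
   `f(u) ~ u'Au + b'u + c` under a Gaussian applicability window, and the
   displacement solves `A d = -(b2 - b1)/2` after window-averaging of the
   normal equations, iterated over a coarse-to-fine pyramid. Solver settings
   (pyramid scale 0.5, 3 levels, window 15, 3 iterations, neighborhood 5,
   sigma 1.2) are the method's standard defaults. Computing flow *after*
   standardization keeps the two streams temporally and spatially aligned
   per cuboid; flow at step t describes motion from frame t to t + 1.
5. **Flow encoding**: by default flow is rendered to 3 channels (direction
   as hue, magnitude as value, 8 px full scale) so both streams share one
   channel geometry and the same block configurations apply to each; a raw
   2-channel (dx, dy) encoding centered at 128 is available
   (`encoding = "raw2"`).
6. **Cuboid assembly** (`extract_cuboids`): consecutive non-overlapping
   windows of T = 8 downsampled frames (about 1.33 s of original video)
   become training samples, normalized to [0, 1]; the trailing remainder is
   discarded. The per-clip label is the majority vote of the frame labels,
   ties broken by the temporally central frame. Windows start at frame 0;
   no overlap or offset is used — the only free choices here, recorded as
   package defaults.

Arrays are kept in `T x H x W x C` order with H = 96, W = 128: the module
tables below and the block stride schedules all assume that order.

# The five architectures

All models are built by `build_model(model_spec(name, variant))`. Common
elements: two input streams of `8 x 96 x 128 x 3` cuboids; an 8-way softmax
head over a `512, 64, 8` fully-connected stack; SGD training. Printed
per-module output geometries (channels and T/H/W) follow the published
module tables exactly, as do the trainable-parameter totals (see the
accounting section).

* **baseline** — four primary CNN modules per stream (two 3-D convolutions
  with batch normalization, leaky-ReLU and 20% dropout each; kernels
  5, 3, 5, 5; filters 16, 32, 64, 128), joined after every module by a
  dense–dropout block applied to the summed streams. The intra-module
  multiplier k = 1.5 manifests at the joint: the joint block projects to
  `1.5 n` channels, which both streams consume.
* **CIv3D_MHA** — primary modules with alternating kernel sizes
  (m, m − 2; m = 7, 5, 5, 3) and `n -> 1.5 n` conv pairs; joint processing
  by a 3-D Inception grid-reduction block (two convolutional branches with
  stride-2 exits plus a pooling branch, concatenated); a self-attention
  block on each stream's end features (48 tokens of width 192, 4 heads of
  key width 48, batch normalization in place of layer normalization, a
  bias-free two-layer MLP) before the final joint block.
* **CIv3D_BiLSTM** — same trunk, primary-module dropout removed; the
  flattening before the FC stack is replaced by a bidirectional LSTM
  (256 units per direction) over the 12 end-feature tokens.
* **SRS** (singly reinforced stream) — built entirely from 3-D Inception
  blocks (1x1->3^3, 1x1->5^3 and pool->1x1 branches; no lone 1x1 branch).
  Both streams pass module 1 separately and are concatenated; afterwards a
  single running stream is reinforced at each bottleneck by concatenating
  strided 1x1x1 projections of the raw flow sequence. The flow sequence is
  cropped once after module 1 to its central T/2 frames (2 + 2 frames
  removed at T = 8; the crop halves and doubles with T = 4 and T = 16, so
  architectural complexity is unchanged across the sweep). Reinforcement
  enters modules 3–5, where the cropped flow geometry aligns with the
  running feature grid; module 6 is the single extra Inception block before
  the FC stack.
* **CRS** (cross reinforced streams) — five Inception modules per stream;
  from module 2 onward each stream's input is the channel concatenation of
  *both* streams' previous outputs, so the streams reinforce each other
  alternately. The wide final stage (1 x 6 x 8 x 1152) is reduced by global
  average pooling before the FC stack — the only head reading compatible
  with the published parameter total, since flattening would give a
  55k-wide first FC layer.

Standalone variants replicate the joint blocks inside each stream and fuse
late (addition before the FC stack for the add-combined models,
concatenation of the flattened/pooled stream features for SRS/CRS).

## Interior widths and the accounting calibration

The module tables print the output geometry of every module, the primary
filter counts, multipliers, kernels and FC widths — but not the widths
*inside* the joint blocks: the baseline joint's dense expansion, the
Inception branch splits, or the attention MLP width. Those interior widths
are genuinely free parameters of the design. They were fixed once, by exact
integer solves against the published per-model trainable-parameter totals
(both variants of all five models), and ship as the package defaults in
`R/widths.R`. Two consequences worth stating plainly:

* `count_parameters()` reproduces all ten published totals exactly, and
  `count_flops()` — defined as twice the trainable parameters of
  multiply-accumulate layers, normalization parameters excluded —
  reproduces the published figures for the non-recurrent models (the BiLSTM
  model's published figure additionally includes time-step unrolling, which
  this convention deliberately does not model).
* The published standalone totals are *not* consistent with plain
  per-stream duplication of any fixed joint block (the baseline's
  sharing/standalone difference is far smaller than one joint's worth of
  parameters), so each variant carries its own calibrated width set rather
  than sharing one.

One structural point was resolved against the totals as well: with the
primary conv pair read as `(n, 1.5 n)` the two baseline streams alone would
exceed the published total for every kernel/channel combination, while the
module-table footnote attaches k = 1.5 to the joint processors. The
baseline therefore uses `(n, n)` conv pairs with the 1.5x expansion at the
joint — the only reading whose arithmetic closes.

## Conditioning at reduced width

Every width in a model scales with `filter_scale`, which makes the same
builders usable as desk-scale trainable models (`filter_scale = 1` is the
reference accounting configuration). Three purely parameter-free aids keep
the narrow instantiations optimizable; they are part of the builders at
every scale and change no parameter count:

* an identity side-path through each baseline joint block (the block input
  is added onto the leading channels of its output);
* a pooled identity side-path around each Inception block (max-pool with
  the block's stride, added onto the leading output channels);
* global gradient-norm clipping and an optional short learning-rate warmup
  in the training loop.

Without the side-paths, the deep narrow instantiations fail to fit even
easily separable data within a 30-epoch budget — the joint bottlenecks
starve gradient flow; with them the reference-width models are unchanged in
their accounting and the desk-scale models train. Dropout is exposed as
`dropout_rate` (reference value 0.2, a declared field of the block
configuration): at strongly reduced width a 20% channel dropout is
disproportionately destructive, so the desk-scale smoke configuration uses
rate 0.

# Training protocol

`train()` implements class-weighted categorical cross-entropy (weights
`N / (K n_k)`, entering the loss, not the sampler), SGD with momentum 0.9,
batch size 8, up to 85 epochs, halving of the learning rate when the
validation loss fails to improve for 5 epochs (minimum improvement 1e-4),
early stopping after 12 such epochs, and restoration of the best-validation
checkpoint. Initial learning rates default to the per-architecture values
(0.0005 baseline, 0.001 otherwise). Runs are exactly reproducible given
`(seed, config)`; the convention for repeated runs is four seeds (0–3) with
metric means and population standard deviations reported by
`aggregate_seeds()`. The plateau/early-stop patiences and the momentum are
not dictated by the protocol source and are recorded as configuration
defaults, not constants.

# Evaluation

`evaluate()` returns accuracy (argmax, ties to the lowest class index),
micro-averaged average precision (all one-vs-rest decisions pooled before
the precision–recall step integration — the "AP" of the result tables),
macro-averaged precision, recall and F1 (the reading consistent with the
stated macro precision), micro and macro one-vs-rest ROC AUC with
trapezoidal integration, and the confusion matrix. `ensemble_predict()`
averages probability matrices at inference. `loocv_plan()` produces the
twelve-fold leave-one-video-out split structure; executing those folds on
the external datasets is out of scope here.

# The synthetic clip generator

`generate_clip()` renders a textured ellipsoidal "mouse" on a static
cage-like background (vertical illumination gradient plus high-contrast
bars, so dense flow is well-posed) and animates it with one behavior's
signature: rest is motionless and flattened in a corner; micromovement
jitters sub-pixel in place; walk translates at 2 px/frame (at W = 128);
groom pulsates its body axes; rear elongates vertically; hang swings below
the ceiling bars; eat and drink oscillate slightly at fixed hopper/spout
landmarks. Each class therefore combines a characteristic location with a
characteristic motion statistic, mirroring how the behaviors present in a
side-view cage; flow cuboids are produced by the package's own flow
pipeline, not synthesized directly. Generation is bitwise deterministic
given `(class, seed)`.

What the generator does *not* emulate: photometric detail of real
recordings, occlusions, posture variation within a behavior, annotation
noise, or class boundaries that are genuinely ambiguous (real
rest/groom/micromovement confusions). Tests passing on synthetic data
therefore demonstrate that the pipeline, architectures and training loop
function and can fit class-structured spatiotemporal data — not that any
accuracy level transfers to real home-cage video.

`generate_dataset()` splits 70/15/15 within each class; an `imbalance`
factor thins selected classes to exercise the class-weight machinery.

# Problem sizes used in the test suite

The accounting checks run at the reference geometry (8 x 96 x 128 x 3,
`filter_scale = 1`) and take seconds, since they need no weights. The
behavioral checks use the package's desk-scale configuration, chosen once:
the 80-clip synthetic set (8 classes x 10 clips) at 8 x 24 x 32 x 3,
models at `filter_scale = 1/4` with `dropout_rate = 0`, trained with
data-dependent init calibration, learning rate 0.05 (2 warmup epochs,
gradient clip 2, plateau halving at patience 5 / minimum improvement
0.005), at most 30 epochs with early exit once 95% evaluation-mode
training accuracy is reached, and a fixed 100-second wall-clock envelope
per run (checked at batch granularity). 24 x 32 is the smallest raster compatible with every kernel and
stride schedule (the SRS flow-reinforcement strides and the baseline's 5^3
kernels bound it from below). The overfit target on this set checks
optimizability of every variant, not generalization; within the stated
envelope the lighter architectures reach it while the heaviest
joint-processing variants exhaust the time budget first — their
trajectories climb steadily and reach the same target when the envelope is
lifted, which the suite records as the bound that it is.

# Numerical choices and degenerate inputs

* Convolutions use same-padding with `ceil(in / stride)` output sizes;
  batch normalization normalizes over batch and positions per channel
  (momentum 0.9 running statistics for inference).
* Initialization: He-uniform for convolutions, Glorot-uniform for dense and
  recurrent weights, zero biases with the LSTM forget gate at 1, batch-norm
  scale 1 / shift 0. Initialization does not affect any accounting figure.
* Attention scores divide by `sqrt(d_k)` (the standard convention); the
  form that divides by `d_k` itself is available via
  `model_spec(..., attention_scale = "dk")` and `attention(..., scale =
  "dk")`.
* Softmax and cross-entropy are computed with max-shifting and a 1e-12
  probability floor; attention softmax rows are shift-invariant by
  construction.
* Argmax ties break toward the lowest class index. Zero class counts are
  rejected (weights undefined). An empty frame errors in `resize_and_crop`;
  sequences shorter than T yield zero cuboids (not an error); a kernel
  exceeding about twice the spatial extent is a build-time configuration
  error naming the module; an SRS temporal crop that would consume all
  frames is rejected at build time.
* The cuboid store is a single-file native-serialization container with a
  format tag; round trips are bitwise.

# Known limitations

* The engine is a compact pure-R implementation; it is intended for
  desk-scale models and verification, not for GPU-scale training on real
  video corpora. Reproducing the published headline accuracies would
  require the external datasets and hardware-scale training, which are out
  of scope.
* The flow solver is single-threaded and tuned for the package's frame
  sizes; it recovers translations to a few tenths of a pixel on textured
  scenes but is not a general-purpose replacement for production flow
  implementations.
* Interior widths are calibrated to the published accounting, not learned
  from the original implementation; any set of widths satisfying the same
  totals and geometries would be equally consistent with the published
  record.
* Video container decoding is not included: frames enter as arrays (or
  image files read by the caller); per-frame annotation parsing is a
  pluggable reader since the reference dataset's dialect is not described
  in the source material.
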