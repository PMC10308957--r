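---
title: "Multistage knowledge distillation for lightweight lesion detectors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multistage knowledge distillation for lightweight lesion detectors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Plant-disease diagnosis in the field needs detectors that run on small,
cheap devices: drones, phones, edge boxes. Accurate anchor-based one-stage
detectors of the YOLO family carry tens of millions of parameters; pruning a
detector down to mobile size usually costs a large fraction of its accuracy.
`leafdistill` implements the remedy this package is built around:
**multistage knowledge distillation (MSKD)**. A large frozen *teacher*
detector supervises a lightweight *student* at three stages —

* a **backbone distiller** that makes the student's four extraction-stage
  feature maps imitate the teacher's (local optimization: gradients reach
  only backbone parameters);
* a **neck distiller** doing the same for the four fused FPN+PAN features
  (reaching neck *and* backbone);
* a **head distiller** that aligns the student's decoded predictions with
  the teacher's at every anchor position (reaching the whole network).

A supervised **detection module (DM)** trains against the ground-truth
labels at the same time. The combined objective is

$$
L = \alpha\,L_{\mathrm{backbone}} + \beta\,L_{\mathrm{neck}}
  + \theta\,L_{\mathrm{head}} + \gamma\,L_{\mathrm{DM}},
$$

with reference weights $\alpha = 10^{-5}$, $\beta = 10^{-8}$, $\theta = 1$,
$\gamma = 0.5$ (the package defaults, see `stage_loss_weights()`).

## The head stage: diversity knowledge transfer

One-hot detection labels carry no information about *negative* classes, yet
visually similar diseases (two rust-like classes, two gray-spot-like
classes) are exactly where lightweight models fail. The teacher's class
scores are never exactly zero, so its score vector encodes between-class
structure. The head loss
$$
L_{\mathrm{head}} = \omega_1 L_{\mathrm{DKT}}(S_{cls}, T_{cls})
 + \omega_2 L_{CE}(S_{obj}, T_{obj})
 + \omega_3 L_{CIoU}(S_{box}, T_{box})
$$
transfers that structure: `dkt_loss()` is a soft-target cross-entropy over
*all* classes at *all* aligned anchor positions, `soft_ce()` matches
objectness, and `ciou_loss()` matches the decoded boxes. The supervised DM
loss has the same three-term shape with one-hot labels and the binary
cross-entropy (`dm_loss()`).

Two readings were open and are resolved as follows. The cross-entropies are
realized **per class with sigmoid scores** (not softmax): the heads are
multi-label sigmoid heads, and per-class BCE covers both the soft and the
supervised form. There is **no temperature parameter**. Head distillation is
**dense** over all aligned positions of all four levels by default
(`head_positions = "all"`), because dense matching is what exploits the
teacher's negative-class scores; a flag restricts it to label positives.

## The feature stages: focal and global imitation

The backbone/neck distillers are reconstructed from the cited
focal-and-global feature-imitation design; only its name is fixed by the
method, so the internals here are this package's own (configurable)
reconstruction:

* **Focal term** — a squared feature difference weighted three ways:
  a foreground/background mask from the scaled ground-truth boxes
  (foreground cells weighted by the reciprocal cell-area of their smallest
  covering box; background cells share one unit of weight), the teacher's
  spatial attention ($HW \cdot \mathrm{softmax}$ of the channel-mean
  absolute feature at temperature $T$), and the teacher's channel attention.
  An L1 attention-imitation term pulls the student's attention maps toward
  the teacher's.
* **Global term** — a squared difference between a shared relation operator
  applied to both feature maps; the default operator is a small context
  block (global average pooling and two pointwise transforms with shared,
  seed-fixed parameters), with plain pooling available.

Defaults: temperature 0.5, sub-loss weights (fg, bg, attention, global) =
(1e-3, 5e-4, 5e-4, 5e-6). Students are narrower than the teacher, so a
trainable pointwise adapter bridges the channel mismatch at each tap; the
adapter belongs to the student side and is updated jointly.

The stage scoping is structural, not asserted: gradients are injected at the
tap nodes, so the backbone loss *cannot* touch neck or head parameters.
`gradient_scope_report()` verifies the contract by backpropagation.

## Architectures and the structural audit

The teacher is a YOLOR-style detector: CSP backbone with four extraction
stages, SPP, three top-down (FPN) and three bottom-up (PAN) fusion stages,
and four anchor-based heads with implicit additive/multiplicative knowledge
vectors. Four students are built by two lightweighting strategies:
Efficient-Block students (`yolor-light-v1/v2`, pointwise-reduce + 3x3 blocks
with residuals kept, most 1x1 up/down-scaling convs removed) and
Mobile-Block students (`mobile-yolor-v1/v2`, sequential
expand/depthwise/project blocks with H-Sigmoid activations; v2 re-enables
squeeze-excitation on the eleven deepest blocks).

The published record of these models consists of a convolution census over
backbone+neck (counts of 1x1, 3x3, depthwise and pointwise layers) and
parameter totals at the 17-class configuration. Those counts pin the block
structure exactly; channel widths are not published, so the shipped configs
were tuned once so that `conv_census()` matches the census exactly and
`count_parameters()` matches the printed totals at their 0.1M precision.
`estimate_flops()` reports analytic FLOPs under both the 2-FLOPs-per-MAC
(default) and 1-MAC conventions; the input resolution behind the published
GFLOPs figures is not stated (and two tables disagree for one model), so
the audit prints computed values and asserts nothing.

Normalization layers are omitted throughout (convolution + bias only): at
desk scale this keeps training deterministic, makes the frozen-teacher
contract exact, and removes batch-statistics ambiguity; census and
parameter-total constraints are unaffected (the census counts convolutions
only, and width tuning absorbs the small parameter difference).

## Detector conventions

* Boxes are continuous center-form `(cx, cy, w, h)`, origin top-left,
  corners closed intervals; IoU of two degenerate boxes is 0.
* CIoU loss is `1 - IoU + rho^2/c^2 + alpha*v` with the aspect penalty
  `v = (4/pi^2)(atan(w_t/h_t) - atan(w/h))^2` and `alpha = v/((1-IoU)+v)`;
  its analytic gradient (`ciou_grad()`) keeps the full dependence of
  `alpha` on the prediction, so it matches numeric differentiation.
* The head decode is the YOLOv4/YOLOR-family power decode:
  `cx = (2*sigma(tx) - 0.5 + col)*stride`, `wh = (2*sigma(twh))^2 * anchor`.
  The teacher family fixes this choice; it is exactly invertible for
  assigned positions (`encode_box()`), which the tests exploit.
* NMS is greedy, hard, per-class; evaluation uses IoU threshold 0.65 and
  score threshold 0.001.
* Anchors: 12 `(w, h)` priors estimated by seeded k-means++ / Lloyd on box
  sizes, Euclidean metric by default (the plainest reading; a 1-IoU metric
  is one flag away), area-sorted and split 3-per-level over the 4 heads.
  The packaged prior file ships 12 pairs from multi-crop disease data.
* Target assignment is ratio-based multi-anchor matching (bound 4.0,
  exclusive, which keeps every assignment encodable) with the two nearest
  neighbor cells, the training convention of the teacher's family.
* AP uses COCO-style 101-point interpolation by default (11-point is
  available); classes absent from the ground truth are excluded from the
  mean; a detection whose IoU *equals* the threshold counts as correct.

## Desk-scale training recipe

The reference optimizer is kept: SGD, momentum 0.937, weight decay 0.0005,
batch 12. Everything below is the package's own desk-scale choice, made for
short schedules on one CPU and then frozen:

* **Prior bias initialisation** of the head conv (objectness bias -4, class
  bias -2): the standard rare-object initialisation; without it most of a
  short schedule is spent suppressing the initial objectness flood.
* **Per-level objectness balance** (4, 1, 0.4, 0.1) with per-level means,
  so fine-level (small-lesion) gradients are not swamped by the coarse
  grids; detection-term gradients are scaled by the batch size (the loss
  *values* stay batch-mean), the convention of the reference family.
* **Learning rate** 0.01 with one warmup epoch and cosine decay;
  **gradient clipping** at global norm 20. Higher rates train faster on
  some seeds but stall or collapse on others at these widths; 0.01 was the
  largest rate that trained smoothly on every seed probed, and it is frozen.
* **Detection-term balance** `(w1, w2, w3) = (2, 1, 1)` for both the DM and
  the head distiller in the desk recipe (`distill_weights()` keeps the
  conventional `(0.5, 1, 0.05)` as its neutral default): with only a few
  thousand optimizer steps, the class and box terms need larger relative
  weight to converge at all. The same triple is used for plain and
  distilled training, so comparisons are like for like.
* `train_plain()` optimizes `gamma * L_DM` (not bare `L_DM`), so a
  distillation run with `alpha = beta = theta = 0` reproduces the plain
  run step for step — a tested equivalence.

## The synthetic benchmark

`generate_synthetic_dataset()` emulates the structure of multi-crop
disease-detection data without any download: textured green leaf
backgrounds (low-frequency color modulation, vein streak, pixel noise),
1-3 lesion-like blobs per 64 px image from 6 classes — two visually similar
pairs (`rust_a/rust_b`, `spot_a/spot_b`, separated only by a faint ring and
small color offsets) and two distinct classes — and a configurable fraction
of images with two disease classes, default 0.74%, the rarity reported for
real multi-disease data. Boxes are the tight extent of the rendered lesion
mask. A corruption option inflates the recorded label size of a fraction of
records by a factor in [1.5, 3] and scales the stored boxes to match —
exactly the invertible error the cleaning pass (`clean_labels()`: rescale,
clip, drop) must repair, giving the cleaning tests an exact ground truth.
Generation is fully seeded and byte-deterministic (pixels are quantized to
8-bit so in-memory images equal the PNGs).

What the generator does *not* emulate: real leaf geometry, occlusion,
lighting, scale variation beyond 64 px, label noise other than the size
error. Passing the benchmark therefore shows the machinery is correct and
the method directionally effective at desk scale — not field performance.

The standard benchmark (`run_benchmark()`) uses 600 train / 150 test
images. A tiny width-scaled teacher/student pair (`build_tiny_pair()`,
scale 0.1) preserves the 4-stage/4-neck/4-head topology so every distiller
attaches unchanged. The teacher is trained on the synthetic set itself —
long enough to be clearly stronger than any short-schedule student, because
a teacher at or below student strength has nothing to transfer and the
framework presumes a proficient teacher — then frozen; per seed, a student
is trained twice from identical initialisation, plain vs distilled, and
compared by held-out mAP@.5. Problem sizes (hundreds of thousands of
parameters, tens of epochs rather than hundreds) are chosen so the whole
experiment runs on one CPU in minutes; the suggested hundreds of epochs for
the tiny teacher would add nothing but wall-clock at these widths.

## Known limitations

* The CNN engine is single-threaded, CPU-only R/Rcpp; it exists to make the
  method exercisable and testable end-to-end, not to be fast.
* No augmentation, EMA, or mixed precision; the desk recipe is deliberately
  minimal.
* Absolute mAP values on the synthetic benchmark are small (undertrained
  tiny models by design); only structural numbers, oracle identities, and
  the plain-vs-distilled comparison are meaningful quantities.
* The feature-distiller internals are a faithful reconstruction of the
  cited design's published description, not a numerical reproduction of any
  particular implementation.
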