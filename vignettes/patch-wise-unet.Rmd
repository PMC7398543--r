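---
title: "Patch-wise U-net brain tissue segmentation: model, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Patch-wise U-net brain tissue segmentation: model, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(patchunet)
```

## The problem and the method

Quantifying brain structure from T1-weighted MRI requires assigning every
voxel to background, cerebrospinal fluid (CSF), grey matter (GM) or white
matter (WM). `patchunet` implements a patch-wise variant of the U-net for
this task: instead of feeding whole 256×256 slices to the network, each
slice is tiled into non-overlapping patches (four 128×128 tiles at the
defaults), the network is trained on and applied to the tiles, and the tile
outputs are stitched back into a full-slice label map. Because the tiling
is exhaustive and disjoint, every pixel is used exactly once — unlike
random-patch schemes — and the smaller input keeps memory modest while
letting the filters concentrate on local structure.

The pipeline is: plane extraction → centred zero-padding to a square canvas
→ per-volume intensity normalization → patch tiling → per-patch softmax
segmentation → score stitching → per-pixel argmax → unpadding back to
native geometry. Each stage is a small, separately tested function, and
each is exactly invertible where it should be (pad/unpad, split/stitch,
one-hot encode/decode).

## Architecture

`unet_spec()` describes the network declaratively; `build_unet()`
instantiates it and emits a layer-record table that mirrors the network
exactly. At the defaults (patch 128, base width 64, depth 3, 4 classes):

* encoder: 3 stages of [3×3 conv, ReLU] ×2 then 2×2 max pool, widths 64 →
  128 → 256, spatial size 128 → 64 → 32 → 16;
* bottleneck: two 3×3 convolutions at 512 filters on the 16×16 map;
* decoder: per stage, ×2 nearest-neighbour upsampling, a 2×2 convolution
  halving the width, concatenation with the same-resolution encoder map,
  and two 3×3 convolutions;
* head: 1×1 convolution to 4 channels, per-pixel softmax.

All convolutions use "same" padding and carry biases; the closed form
(k·k·c_in + 1)·c_out then reproduces each layer's parameter count and a
total of 7,696,388, which the package asserts against the actual allocated
arrays.

Two readings of the published operation tallies had to be reconciled:

* **Up-convolution.** The layer table separates a zero-parameter upsampling
  layer from a following 2×2 convolution whose counts match
  (2·2·c_in + 1)·c_out — e.g. 524,544 = (4·512 + 1)·256. This is only
  consistent with *upsample-then-2×2-conv*, not with a strided transpose
  convolution, so that is what is implemented. A 2×2 "same" convolution on
  an even grid anchors at the top-left (output size equals input size),
  which fixes shapes and counts independent of any framework convention.
* **Convolution count.** The coarse operation summary (15 convolutions)
  undercounts the detailed 18-row layer table; the detailed table is taken
  as authoritative, and the builder reproduces it row by row.

## Training

`train_config()` defaults to the published optimizer setting: plain SGD
with learning rate 0.001 and momentum 0.99, minimizing categorical
cross-entropy (mean over pixels and batch) against the one-hot target
stack, with **no data augmentation**. Settings the source leaves open are
config-exposed with these defaults:

* *batch size 32, epochs 50* — unstated upstream; both are schedule knobs,
  not model properties (the desk-scale checks use 8 and 30, see below);
* *initialization* — only "a normalization technique" is referenced;
  He-normal is the default as the standard choice for ReLU stacks, with
  Glorot-uniform selectable;
* *no validation split by default* — none is described; an optional
  held-out fraction exists but only gates early stopping when explicitly
  enabled;
* *intensity scaling* — unstated; per-volume min–max to [0, 1] is the
  default (stable under SGD at lr 0.001 without per-dataset tuning),
  z-score selectable;
* *one model per plane* — whether a single model served all three
  anatomical planes is not stated; the CLI trains per plane.

Determinism: given a seed, weight initialization and epoch shuffling are
fully reproducible, so two runs produce identical loss traces and weights
(asserted bitwise in the tests). With learning rate 0 the weights are
unchanged after an epoch, which the suite also asserts.

## Tiling and stitching

Patch grids record their 0-based row-major offsets, canvas shape and
stride, making them serializable and exactly invertible. Non-overlapping
stitching validates that the tiles partition the canvas. For the
overlapping (strided sliding-window) harness the combination rule is not
defined upstream; the package uses the per-pixel **mean of class scores
over covering patches, before argmax** — the standard variance-reducing
choice — and with stride = P it reduces bit-exactly to the non-overlapping
path. Anchors that the stride does not reach are not force-included by
default (`include_edges` adds them), keeping patch counts analytic:
⌊(H−P)/s⌋+1 per axis, e.g. 17×17 = 289 for a 256 canvas, 128 patch,
stride 8. The published per-slice counts for this harness (32 at stride 8,
258 at stride 1) are not consistent with any 2D sliding-window enumeration
on that geometry; the standard enumeration is implemented and the
discrepancy simply documented.

Argmax ties in `decode_onehot()` break toward the lowest class index:
deterministic, and background-favouring on exact ties.

## Preprocessing geometry

Zero-padding centres a slice on the canvas, with odd remainders placed at
the bottom/right (the published cases are all even, but a rule is still
required); labels pad with background. The recorded amounts make
`unpad()` an exact inverse. The two reference geometries pin the
behaviour: 208×176 → 24 rows top/bottom + 40 columns left/right; 128 rows
→ 64 top/bottom.

Training-slice selection keeps `count` indices at constant `interval`
(48 and 3 canonically), centred via
`start = floor((n − 1 − (count−1)·interval)/2)`: the published setting
fixes only the count and interval, and centring includes both
information-rich central slices and sparse peripheral ones. Indices are
0-based, as are patch offsets; rows index image height with row 1 at the
top, and all ranges are half-open at the pixel level.

Volume orientation is declared, not inferred: `axis_names` states which
array dimension indexes which anatomical plane, avoiding silent
reorientation of Analyze-format data with ambiguous headers.

## Evaluation suite

Per tissue class (CSF, GM, WM — background is excluded from per-class
reporting), `evaluate_segmentation()` reports Dice and Jaccard overlap and
the Hausdorff distance; the whole map is summarized by the MSE between
integer label maps. Numerical conventions:

* **Empty masks.** Overlap of a class absent from both maps is defined as
  DSC = JI = 1 (perfect agreement on absence) with a `both_empty` flag;
  Hausdorff is undefined there and reported as NA, never silently 0. This
  keeps aggregation over sparse peripheral slices well defined without
  hiding the condition.
* **Hausdorff.** Euclidean distance on integer (row, col) pixel
  coordinates, computed on the *full masks* exactly as the set definition
  reads — no boundary extraction, no 95th-percentile variant. The C++
  implementation is the exact O(n·m) double loop with an early-exit bound;
  the tests cross-check it against an independent R oracle to 1e-9.
* **MSE on labels.** The squared difference of class codes makes the value
  depend on the coding (0, 1, 2, 3 = background, CSF, GM, WM); it is kept
  because it matches how the quantity is defined for segmentation maps,
  and is documented loudly for that reason.
* DSC = 2·JI/(1+JI) holds exactly and is property-tested on random masks.

## The phantom suite

No patient data ship with the package; `phantom_config()` /
`make_phantom_suite()` generate labeled volumes that emulate the *shape*
of the task: stackable 2D slices, four classes, T1-like contrast ordering
(background 0.0 < CSF 0.2 < GM 0.5 < WM 0.8 in normalized units), a smooth
multiplicative bias field (amplitude 0.1 — mild, since the emulated inputs
are bias-corrected), additive Gaussian noise (σ 0.05), and a
spherical-cap head-size profile so central slices carry rich anatomy while
peripheral slices are nearly empty. Geometry per slice: an outer CSF rim,
a GM band with sinusoidal "sulcal" perturbations, a WM core with paired
CSF "ventricles", all jittered per volume. With noise and bias switched
off the intensities take exactly four values, and thresholding at the
tissue-mean midpoints recovers the labels — a closed-form perfect
segmenter the metric suite must score as DSC = JI = 1, HD = 0, MSE = 0.

What the phantom does **not** emulate: anatomical realism, MR physics,
partial-volume voxels, 3D tissue continuity beyond the smooth head
profile, inter-subject anatomy differences, or annotation conventions
(e.g. whether sulcal CSF is labeled). Passing the phantom checks therefore
demonstrates that the pipeline's mechanics — tiling, training dynamics,
stitching, scoring — are correct and learnable end to end; it does not
certify segmentation accuracy on clinical data.

## Desk-scale problem sizes

The package's own verification runs are sized for a single CPU: the
canonical 20-train / 30-test split at canvas 64 with 12 slices per volume;
a reduced network (base width 8, patch 64); 5 training slices per volume
at interval 2 (100 patch pairs); 30 epochs at batch 8; held-out scoring on
the three central slices of six test volumes. Under these conditions
training from three different seeds reaches held-out mean Dice above 0.85
across CSF/GM/WM (the test suite asserts this, and that every trained
model strictly beats its untrained initialization). These sizes are the
package's choice of a convincing-but-small experiment, not a reproduction
of full-scale results on clinical datasets.

## Known limitations

* The engine is CPU-only and single-threaded; full-scale training (dozens
  of subjects at canvas 256, base width 64) is out of its intended range.
* Per-volume min–max normalization is sensitive to single extreme voxels;
  z-score is available where that matters.
* MSE depends on the class coding, as discussed.
* The overlapping-mode aggregation rule and the slice-selection anchor are
  principled choices for under-specified details; both are config-exposed
  rather than hidden.
* Skull stripping, bias-field correction, registration and DICOM ingestion
  are out of scope: the pipeline consumes preprocessed volumes.
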