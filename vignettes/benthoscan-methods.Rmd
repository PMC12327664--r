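---
title: "Methods: grid-point and patch-based annotation of benthic imagery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: grid-point and patch-based annotation of benthic imagery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(benthoscan)
```

## The problem

Benthic habitat surveys from drop-video imagery are conventionally scored by
trained analysts who label a fixed grid of points per frame (point-count
annotation). `benthoscan` implements two automated counterparts of that
workflow for in-house use, where imagery cannot be uploaded to externally
hosted annotation platforms:

* a **grid-point model** that classifies each node of the fixed 8 × 8 grid
  (64 points per image) into one of four consolidated habitat classes —
  unconsolidated substrate, macroalgae, seagrass, reef structure; and
* a **patch presence model** that divides an image into three large
  overlapping patches (left, centre, right) and, for each patch, makes four
  independent presence/absence decisions, one per class.

Because real fishery survey imagery is proprietary, the package also ships a
procedural scene generator that produces imagery with exact per-pixel ground
truth, so every part of the pipeline is testable end to end.

## Label consolidation

CATAMI-broad habitat labels are consolidated before modelling:
`Unconsolidated Substrate (Sand) → 1_UnCon Sub`, `Macroalgae → 2_MA`,
`Seagrass → 3_SG`, and sponge, hard coral, soft coral and consolidated
substrate pooled into `ReefStructure`. The packaged scheme
(`catami_scheme()`) carries exactly this seven-to-four mapping; rare
categories outside it can be marked with an `EXCLUDE` sentinel in the scheme
file, which drops their points from modelling. A conflicting duplicate (one
original label mapped to two targets) is a schema error, never silently
resolved.

## Annotation geometry

Coordinates are 0-based pixels, `x` = column, `y` = row, origin top-left.
The survey grid partitions the image into 8 × 8 equal cells with one point
at each cell centre, `x = floor((col + 0.5) · W/8)`. Where exactly within a
cell manual analysts clicked is not recoverable from point tables, so the
cell centre is this package's convention; it is deterministic and
content-independent. Train/test splitting operates on whole images
(`split_by_image()`), so all 64 points of an image land on the same side —
point-level splits would leak near-duplicate features across the boundary.
`floor(n · fraction)` ids go to training; the split is a partition and is
byte-identical under a fixed seed.

## The grid-point model

The backbone is a residual network in the 50-layer configuration
(bottleneck units of 3/4/6/3 per stage; block output widths
256/512/1024/2048), with one structural modification: the spatial strides of
residual blocks 3 and 4 are reduced from 2 to 1. With the stem contributing
a factor of 4, the cumulative downsampling after blocks 1–4 is 4, 8, 8, 8,
so a 448 × 224 input (images are resized to this frame) yields a final
56 × 28 feature map in which each cell corresponds to an 8 × 8 pixel region
of the input.

Classification is sparse: instead of a dense per-pixel segmentation head,
the caller supplies N pixel coordinates. At each backbone stage the
coordinates are rescaled by the stage's cumulative factor
(`index = floor(coord / factor)`, clamped to the map extent — the cell
*containing* the pixel), the per-block feature vectors at those cells are
gathered and concatenated (3840 features per point at full width), and a
fully connected head (one hidden layer, default width 512) produces C = 4
scores per point, normalised by softmax.

A single-head scaled dot-product self-attention module operates on the
flattened spatial positions of the block-4 map, with a residual connection
(`x + softmax(QKᵀ/√d) V Wo`). Placement is configurable (after block 3,
block 4, both, or none); the default is after block 4 only, which costs one
module while behaving comparably to the two-module variant. The projection
width `d` and the head internals are not constrained further by the
problem, so the simplest standard form is used and exposed in
`backbone_config()`.

### Training regime

Training minimises the cross-entropy loss averaged across all point labels,
with Adam under a one-cycle schedule (warmup over the first 30% of steps,
cosine decay to 1% of the peak). Augmentation applies horizontal and
vertical flips, rotations up to ±10°, and brightness/contrast jitter, with
every geometric transform applied identically to the query coordinates so
labels stay aligned with the pixels underneath them.

A deliberate design choice: the convolutional trunk and attention
projections are randomly initialised (He-normal) and **held fixed**;
gradient training is applied to the fully connected head over the sampled
multi-block features. In the random-features regime the concatenated
multi-scale basis is rich enough that the head alone separates the four
texture classes, and the whole training loop stays deterministic, fast and
dependency-free. The trade-off is honest: nothing adapts the early filters
to a new image domain, which is a real limitation for subtle natural
imagery (see *Limitations*). `backbone_config(pretrained = TRUE)` is
rejected explicitly rather than silently substituting random weights;
trained models round-trip through single-file versioned checkpoints
instead.

## The patch presence model

Patches are 880 × 880 px squares: left flush to `x = 0`, right flush to
`x = W − 880`, centre at `floor((W − 880)/2)`, all vertically centred (the
vertical placement and exact origins are this package's convention). For a
1920 × 1080 frame the three patches overlap and jointly cover the full
width. Images smaller than the patch fall back to `min(W, H)` with a
warning. The reference label of a patch is the OR over the annotated points
it contains, using half-open intervals `[x0, x0+size)` so boundary points
are counted exactly once; a patch containing no points is all-absent and
flagged.

The model pools the trunk's four block outputs (per-channel average and
maximum) into one feature vector per patch and trains a sigmoid head (one
hidden layer, width 512 at full scale) with binary cross-entropy averaged
over the four outputs, so every class carries equal weight regardless of
prevalence. Training is two-stage: stage 1 at 224 × 224 inputs with
augmentation (flips, rotation, random 90–100% crops, photometric jitter),
then fine-tuning of the same head at 448 × 448 inputs — prediction also
runs at the stage-2 resolution. At desk scale the stage-2 pass uses the
un-augmented patches only; the stage-1 statistics are reused to keep the
feature transform consistent across stages. The decision threshold defaults
to 0.5 and is exposed; predictions are monotone in it by construction.

A point-centred 224 × 224 small-patch extraction was considered and
rejected: such patches are zoomed in too far and frequently contain
multiple habitat types under a single point label, so only the large-patch
layout is implemented.

## The synthetic scene generator

`generate_scene()` emulates the properties of survey imagery that the
models actually depend on:

* spatially contiguous regions of four distinct textures (bright smooth
  speckle, dark lobed blobs, thin upright strokes, high-frequency angular
  clutter), produced by warped nearest-seed (Voronoi) regions;
* strong class imbalance — the default weights 0.70/0.15/0.14/0.01 make the
  top three classes carry 99% of annotations, mirroring the imbalance of
  real survey data;
* fragmented, boundary-straddling regions, controlled by `fragmentation`
  (a smooth coordinate-warp amplitude; default 0.2), which reproduces the
  ambiguous-grid-point-at-habitat-boundary error regime;
* exact ground truth: every grid label equals the mask class at its pixel,
  an invariant asserted per scene.

It deliberately does **not** model turbidity, lighting, camera optics,
epiphytic overgrowth, or any photometric property of real sea water.
Passing the recovery tests therefore demonstrates that the machinery —
geometry, sampling, training, evaluation — is correct and learnable, not
that the models reach any particular accuracy on real imagery.

Scene size defaults to 1920 × 1080 so the three-patch 880 px geometry is
exercised at a realistic aspect ratio. Scene `i` of a dataset uses
`seed + i − 1`, making datasets byte-reproducible from one root seed
(`generate_dataset()` manifests hash identically across runs).

## Evaluation

Point predictions are summarised by a confusion matrix (rows = true,
columns = predicted, class order fixed by the scheme), per-class precision
`cm[k,k]/colsum` and recall `cm[k,k]/rowsum`, and overall accuracy
(trace/total). A 0/0 ratio — e.g. the rare reef class never predicted on a
small run — is reported as `NA`, never as 0. Patch predictions report
per-class binary precision/recall, element-wise accuracy (all class-patch
decisions pooled, the "overall accuracy" analogue for the patch model; the
definition is embedded in the JSON report since more than one pooling is
defensible), and patch-wise accuracy (all four decisions simultaneously
correct), which can never exceed the element-wise figure. Reports embed the
configuration fingerprint and seed.

## Numerical and protocol choices

* Coordinate rescaling: floor division then clamp — the containing-cell
  rule; tie-breaks at cell boundaries therefore go to the lower cell.
* Head training: Adam (β = 0.9/0.999, ε = 1e−8), weight decay 1e−4,
  mini-batches of 256, peak learning rate 1e−3 (halved for the patch
  model's fine-tuning stage).
* Features are column-standardised with training-set statistics; the
  statistics are stored in the model and re-applied at inference.
* All randomness (weights, augmentation, batch order, scene content) flows
  from a single root seed through a restore-on-exit seeding helper, so
  training twice with one seed gives identical loss traces and weights.
* Desk-scale protocol used by the tests: 50 scenes at default generator
  conditions (fragmentation 0.2), split 40/10 by image, narrow backbone
  (widths 16/32/64/128, one unit per block, attention width 16, hidden
  width 128), 40 head epochs for the grid model and 30 + 15 for the patch
  model. These sizes are the package's chosen test protocol; the full-width
  architecture is exercised separately for its shape arithmetic.

## Limitations

* The frozen-trunk regime means accuracy on real imagery would depend on
  fine-tuning the convolutional stages, which this package does not
  implement; on procedural textures the distinction is immaterial, on real
  imagery it is not.
* Patch presence labels derive from 64 sparse points, so a class can be
  visible in a patch yet absent from its label (and vice versa at
  boundaries); this label noise is inherent to the point-aggregation
  protocol, not an implementation artifact.
* The rare reef-structure class (1% weight) is frequently absent from small
  held-out sets; its precision/recall are then undefined and reported as
  `NA` by design.
* Dense per-pixel segmentation, bounding-box detection, and abundance
  estimation are out of scope; the patch model states only presence.
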