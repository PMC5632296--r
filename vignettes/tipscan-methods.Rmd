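---
title: "Methods: sliding-window CNN localization of plant features"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: sliding-window CNN localization of plant features}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

High-throughput plant phenotyping needs point features — root tips in 2D
seedling images, leaf and ear tips and bases in shoot photographs — located
automatically in large image sets, so that architectural traits can be
derived and fed into quantitative-genetics analyses such as QTL mapping.
tipscan implements that pipeline as a chain of small, separately testable
stages:

1. **patch datasets** — fixed-size crops centred on point annotations,
   balanced with mined hard negatives;
2. **patch classifiers** — small convolutional networks trained on those
   crops;
3. **localization** — the classifier slid over whole images at a fixed
   stride, producing per-class probability maps;
4. **tip extraction** — thresholding, morphological erosion and connected
   components turn a map into discrete coordinates;
5. **traits** — a per-image vector of geometric descriptors of the tip
   cloud, exported as CSV for downstream QTL software (QTL model fitting
   itself is out of scope).

A synthetic scene generator with exact ground truth makes the whole chain
reproducible without any external data.

## Patch dataset construction

Root-domain crops are stored at 42×42 px around each annotated tip and
randomly sub-cropped to the 32×32 network window during training, so the
tip jitters off-centre by up to ±5 px — the augmentation that lets the
detector respond near, not only exactly on, a feature during scanning.
Shoot crops are stored at 128×128 px and downscaled 2× (area-weighted,
each output pixel the mean of a 2×2 block) to the 64×64 window; the larger
field of view keeps more context around the higher-resolution shoot
features. Root tips whose bearing root is 16 px or shorter (half the
window) are excluded as positives: such stubs are ambiguous with root
hairs.

Negatives are mined at a 2:1 ratio for roots — half at random image
positions, half on the traced root system itself (arc-length-uniform along
the polylines), the hard negatives that teach the network "root but not
tip" — and at a 1:1 ratio for shoots, centred on Harris corner candidates
so clutter is well represented, topped up with a 10% fraction of truly
random positions so plain background appears too. Every negative centre
must lie farther than half a window (16 px root / 32 px shoot) from every
annotation; this mining radius is our choice — it mirrors the radius used
when scoring localization. Border crops are completed by edge replication
rather than discarded, to avoid biasing against image-margin tips.

The dataset is split 80/20 into training and validation by a seeded
shuffle (`floor(0.8 N)` training samples), and the training-set mean
colour is recorded for input centring.

## Network architectures

Both classifiers are plain convolutional stacks of unpadded 3×3 kernels
with ReLU after every layer, 2×2 max pooling between groups, and three
fully connected layers with 50% dropout between them, ending in a softmax.
Unpadded convolutions are chosen so the spatial size reaches exactly 1×1
before the fully connected stack:

* root: conv–conv–pool ×2, conv–conv; trace 32–30–28–14–12–10–5–3–1;
  filters 64→256, doubling after each pool; FC 256–64–2.
* shoot: groups of 2, 3 and 3 convolutions (the counts keep every pre-pool
  size even) with pooling, one final convolution; trace
  64–62–60–30–28–26–24–12–10–8–6–3–1; filters 64→512; FC 512–128–5.

The per-layer filter ramps and the hidden fully connected widths are our
design choices within the stated 64→256 / 64→512 envelopes. `filters_base`
scales all widths together, giving reduced networks for desk-scale
experiments without changing the architecture's shape.

## Training

Mini-batch momentum SGD (momentum 0.9, weight decay 5e-4, batch 64 —
conventional values for this family of networks) under the step schedule:
learning rate 0.1 divided by 10 every 20,000 iterations at full scale.
Inputs are the raw 8-bit values minus the training-set mean colour,
divided by 255. The division is a numerical choice of this implementation:
with fan-in-scaled ("He") initialization, unit-range inputs keep early
activations at order one, which makes the stated learning-rate schedule
stable; without it the first layers saturate and training collapses to
the majority class. Weights are He-initialized; all randomness
(initialization, batch order, augmentation offsets, dropout) derives from
one training seed, so runs are bit-reproducible on a device.

Validation accuracy is measured every `check_interval` iterations.
"Steady state" stopping is codified as: no improvement greater than 0.1
percentage points over five consecutive checks; the best checkpoint is
kept. Non-finite loss aborts with a diagnostic rather than continuing.

## Localization and tip extraction

Scanning applies the classifier to every window whose top-left corner lies
on a stride-4 grid; windows are fully interior (no padding), so the map is
smaller than the image and cell (i, j) maps back to image coordinates as
`origin + stride·(j−1, i−1)` with `origin = window/2` — an exactly
invertible correspondence. Batched evaluation is bit-identical to
classifying one window at a time.

Cells above a likelihood threshold are foreground. The binary heat map is
rendered at image resolution — each grid cell becomes a `stride × stride`
pixel block centred on the cell's image position, which is what the
heat-map overlay figures display — then eroded with the full 3×3
structuring element for 3 iterations (borders count as background).
Surviving regions are labelled with 8-connectivity and each component's
unweighted pixel centroid is a reported tip. The resolution choice is
load-bearing: at stride 4, three pixel-space erosions delete a lone
heat-map cell (a 4×4 block vanishes by the second pass) yet preserve any
response spanning two or more cells — exactly the "remove single-pixel
artefacts without removing tips" compromise the procedure is meant to
strike. Eroding the stride-resolution grid directly instead would remove
every response narrower than 7 cells (28 image pixels) and therefore
almost every genuine detection; we implemented both and kept the
image-resolution form. The threshold defaults to 0.5 and is
config-exposed; the erosion count stays at the prescribed 3.

## Trait vector

From a tip set alone: tip count; convex hull area (shoelace formula over
`chull` vertices; degenerate hulls of fewer than three non-collinear
points have area 0); bounding-box width and depth and their ratio (`NA`
when depth is 0); mean and population standard deviation (n denominator)
of x and y; counts of tips in the 100/200/300-px strips below the seed;
total length estimated as the summed tip-to-seed distances; and the
centre of mass. The seed position is estimated as the mid-point of the top
edge of the tips' bounding box — consistent across images even if crude.
"Mean X/Y" and "Centre of mass X/Y" are computed identically but exported
as separate columns for fidelity to the published trait list. Units are
pixels throughout; physical calibration is a downstream multiplication.

## Evaluation metrics

Classification accuracy is `100 · Σcorrect / Σ(correct+misclassified)`
over the selected classes. Localization is scored per map cell: a positive
cell farther than half a window from every ground-truth feature is a false
positive; a non-positive cell within that radius of some feature is a
false negative; both as percentages of all cells, and
`feature accuracy = 100 − FP − FN` holds exactly before rounding. The
all-in-radius-cells reading of false negatives is implemented literally.
Cells, not image pixels, form the evaluation universe; at stride 1 the two
coincide.

## The synthetic scene generator

Root scenes: dark, slightly curved strokes on a light noisy background
(the growth-pouch analogue), growing downward from a top-centre source
point with laterals branching at random arc positions; every drawn root is
returned as a polyline, and tips of primaries and of laterals longer than
16 px are annotated. Laterals at or below the floor are drawn but *not*
annotated, deliberately reproducing the root-hair ambiguity the negative
mining must handle. Shoot scenes: leaf and ear strokes over clutter bars
and blobs, with the four feature classes annotated and the clutter
unannotated. Scenes are deterministic functions of their parameter set and
seed.

What the generator does *not* emulate: photographic texture, root
overlap/occlusion density of real pouch images, root hairs as actual
texture (only as short unannotated laterals), lighting variation,
perspective. Passing the synthetic study therefore demonstrates that the
pipeline's machinery — data preparation, optimization, scanning geometry,
morphology, traits — is correct and internally consistent, not that the
shipped defaults would reach the same accuracy on real photographs.

## The desk-scale benchmark

`run_synthetic_benchmark()` is the package's standard study, sized for one
CPU. Scenes are 320×320 px and deliberately heterogeneous — 3–5 primaries
of widely varied length (90–230 px, so they end at different depths)
bearing 1–4 laterals each of 35–80 px — so the derived traits vary
between scenes the way they do across a mapping population; without that
between-scene variance a trait correlation would measure detector noise
against nothing. Two geometric conditions make the scenes a
*well-separated-tip* study: `min_tip_separation = 28` px (the erosion
scale; two tips closer than the response-plus-erosion scale merge into a
single detection by construction, which measures crowding rather than
detector quality) and `tip_clearance = 10` px (a tip lying on another
root's path is an ambiguous crossing, not a clean line-end, for any
observer). Both are bounded-retry constraints in the generator, off by
default and enabled here; they leave >90% of nearest-neighbour tip
distances above 24 px at ~13 tips per scene. 150 training scenes give
over 2,000 positive patches; 16 held-out scenes are scanned for
evaluation. The classifier is a reduced-width root network
(`filters_base = 8`, FC 32–8–2) trained with initial learning rate 0.01
decayed by 10 every 1200 iterations, batch 32, for at most 2500
iterations with validation checks every 250. The learning rate and batch
are scaled down with the network width, standard practice when shrinking
a model; the full-scale defaults keep the 0.1 / 20,000-iteration
schedule. Extraction uses the default threshold 0.5 and the prescribed 3
erosion iterations.

Two findings from developing this study are worth recording. Training
*longer* raises centred-patch validation accuracy while *lowering* tip
recall: a sharper decision boundary narrows the spatial response that
scanning and erosion depend on, and validation accuracy simply does not
measure response width. And occluded tips (within a stroke width of
another root) are where the detector degrades first — on real imagery,
where occlusion is common, per-tip recall should be expected well below
the clean-scene figure.

Reported quantities: validation accuracy of the patch classifier; recall
of ground-truth tips by detections within half a window (16 px); spurious
detections as a percentage of ground-truth tips; and the mean Pearson
correlation, across evaluation scenes, between each trait computed from
detected tips and from ground-truth tips.

## Numerical conventions and edge cases

* Coordinates are 0-based, x rightward, y downward; rasters are `(H, W, 3)`
  arrays on the 0..255 scale, 8-bit on disk.
* Even-sized crops centre the feature at index `floor(side/2)`.
* `max.col` ties break to the first class; softmax rows are normalized in
  double precision and sum to 1 within 1e-6 after batching.
* Empty tip sets are valid detector output but an error for trait
  computation and seed estimation.
* Erosion with `iterations = 0` is the identity; labelling an all-false
  mask returns zero components.
* If an image cannot supply the requested number of valid negative
  centres within a bounded number of attempts, fewer are returned with a
  warning rather than an error.

## Known limitations

* The engine is plain R over BLAS: fine at reduced width and desk-scale
  image counts, not at the full 64→256/512-filter scale, which would need
  a GPU framework.
* No rotation/flip augmentation (deliberately: not part of the protocol).
* Tips closer together than the erosion scale (≈28 px at stride 4) can
  merge into one detection; sub-stride refinement is out of scope.
* Scanning is dense; fully convolutional acceleration is out of scope.
* The generic JSON manifest, not any repository-specific layout, is the
  interchange format; RSML import is tolerant and optional.
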