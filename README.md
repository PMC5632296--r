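# tipscan

Sliding-window CNN localization of plant root and shoot features, and the
root-trait table it feeds into quantitative-genetics pipelines.

## The problem

Measuring root system architecture from 2D seedling images — and shoot
architecture from studio photographs of whole wheat plants — hinges on
finding *point features*: root tips, leaf tips and bases, ear tips and
bases. Locating them by hand is the rate-limiting step in phenotyping for
QTL discovery. tipscan automates it:

1. **Patch datasets.** Point-annotated images become balanced
   classification sets: crops centred on each annotation (root tips on
   roots longer than 16 px only), plus mined *hard negatives* — for roots,
   half on the traced root system away from tips and half at random; for
   shoots, Harris-corner candidates in the clutter, topped up with random
   background. Root crops are stored at 42×42 and randomly sub-cropped to
   32×32 during training; shoot crops at 128×128, downscaled to 64×64.
2. **Classifiers.** Small CNNs of unpadded 3×3 convolutions with ReLU, max
   pooling, and three fully connected layers with 50% dropout: filters
   64→256 (root, 2 classes) or 64→512 (shoot, 5 classes), trained by
   momentum SGD under a step schedule (learning rate 0.1, ÷10 every
   20,000 iterations) on mean-colour-centred inputs, with an 80/20
   train/validation split and steady-state early stopping.
3. **Localization.** The classifier scans whole images at stride 4,
   producing a per-class probability map whose cell (i, j) corresponds
   exactly to image pixel `window/2 + 4·(j−1, i−1)`.
4. **Tips.** Cells above a likelihood threshold are eroded (3×3
   structuring element, 3 iterations), labelled by 8-connectivity, and
   each component's centroid is a tip coordinate.
5. **Traits.** Per image: tip count, convex hull area, bounding-box width,
   depth and ratio, mean/SD of tip positions, tip counts in the
   100/200/300-px strips below the estimated seed position (the mid-top of
   the tip bounding box), total length (summed tip-to-seed distances) and
   centre of mass — exported as CSV for external QTL software.

A synthetic scene generator (`generate_root_image()`,
`generate_shoot_image()`) draws annotated root systems and cluttered
shoot scenes with exact ground truth, so the entire pipeline is testable
and reproducible offline. See the methods vignette
(`vignettes/tipscan-methods.Rmd`) for the model details and design
choices.

## Worked example

```r
library(tipscan)

# a synthetic root scene with known ground truth
img <- generate_root_image(root_scene_params(seed = 42))
img
#> <annotated_image 'root_scene_0000000042'> 256x256 px, 31 annotation(s), 31 polyline(s)

# patch dataset: positives + 2x mined negatives, 80/20 split
cfg <- dataset_config("root", rng_seed = 42)
ds  <- build_patch_dataset(list(img), cfg)
table(ds$label)
#> root_negative      root_tip
#>            62            31

# train a reduced-width network on many such scenes (desk scale)
bench <- run_synthetic_benchmark(seed = 1)
glance(bench$model)
bench$val_accuracy_pct    # validation accuracy of the patch classifier, %
bench$tip_recall_pct      # ground-truth tips recovered within 16 px, %
bench$trait_correlations  # per-trait detector-vs-truth Pearson r

# single-image localization with the trained model
map  <- scan_image(bench$model, img, stride = 4)
tips <- extract_tips(map, "root_tip", threshold = 0.5, iterations = 3)
traits <- compute_traits(tips)
write_trait_table(traits, "traits.csv")
```

`run_synthetic_benchmark()` returns the quantities the package is judged
by. At seed 1 it trains on 150 heterogeneous well-separated-tip scenes
(2,114 positive patches plus twice as many mined negatives), reaches
98.3% validation accuracy, recovers 94.2% of ground-truth tips on 16
held-out scenes with zero spurious detections, and the traits derived
from detected tips correlate with traits from the ground-truth tips at a
mean Pearson r of 0.92 across scenes (runtime ≈5 minutes on one CPU;
nearby seeds give 94–98% recall and r 0.92–0.96).

A thin command-line dispatcher is included for shell use:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "tipscan.R", package = "tipscan"))')" \
    all --config pipeline.yaml
```

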