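# shootseg

Automated plant/background segmentation and phenotyping of greenhouse
shoot images, for plant scientists running high-throughput phenotyping
experiments. Chamber walls, carriers and pots share colors with leaves,
illumination drifts, and senescing plants turn yellow and brown — so
fixed color rules fail, and a supervised, context-aware segmenter is
needed before any trait can be measured.

At the core is a batch-normalized encoder–decoder U-net operating on
non-overlapping 256×256 patches:

* encoder: 3 blocks of two (7×7 conv → batch norm → ReLU) layers at
  16/32/64 filters, each followed by 2×2 max-pooling;
* bridge: one such block at 128 filters (output 32×32×128);
* decoder: 3 blocks, each a 3×3 stride-2 transpose convolution that
  doubles the spatial size and halves the channel depth, concatenation
  with the matching encoder output, then two conv–BN–ReLU layers;
* head: 1×1 convolution to a single sigmoid channel, trained with
  pixel-averaged binary cross-entropy;
* 2,484,721 trainable parameters in the default configuration.

Training follows the reference protocol (Adam, initial learning rate
0.001 reduced ×0.2 after 5 stagnant validation epochs, Gaussian init
SD 0.05, equal-proportion plant/background patch balancing, 85:15
image-level split). Whole-image inference pads to a 256-multiple, tiles,
predicts, reassembles, crops, thresholds at probability ≥ 0.6 and
optionally removes small connected components (8-connectivity).
Segmentation quality is scored with the Dice coefficient
2|P∩G|/(|P|+|G|). A quantification stage computes 35 shoot traits in 4
groups (area, bounding box, convex hull, color statistics), and a
27-feature 3×3-neighborhood pixel classifier is included as the shallow
baseline. A seeded synthetic greenhouse-scene generator (gradient
backgrounds, pot/carrier distractors, shadows, branching green-to-brown
plants with pixel-exact masks) makes the whole pipeline trainable and
testable with no external data. The convolutional engine (forward and
backward) is implemented in C++/BLAS inside the package — no Python or
deep-learning framework is required.

## Worked example

Generate scenes, train a reduced network, segment a held-out scene and
extract its traits:

```r
library(shootseg)

ds <- generate_dataset(50, scene_config(), seed = 1)
images <- lapply(ds$scenes, `[[`, "image")
masks  <- lapply(ds$scenes, `[[`, "mask")

fit <- fit_unet(images, masks,
                unet_config(encoder_filters = c(8L, 16L, 32L),
                            bridge_filters = 64L),
                training_config(epochs = 20L, batch_size = 16L, seed = 1L))

i <- fit$split$val[1]
seg <- segment_image(fit$model, images[[i]], threshold = 0.6)
dice(seg$mask, masks[[i]])
#> [1] 0.9540112

dices <- sapply(fit$split$val, function(i)
  dice(threshold_probability(predict_probability(fit$model, images[[i]]), 0.6),
       masks[[i]]))
mean(dices)
#> [1] 0.9518203

tr <- compute_traits(seg$mask, images[[i]])
round(tr[c("area.plant_area_px", "hull.solidity", "color.mean_h")], 2)
#> area.plant_area_px      hull.solidity       color.mean_h
#>            4385.00               0.29             113.13
```

The mean held-out Dice of 0.95 says the network recovers ~95% overlap
with the pixel-exact ground truth on scenes it never saw; solidity 0.29
is typical for an open branching side-view shoot, and a mean hue of
~113° sits in the green band. (The training run takes ~10 minutes on one
CPU; trait values are for the first validation scene under seed 1.)

The same stages are scriptable from a shell via the thin CLI wrapper:

```sh
Rscript inst/cli/shootseg.R simulate --n 10 --out data --seed 1
Rscript inst/cli/shootseg.R train    --data data --out model.rds --epochs 20 \
                                     --filters 8,16,32 --bridge 64 --seed 1
Rscript inst/cli/shootseg.R predict  --model model.rds --input data/images \
                                     --out preds --threshold 0.6
Rscript inst/cli/shootseg.R evaluate --pred preds --gt data/masks --out eval.csv
Rscript inst/cli/shootseg.R traits   --images data/images --masks data/masks \
                                     --out traits.csv
```

Every run writes a JSON run record (subcommand, options, seed, version)
sufficient to reproduce it.

## Package layout

* `R/tiling.R`, `R/image_io.R` — padding/tiling/reassembly, PNG/TIFF/JPEG I/O
* `R/unet.R`, `src/ops.cpp` — architecture, parameter accounting, C++ engine
* `R/training.R` — patch balancing, splitting, Adam + plateau training
* `R/inference.R` — whole-image prediction, thresholding, cluster cleanup
* `R/metrics.R` — Dice, cross-entropy, batch evaluation
* `R/traits.R` — the 35-trait registry and extraction
* `R/synthetic.R` — the seeded scene generator
* `R/baseline.R` — the 3×3-neighborhood pixel classifier
* `R/cli.R`, `inst/cli/shootseg.R` — command-line front end
* `vignettes/shoot-segmentation.Rmd` — models, assumptions, numerical design
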