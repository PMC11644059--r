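# lpcsononet

Compact convolutional networks for fetal ultrasound standard-plane
detection, in R.

Prenatal ultrasound screening is organized around *standard planes* —
canonical views (trans-thalamic brain, four-chamber thorax, femur, …) on
which fetal biometry is measured. Recognizing them automatically is a
multi-class grayscale image classification task, and clinically useful
models must stay small. This package implements:

* the **light pyramid convolution (LPC) block**: two stacked bias-free 3×3
  convolutions (widths `C_h`), concatenation of the input with both
  intermediate maps (three receptive-field scales, width `C_in + 2C_h`),
  and a 1×1 fusion convolution to `C_out` — every convolution followed by
  batch norm and ReLU, with the closed-form weight count
  `9·C_in·C_h + 9·C_h² + (C_in+2C_h)·C_out + 2(2C_h + C_out)`;
* **LPC-SonoNet** (four LPC blocks, channel ladder 64, 256, 512, 512,
  pyramid widths `C_out/2`) and the **SonoNet64** reference (five VGG-style
  conv blocks), both ending in the same fully convolutional adaptation
  head (1×1 conv 512→256, 1×1 conv 256→K, global spatial max-pool) that
  accepts variable input sizes: 4,321,900 vs 14,850,892 trainable
  parameters at K = 6 (4.3 vs 14.9 million, ratio 0.29);
* exact **parameter accounting** (closed form cross-checked against
  enumeration of the instantiated model, layer by layer);
* an imbalance-correcting **data pipeline**: stratified 8:1:1 manifest
  splitting and deterministic augmentation (flip / rotation / brightness /
  contrast / Gaussian blur) to exact per-category target counts;
* a seeded **training loop** (Adam, cross-entropy, learning rate 0.001
  decayed ×10 on a fixed epoch schedule, best-validation checkpointing)
  and **one-vs-rest metrics** (accuracy, macro sensitivity, macro
  specificity);
* **GradCAM** heatmaps for attributing predictions to image regions;
* a seeded **ultrasound phantom generator** (category-discriminative
  geometry, multiplicative speckle) so everything above is testable
  without any clinical data.

The network engine (im2col convolutions through BLAS sgemm, batch norm,
pooling, concat, reverse-mode gradients, Adam) is implemented in
single-precision C++ via RcppArmadillo — no deep-learning runtime is
required.

## Worked example

```r
library(lpcsononet)

count_parameters(build_lpc_sononet(6))
#> <param report> 28 learnable layers, total 4,321,900 parameters (4.3 million)
#>   convolutions: 14 layers, 4,316,000 parameters
#>   batch norm:   14 layers, 5,900 parameters

# nine-class phantom dataset: 55 images per class at 64x64, speckle 0.1
man <- generate_dataset(setNames(rep(55L, 9), plane_categories("nine")),
                        "phantoms", image_size = c(64, 64),
                        speckle = 0.1, seed = 101)
split <- make_split(man, seed = 101,
                    counts = data.frame(category = plane_categories("nine"),
                                        train = 40, val = 15, test = 0))

cfg <- train_config(epochs = 6, initial_lr = 0.001, decay_factor = 10,
                    decay_every = 5, batch_size = 32,
                    input_size = c(64, 64), seed = 101)
fit <- train_network(build_lpc_sononet(9), split$manifest, cfg, verbose = TRUE)
#> epoch   1 lr 1.0e-03 | train loss 1.3277 acc 0.531 | val loss 3.1527 acc 0.222
#> epoch   2 lr 1.0e-03 | train loss 0.6510 acc 0.753 | val loss 0.5416 acc 0.793
#> epoch   3 lr 1.0e-03 | train loss 0.3566 acc 0.861 | val loss 0.3358 acc 0.844
#> epoch   4 lr 1.0e-03 | train loss 0.2066 acc 0.922 | val loss 0.4805 acc 0.867
#> epoch   5 lr 1.0e-03 | train loss 0.0835 acc 0.986 | val loss 0.2028 acc 0.941
#> epoch   6 lr 1.0e-04 | train loss 0.0249 acc 1.000 | val loss 0.0638 acc 1.000

ev <- evaluate_network(fit, split$manifest, split = "val")
ev$metrics
#> accuracy 1.0000 | macro sensitivity 1.0000 | macro specificity 1.0000

# where does the model look when it says "femur"?
img <- generate_image("femur", c(64, 64), speckle = 0.1, seed = 7)
hm <- gradcam(fit$model, matrix(img, 64, 64),
              target_class = match("femur", fit$categories))
overlay_heatmap(unclass(hm), matrix(img, 64, 64), path = "femur_cam.png")
```

The epoch lines show the loss falling and validation accuracy reaching
1.00 on the held-out phantoms once the learning rate steps down — the
nine phantom categories are constructed to be separable, so a converging
implementation should saturate quickly. The GradCAM overlay concentrates
its warm colors on the bright femur bar.

A command-line front end over the same functions ships in
`inst/cli/lpcsononet.R` (subcommands `params`, `synth`, `split`,
`augment`, `train`, `evaluate`, `gradcam`).

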