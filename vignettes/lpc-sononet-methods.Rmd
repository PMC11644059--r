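---
title: "Light pyramid convolution networks for standard-plane detection: models, pipeline, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Light pyramid convolution networks for standard-plane detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

Fetal ultrasound screening hinges on *standard planes* — canonical 2D views
(trans-thalamic brain, four-chamber thorax, femur length, and so on) on
which biometric measurements are defined. Automating their recognition is a
multi-class image classification problem with two practical constraints:
images arrive at varying sizes, and clinically deployable models should be
small. This package implements a compact convolutional architecture for
that problem, the surrounding data pipeline, and the diagnostics used to
interrogate it, with a synthetic phantom generator so the entire stack can
be exercised and tested without any clinical data.

## The LPC block and the two architectures

The light pyramid convolution (LPC) block takes a `C_in`-channel feature
map, passes it through two stacked bias-free 3×3 convolutions of width
`C_h` (each followed by batch normalization and a ReLU), concatenates the
input with both intermediate maps — three receptive-field scales, width
`C_in + 2 C_h` — and fuses them with a 1×1 convolution to `C_out` channels.
Spatial dimensions are preserved throughout. Its trainable weight count is
closed-form:

    9 C_in C_h  +  9 C_h^2  +  (C_in + 2 C_h) C_out  +  2 (2 C_h + C_out)

with the last term contributed by the three batch norms.

`build_sononet64()` is the reference VGG-style baseline: five plain conv
blocks (64,64 | 128,128 | 256×3 | 512×3 | 512×3), 2×2 max-pooling after
blocks 1–4, and a fully convolutional *adaptation head* — 1×1 conv
512→256 (norm + ReLU), 1×1 conv 256→K (norm), global spatial max-pool.
Because the head is convolutional and ends in a global pool, any input of
at least the minimum size yields a `(N, K)` logit matrix, and the global
max implicitly localizes the most discriminative region.

`build_lpc_sononet()` removes one block and replaces the remaining four
with LPC blocks. The published description fixes the block count, the
shared head, and the total budget (4.3 million parameters at K = 6,
roughly one third of the baseline's 14.9 million), but not the channel
ladder or pyramid widths. We pinned them by calibration: enumerating
remove-one-block ladders crossed with hidden-width ratios (¼, ½, 1) and
selecting the combination whose closed-form count lands on the printed
budget. That is the ladder (64, 256, 512, 512) with `C_h = C_out / 2`
(i.e. the 128 block removed), which gives exactly 4,321,900 parameters at
K = 6 versus 14,850,892 for the baseline (ratio 0.291). The calibration
grid is frozen in a unit test, so any drift in the accounting is caught.
This is a reconstruction consistent with the stated constraints, not a
claim about the original authors' exact choice.

Pooling in the LPC variant follows blocks 1–3 only, mirroring the
baseline's design of feeding the head at the last block's resolution; the
total downsampling factor is 8 (versus 16), and the minimum input size is
`2^pools` per dimension (8 or 16 pixels) — violations raise an error
naming that minimum. Convolutions carry no biases because each is
immediately normalized; biases would be absorbed by the batch-norm shift.

```{r}
library(lpcsononet)
count_parameters(build_sononet64(6))    # 14,850,892 -> 14.9 million
count_parameters(build_lpc_sononet(6))  # 4,321,900  -> 4.3 million
```

`channel_load()` reports per-convolution tensor widths. Note a subtlety:
averaged over *input* channels the pyramid network is not narrower than the
baseline (317.9 vs 298.7) because concatenation widens the fusion inputs,
while averaged over *output* channels it is markedly narrower (210.7 vs
298.7). The report carries both summaries; it is a descriptive diagnostic
only and no quantitative claim rests on it.

## The network engine

No deep-learning runtime is assumed: the computation graph (convolution via
im2col + BLAS `sgemm`, batch norm, ReLU, 2×2 max-pool, channel concat,
global max-pool) and its reverse-mode gradients are implemented in C++
(RcppArmadillo) in single precision, with an Adam optimizer (β₁ = 0.9,
β₂ = 0.999, ε = 1e-8) and batch-norm ε = 1e-5, momentum 0.1 — the
conventional values. Weights are initialized fan-in-scaled normal
(sd = √(2/fan_in)) from a seeded stream; two instantiations from the same
spec and seed are bit-identical, and a training run is deterministic given
its configuration seed. Argmax predictions break ties at the lowest class
index. Gradient checks (every learnable tensor receives non-zero gradient
after one step) and an exact equivalence between closed-form parameter
counting and enumeration of the live model's tensors are part of the test
suite.

## Data pipeline

A dataset is described by a manifest (CSV: `path, category, split,
provenance`). `make_split()` partitions each category 8:1:1: `floor(0.8 n)`
training images, then validation takes the ceiling of half the remainder.
Published split tables occasionally differ by one image from any fixed
rounding rule, so an explicit-counts mode reproduces a given per-category
(train, val, test) table verbatim. Assignment within a category is
seeded-random and deterministic.

Augmentation corrects class imbalance *on the training split only*, to
explicit per-category target counts treated as configuration (the shipped
profiles follow the published tables; the printed targets are not derivable
from any single multiplication rule, so they are data, not formula).
`plan_augmentation()` distributes each category's deficit `d` over its `n`
sources round-robin in a seeded order — `floor(d/n)` jobs each, plus one
for the first `d mod n` sources — and draws each job's transform from five
families: horizontal flip, rotation (±15°), brightness (×0.7–1.3),
contrast (×0.7–1.3 about the image mean), Gaussian blur (σ 0.5–1.5).
The parameter ranges are pinned as mild, label-preserving choices typical
for ultrasound; flips are horizontal only since a vertical flip inverts
the fan geometry implausibly. Identity parameters are excluded and no two
jobs on one source share a spec, so every augmented image differs from its
source. Rotation is bilinear about the center (counter-clockwise positive,
zero fill at exposed corners, delegated to EBImage); blur uses a
normalized kernel, so constant images pass through unchanged; outputs are
clipped to [0, 1]. The plan is a pure function of (manifest, targets,
seed), and executing it makes per-category training counts equal the
targets exactly.

## Training and evaluation

The reference recipe is cross-entropy with Adam for 200 epochs, initial
learning rate 0.001 divided by 10 every 50 epochs (`lr_at()` exposes the
staircase), batch size 32, grayscale inputs resized to 224×288 and
standardized per image to zero mean and unit variance. Batch size and
input size are unstated in the source description and pinned to those
conventional values; all are configurable. The retained checkpoint is the
epoch with the best validation accuracy, earliest epoch on ties —
validation-accuracy selection is pinned since the monitored quantity was
not stated.

Evaluation reports the confusion matrix, accuracy (trace over total), and
per-class sensitivity `TP/(TP+FN)` and specificity `TN/(TN+FP)` in the
one-vs-rest reduction, aggregated by **macro** averaging (equal class
weight). Macro averaging is pinned because the published multiclass
summaries show specificity near 99% with accuracy between sensitivity and
specificity — the signature of macro one-vs-rest — and because
micro-averaged sensitivity degenerates to accuracy. A class absent from
the truth has undefined sensitivity; it is flagged and excluded from the
macro mean rather than imputed.

## GradCAM

`gradcam()` attributes a class score to spatial positions: channel weights
are the spatial means of the class-logit gradient at a feature layer, the
raw map is the rectified weighted channel sum, upsampled bilinearly to the
input size and max-normalized (an identically zero map — e.g. when the
chosen logit does not depend on the layer — stays zero rather than being
divided by zero). The default layer is the rectified output of the last
feature block, the deepest spatial layer before the head, the standard
choice when the attribution layer is unspecified; any graph node can be
requested by name. The map is invariant to channel permutation and to
positive rescaling of the features, which the tests assert directly.

## The phantom generator

`generate_image()` draws seeded grayscale phantoms whose geometry is
discriminative for the nine categories: a rimmed disc with a dark interior
blob (abdomen), a shared elliptical skull rim whose interior carries the
plane-specific structure (dark off-axis slit / central paired blobs /
posterior dumbbell / nothing, for the four brain planes), a bright oblique
bar (femur), a rimmed disc with an interior cross (thorax), a narrowing
bright band (cervix), and a featureless field (other). Outline jitter
(center ±8%, scale 0.9–1.1, rotation ±10°, femur ±30°) is drawn before any
category-specific parameter, so phantoms of different categories from one
seed share their outline — which also pins down, and lets us test, that
brain sub-planes differ only inside the rim. Speckle is multiplicative,
`clip(p(1+sη))` with standard-normal η per pixel: it preserves the key
statistical property of ultrasound speckle (signal-dependent noise)
without modeling Rayleigh scattering physics. Jitter ranges were chosen
once so that categories remain linearly separable at the default speckle
0.1 (a linear classifier on 16×16 downsampled phantoms exceeds 70%
nine-class accuracy — asserted in the tests), which keeps the network
convergence test meaningful rather than vacuous.

What the phantoms do **not** emulate: acoustic shadowing, probe-fan
geometry, device-dependent contrast, intra-class anatomical variability,
or the blurry low-quality images of portable devices. Passing phantom
tests therefore validates the machinery (architectures, pipeline
determinism, optimization, attribution), not clinical performance; the
published real-data accuracies require the external clinical dataset and
GPU-scale training and are deliberately out of this package's testing
scope.

## Problem sizes used by the test suite

Training this architecture on a single CPU costs a few seconds per batch,
so the suite's convergence experiment runs a deliberately scaled-down
version of the study conditions, chosen once for tractability: nine-class
phantoms at 64×64 and speckle 0.1, 40 training and 15 validation images
per class, batch 32, initial lr 0.001 with `decay_every = 5`, 6 epochs
(so one full learning-rate decade still occurs), three seeds of which at
least two must reach 0.90 final validation accuracy. At this scale one
run takes about four minutes on one core and reaches validation accuracy
1.00; larger runs (e.g. 150/class for 15 epochs) behave the same way but
add nothing to the property being tested. The augmentation exactness
checks run both 100 randomized small configurations and the full published
six-category profile (12,400 originals, 16,448 after augmentation) on
32×32 phantoms.

## Known limitations

* The LPC ladder and hidden widths are a budget-calibrated reconstruction;
  other ladders within ±0.05 million of the target would be
  indistinguishable by the printed precision (the calibration test records
  the full grid).
* The engine is single-precision and single-threaded by design; it is a
  faithful, testable implementation, not a performance-competitive
  runtime, and inference-time benchmarking is out of scope.
* The per-layer "channel load" statistic has no canonical definition; both
  summaries are reported and neither is an acceptance surface.
* Checkpoints are RDS files tied to this package's parameter layout; no
  interchange format is provided.
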