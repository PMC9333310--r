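---
title: "Counting plant stands by density-map regression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Counting plant stands by density-map regression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(standcount)
```

## The problem

An early-season stand count — the number of emerged maize plants in a plot —
is the first field measurement that tells a grower or breeder whether
planting succeeded, and it has to be taken in a narrow window (roughly
stages VE through V4; later, overlapping leaves make plants inseparable even
for people). `standcount` estimates stand counts from single RGB photographs
taken a few feet above the canopy, replacing manual counting with an
image-based pipeline suited to high-throughput phenotyping.

Detection-style counting (find every plant, count the boxes) degrades badly
under occlusion and dense spacing, and whole-image regression discards the
spatial evidence. The package therefore follows the approach that modern
crowd-counting methods use: regress a *density map* and integrate it.

## The model

### Ground-truth densities

Each annotated plant center $x_i$ contributes a Gaussian kernel, so an image
with $M$ plants has ground truth

$$D(x) = \sum_{i=1}^{M} \delta(x - x_i) * G_{\sigma_i}(x),$$

whose integral is exactly $M$. The bandwidth is *geometry-adaptive*:
$\sigma_i = \beta \cdot \bar d_i^{(k)}$, where $\bar d_i^{(k)}$ is the mean
distance from plant $i$ to its $k$ nearest annotated neighbours. Densely
planted regions get narrow kernels, sparse regions wide ones, so the density
scale tracks apparent plant size.

Defaults are $k = 3$ and $\beta = 0.3$, the values conventional in the
crowd-counting literature this construction comes from; both are settable in
`sigma_policy()`. Two numerical details matter and are forced by the
requirement that the map integrates to the count:

* kernels are truncated at $3\sigma$ and **renormalized to unit mass after
  clipping to the image**, so border plants still contribute exactly 1;
* images with fewer than $k+1$ points fall back to a fixed
  `fallback_sigma` (15 px), and $\sigma$ is floored at 1 px so coincident
  points cannot produce a degenerate kernel.

`render_density_map()` implements this; conservation is tested to
$10^{-3}$ per point, border points included.

### The network

`build_network()` constructs a fully convolutional regressor:

* **Backbone** — the ten 3×3 convolution layers of VGG-16 up to and
  including the conv4 block, with three 2×2 max-poolings, so the feature map
  is 1/8 of the input resolution. (Dropping only the *last* of VGG-16's five
  pools would give 1/16; with three stride-2 upsampling layers downstream,
  only the three-pool truncation is consistent with both the stated 1/8
  ratio and an output the size of the input, so that is what we build.)
* **Multi-scale branches** — two stride-2 3×3 convolutions (256 and 128
  filters) produce 1/16 and 1/32 maps. The smaller maps are zero-padded
  (centered) to the 1/8 map's size and concatenated along channels; a 3×3
  convolution fuses the 896 concatenated channels down to 128. Padding
  rather than upsampling keeps the branch cheap; the price is spatial
  misalignment of the coarse features, which the fusion layer must absorb.
* **Upsampling head** — three stride-2 transposed convolutions (128, 64, 32
  filters). The first uses 'valid' padding ($out = 2\,in + 1$), the other
  two 'same' ($out = 2\,in$): for a 300 px patch this is
  $300 \to 150 \to 75 \to 37 \to 75 \to 150 \to 300$, i.e. the output
  exactly matches the input. A final 1×1 convolution with a ReLU yields the
  single-channel, non-negative density map.

All convolutions use TensorFlow-style asymmetric 'same' padding (excess on
bottom/right); max-pooling floor-halves. Sizes congruent to 4 (mod 8) are
restored exactly; `forward_density()` handles every other size by
reflect-padding bottom/right to the next such size and cropping the output
back, so predictions always match the image dimensions (a 1024×768 frame is
padded to 1028×772 internally).

`width_multiplier` scales every filter count, preserving the topology; the
desk-scale experiments below use 0.25 (and shape/gradient tests 0.05). The
engine itself — im2col/GEMM convolution, max-pooling, transposed convolution
as zero-stuffed convolution with the flipped kernel, and their gradients —
is implemented in Rcpp/Armadillo in this package and verified against finite
differences to $10^{-3}$ relative error (the check randomizes biases first:
at a pre-activation of exactly zero the ReLU subgradient and a finite
difference legitimately disagree).

Inputs are scaled to $[0,1]$ and standardized with constants recorded in the
configuration. The defaults are mean 0, sd 1 (pure scaling): the model is
trained from scratch (Xavier initialization, no pretraining), so channel
standardization buys nothing and pure scaling keeps an all-black image an
exact zero of the network with zero biases — a useful structural test.

### Training

The loss is the mean over images of the pixel-wise squared L2 distance
between predicted and ground-truth maps. `train_network()` minimizes it with
Adam, mini-batches of 24, learning rate 3e-4 decayed to 25e-6 over 80,000
iterations — the full-scale recipe, all in `train_config()`. "Gradually
decayed" fixes only the endpoints; we default to a cosine schedule because
it is smooth and hits both endpoints exactly, with linear and geometric-step
shapes available. Ground-truth patch maps are rendered at full patch
resolution since the network output matches its input; no downsampling
factor exists. Determinism is end-to-end: initialization, data order and
noise draws all derive from the configured seed.

### Augmentation

`build_training_set()` reproduces the patch-sampling scheme: a multi-scale
pyramid per image (scales 0.4–1.3, step 0.1 — ten levels), 300×300 crops at
uniform random offsets, horizontal mirroring with probability 0.5, and
additive Gaussian pixel noise with sd drawn from [0, 5] on the 0–255 scale
(the flip axis, flip rate and noise magnitude are unpublished; these are our
choices). Crops use a half-open window, so points on the right/bottom edge
belong to the next crop; undersized pyramid levels are zero-padded rather
than skipped so extreme scales never silently drop data. Patch densities are
re-rendered from the transformed points — not cropped from a full-image
map — so kernels clipped by the crop border renormalize correctly.
With 314 training images, ten scales and the default 30 crops per level the
set has 94,200 patches, close to the ~93k a full-scale training run uses
(that total is not divisible by 314×10, so the original crop allocation is
not exactly recoverable; 30 is the nearest integer).

### Post-processing

Counting needs only `count_from_density()`; localization for visualization
uses `detect_stands()`: (1) threshold the map, (2) find peaks — local maxima
over an 8-neighbourhood, kept greedily in decreasing density order at a
minimum mutual distance, ties broken row-major; (3) draw a fixed-size box
around each peak, clipped to the image; (4) greedy IoU non-maximum
suppression (half-open integer boxes). All four parameters (threshold
$10^{-3}$, minimum distance 10 px, box 40 px, IoU 0.3) are unpublished in
the source method and exposed as arguments. The reported count is always the
raw map's integral — post-processing can never change it.

### Evaluation

`count_metrics()` / `evaluate_by_stage()` compute MAE, RMSE, MAPE (%) and
signed bias per growth-stage class and pooled. RMSE takes the square root of
the mean squared error: the printed definition in the source omits the
radical, but the values it reports alongside (RMSE ≥ MAE at the same scale
throughout) are only consistent with the rooted form. Predictions enter as
real numbers; MAPE requires strictly positive ground truth and errors
otherwise.

## The synthetic data generator

The 394-image field dataset behind the published results is private, so
`generate_field_image()` produces a stand-in with the same statistical
skeleton: frames (default 1024×768) holding 5–31 plants each — uniform by
default (mean 18), or a triangular mode targeting the published mean of
15.62 — drawn as procedural rosettes of elongated green ellipses over
low-frequency soil texture, with per-plant hue/size/rotation jitter and
per-image illumination jitter. Growth stage drives difficulty monotonically:
V5–V6 means more and longer leaves at smaller center separations, i.e. more
occlusion, mirroring where image-based counting genuinely degrades. Centers
are placed by rejection sampling at a minimum separation that is halved
(with a message) after 1,000 consecutive failures.

What the generator deliberately does **not** model: real leaf morphology,
shadows and specularities, weeds and residue, perspective, and camera
effects. Tests that pass on this data demonstrate that the pipeline's
machinery is correct — geometry, conservation, optimization, end-to-end
learnability — not that the trained weights transfer to photographs.

## Desk-scale study conditions

Full-scale training (80,000 iterations, ~93k patches of 300×300) is far
beyond a package test suite, and the published error tables additionally
require the private imagery, so they are not reproduction targets here. The
package instead fixes two scaled-down conditions, run by both the test suite
and `scripts/acceptance.R`:

* **Memorization**: a quarter-width network on 8 synthetic 64×64 patches
  (1–6 plants, stage V2), full-batch Adam, 300 iterations with the published
  learning-rate endpoints. Training loss must fall by at least 90%; the
  pilot behaviour is a drop to ~1.5% of the initial loss.
* **Generalization**: the same architecture on 200 such patches, evaluated
  on 40 held-out images against the predict-the-training-mean baseline,
  which it must beat on count MAE. 300 iterations keeps the run inside a
  laptop-scale budget (a few minutes each on one core).

These sizes were chosen once, before the runs, as the smallest problems that
still exercise every layer and the full training loop.

## Known limitations

* The exact channel counts and tap points of the multi-scale branches are
  not recoverable from the source description; the defaults here (256/128
  branch filters, 128 fusion filters) are implementer choices, exposed in
  `network_config()`.
* Zero-padded concatenation spatially misaligns the coarse branches (taken
  at the description's word); an interpolating variant would align them but
  is out of scope.
* The CPU engine is adequate for desk-scale experiments and inference on
  single images, not for full-scale (80k-iteration) training.
* Stage labels in `evaluate_by_stage()` come from the data manifest; the
  package does not infer growth stage from imagery.
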