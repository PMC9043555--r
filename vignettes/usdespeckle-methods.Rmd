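---
title: "Speckle suppression for breast ultrasound: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Speckle suppression for breast ultrasound: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(usdespeckle)
```

## The problem

Coherent imaging modalities such as ultrasound produce *speckle*: a
granular, multiplicative interference pattern that degrades apparent
resolution and obscures lesion boundaries. In breast ultrasound, where
diagnosis hinges on the shape and margin of small hypoechoic masses,
speckle suppression that *preserves edges* is the whole game: a filter
that smooths speckle but blurs margins is clinically useless.

`usdespeckle` implements a complete suppression pipeline for grayscale
images and small volumes:

1. **Contrast normalization** — a piecewise log/exponential transform
   driven by the image's grayscale mean;
2. **Detail enhancement** — guided filtering plus detail re-injection;
3. **Sharpening control** — a fixed high-pass spatial template that
   bounds the over-sharpening the previous stage can introduce;
4. **Learned despeckling** — a small 3D convolutional network trained
   with an L1 + edge-sensitive objective;
5. **Evaluation** — MSE, SNR, PSNR, edge preservation index (EPI),
   false recognition rate, and suppression time.

A synthetic phantom and noise generator makes the whole method trainable
and testable with no clinical data.

## Intensity conventions

All images live on the unit scale internally (`gray_image` enforces
values in [0, 1]); 2D images are stored as depth-1 volumes so every
stage is dimension-agnostic. The contrast transform's branch thresholds
are defined on the conventional 8-bit scale, so the branch selector is
the 255-scale mean `M = 255 * mean(img)`. One canonical internal scale
removes a whole class of renormalization bugs; the 255-scale appears
only where the method's constants are defined on it.

## Piecewise contrast transform

With mean `M`, defaults `m_low = 100`, `m_high = 180`, and coefficients
`a, b, c` (defaults 0, 1, 1):

* `M < 100` (dark image): logarithmic stretch
  `g = b * log(1 + f255)^c + a`. The `log(1 + .)` form is the standard
  contrast stretch and is defined at zero.
* `100 <= M < 180`: identity.
* `M >= 180` (bright image): the *functional inverse* of the log branch,
  `g = exp(((f255 - a)/b)^(1/c)) - 1`, i.e. the compression that exactly
  undoes the log stretch. The role of this branch is inverse
  compensation for over-bright images, and an exact inverse delivers
  that role with no extra free parameters.

Each branch output is affinely rescaled to span the input's dynamic
range before clipping. Without this, the arbitrary units of `a`, `b`,
`c` would change overall brightness, which is not the transform's job;
with it, every branch is monotone non-decreasing and changes only the
distribution of gray levels. Degenerate inputs (constant images, or a
degenerate transformed range) pass through unchanged.

The exponential branch is evaluated in a rescaled form,
`(e^{t} - e^{t_min}) / (e^{t_max} - e^{t_min})` computed via
`exp(t - t_max)`, so that small `b` cannot overflow double precision.

## Guided filtering and detail enhancement

The guided filter expresses its output as a locally linear function of a
guide image `I`: within every window `w_k`,
`q = a_k I + b_k` with `a_k = cov(I, p) / (var(I) + eps)`, and each
pixel averages the coefficients of all windows containing it. This is
mathematically identical to a data-dependent weighted-average kernel
`W_ij(I)`; the package's test suite verifies the fast box-filter route
against a brute-force evaluation of that kernel on small images to
1e-6. At image borders the windows are truncated and the window size
becomes position dependent — the only convention under which the kernel
weights sum to one everywhere, so constant images are preserved exactly
up to the border.

Both the filter input and the guide are the contrast-transformed image:
the stage is self-guided edge-preserving smoothing. `eps` (default 0.01
on the unit scale) sets the variance threshold separating "edge" from
"texture"; the radius (default 2, i.e. 5x5 windows) sets the smoothing
scale. Detail is then re-injected with gain `E` (default 1.5):
`I' = q + E (I - q)`. `E = 1` returns the guide unchanged; `E > 1`
amplifies the detail layer.

The final preprocessing stage convolves each slice with the fixed 3x3
template `(1/7) [-1 -2 -1; -2 19 -2; -1 -2 -1]` — unit DC gain with a
negative surround — using mirror padding (reflection about the border
pixel). Mirror padding avoids the dark frame a zero-padded convolution
would paint; since the template coefficients sum to one, the normalized
form of this filtering reduces to plain convolution. Guided filtering
and the high-pass stage run per 2D slice even on volumes: the
preprocessing model is planar, only the network is three-dimensional.

## The 3D convolutional denoiser

The network maps a noisy 32x32x8 patch to a denoised patch, with 5x5x3
convolution kernels, 2x2x1 max pooling, and K = 16 feature maps per
block (all configurable). It is realized fully convolutionally as a
residual encoder–bottleneck–decoder:

* conv (1 -> K) + ReLU at full resolution,
* 2x2x1 max pool,
* conv (K -> K) + ReLU at the pooled resolution — the bottleneck, which
  plays the "fully connected" role of aggregating context,
* nearest-neighbour upsampling,
* a final linear convolution over the *stacked* full-resolution and
  upsampled features (2K channels) producing the noise estimate `r`;
  the output is `input - r`.

Two design points deserve emphasis:

* **Residual prediction with a skip connection.** The network predicts
  the noise field, which is almost pure high-frequency content. A plain
  encoder–decoder cannot emit high frequencies after pooling has
  discarded them — in early experiments such a network converged to the
  identity map and removed nothing. Feeding the full-resolution encoder
  features to the decoder head (the standard U-Net skip) restores the
  high-frequency path while keeping the pooled context. Depth is kept at
  one encoder stage: the effective receptive field (~13 px in-plane, 7
  slices) already covers several speckle correlation lengths, and the
  phantom statistics are stationary, so additional stages buy little at
  desk scale.
* **Zero-initialized output head.** The untrained network is exactly the
  identity, which makes `iterations = 0` runs well-defined and gives the
  tiled-inference stitching a sharp correctness check (identity in,
  identity out, to the last bit).

### Objective

The loss is `alpha * L1 + beta * L_edge`, with
`L_edge = mean |D_v(pred) - D_v(target)|` and `D_v` the first-order
difference along the vertical (row) axis, per slice. Breast anatomy is
layered, which makes the vertical gradient the structurally important
one; the edge term penalizes gradient mismatch directly rather than
intensity mismatch. By default `beta` is calibrated once at training
start so that `beta * L_edge ~ alpha * L1` on the initial residual
(keeping the two terms at similar magnitude) and then frozen; it can be
fixed explicitly instead.

An optional adversarial term (off by default) adds a deliberately small
patch-classifier discriminator — logistic regression on four
differentiable patch statistics — trained one ascent step per generator
step, with the generator receiving the non-saturating `-log D(pred)`
gradient. It exists for completeness of the min–max formulation; the
package makes no claim that it improves the desk-scale results.

### Optimization and determinism

Training uses Adam (learning rate 1e-3, default batch 16); one
*iteration* is one epoch over the training patch set, and pairs larger
than the patch contribute one fresh random crop per epoch. All
randomness (initialization, shuffling, crops) derives from one seed, and
the compiled forward/backward passes are deterministic, so training is
bit-reproducible. Network arithmetic is single precision — standard for
convolutional training and a 2x throughput gain — while losses and the
recorded history are accumulated in double precision. The per-iteration
history records the training MSE (as percent of the squared unit dynamic
range, so 1% means RMSE 0.1), the false recognition rate, and the loss
decomposition.

Inference tiles the image with half-patch stride and averages
overlapping predictions with uniform weights; volumes shallower than the
patch depth are mirror-padded in depth and cropped back. Non-finite
losses abort training with the iteration named.

## The synthetic data generator

Phantoms emulate what matters statistically for this method: a
piecewise-smooth background of horizontal intensity strata (echogenicity
layers: skin, subcutaneous fat, gland), plus ellipsoidal inclusions with
anti-aliased borders, mostly hypoechoic (intensity 0.02–0.15, as most
breast masses appear) with a minority of hyperechoic ones (0.78–0.92).
Default layer intensities are (0.55, 0.35, 0.60, 0.40) — adjacent-layer
contrast of ~0.2, typical of gland/fat interfaces on a normalized 8-bit
display. Lesions are placed by rejection sampling so they never overlap,
and the voxel-wise lesion label map is returned for verification.

Speckle is modelled as fully developed multiplicative intensity noise:
each voxel is multiplied by an i.i.d. gamma variate with mean 1 and
variance `1/L` (the *looks* parameter). `L = 4` — severe, visible
speckle — is the working condition for training and evaluation here.
Additive white Gaussian noise at a target SNR (power definition
`10 log10(sum(img^2)/sum(noise^2))`) is available for protocols stated
in decibels; the realized noise field is returned so calibration can be
verified empirically. Values are clipped to [0, 1] after corruption;
the small clipping bias this introduces at bright voxels is accepted
and affects generator and evaluator alike.

What the generator does **not** emulate: spatially correlated speckle
(real speckle has a point-spread-function-sized grain, ours is white),
depth-dependent attenuation and focusing, acoustic shadowing and
enhancement behind structures, and real anatomy. Consequently, passing
the package's tests demonstrates that the algorithm and its training
loop work as specified on the stated noise model — not clinical
performance on patient images.

## Evaluation metrics

* **MSE** on the unit scale, also reported as percent of the squared
  dynamic range.
* **SNR** `10 log10(sum(ref^2)/sum((ref - test)^2))` against the clean
  reference. The literature quotes ideal thresholds of both 50 and
  60 dB for this class of method; both are recorded as named constants
  (`quality_thresholds`) and neither is adjudicated here. For real data
  with no clean reference the denoised image can serve as reference
  proxy, which yields a residual-noise SNR — the documentation flags
  that difference.
* **PSNR** `10 log10(max_i^2 / MSE)`; 65 dB is the corresponding quoted
  threshold.
* **EPI**: Pearson correlation of the mean-centered Laplacians
  (4-neighbour stencil, per slice, mirror padding) of the image before
  and after processing, clamped to [-1, 1] against rounding. This is
  the reading of the edge-preservation index that is actually bounded
  like an index; it is exactly 1 for identical images, invariant to
  constant offsets, and its quoted working threshold is 0.45.
* **False recognition rate**: the method this package realizes reports
  a "false recognition rate" without defining it; the package's
  stand-in is the fraction of voxels deviating from the clean reference
  by more than a tolerance (default 0.05 of the dynamic range). It is
  clearly labelled as a stand-in wherever it appears.
* **Suppression time**: the sum of per-image wall-clock laps. Because
  timing is inherently run-dependent, the pipeline writes it to a
  separate artifact excluded from the bit-reproducibility contract.

### What EPI can and cannot measure here

EPI deserves a caveat that falls straight out of the noise model. With
white multiplicative speckle at `L = 4`, the Laplacian of the noisy
image is overwhelmingly noise: on our held-out phantoms the EPI between
the noisy image and the *clean ground truth* is only ~0.04. An accurate
denoiser therefore necessarily decorrelates from the raw noisy input,
and no accurate output can reach the conventional 0.45 working
threshold against it. The threshold is meaningful for the *complete
suppression algorithm*, whose first stage (guided-filter-based
preprocessing) removes part of the speckle while keeping residual
structure correlated with the input. The package's evaluation protocol
accordingly computes EPI between the noisy input and the output of the
full chain — preprocessing followed by the trained network — which is
also the order in which the method is defined to operate.

## Problem sizes

The package's working protocol — chosen once as a realistic desk-scale
analogue and used by the test suite and the acceptance script alike —
is: 200 training patch pairs of 32x32x8 voxels with `L = 4` speckle,
100 training iterations of the default network, and 20 held-out
64x64x8 phantoms (3 lesions each) for evaluation. On one CPU core the
training run takes a few minutes.

## Known limitations

* The preprocessing stages are planar; only the network uses the slice
  dimension.
* The false recognition rate is a stand-in definition (above).
* The adversarial option is a minimal realization, provided for the
  completeness of the objective, not as a tuned feature.
* The speckle model is white multiplicative gamma noise; conclusions
  about spatially correlated clinical speckle require retraining on
  data with that correlation structure.
* Maximum pooling breaks ties by first occurrence in scan order; with
  continuous noise, ties have probability zero.
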