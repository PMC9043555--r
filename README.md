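# usdespeckle

Speckle noise suppression for breast ultrasound images and small volumes
in R, with a self-contained synthetic-data path so the whole method can
be trained, evaluated and reproduced without clinical data.

Ultrasound speckle is multiplicative interference noise that obscures
lesion margins. This package implements a complete suppression
pipeline:

1. **Preprocessing** — a piecewise contrast transform driven by the
   255-scale grayscale mean *M* (logarithmic stretch
   *g = b·log(1+f)^c + a* for *M* < 100, identity for 100 ≤ *M* < 180,
   inverse-log compression for *M* ≥ 180), self-guided **guided
   filtering** (window radius *r*, smoothing factor *ε*), detail
   re-injection *I′ = q + E(I − q)*, and a fixed 3×3 high-pass template
   (1/7)·[−1 −2 −1; −2 19 −2; −1 −2 −1] that bounds over-sharpening.
2. **A 3D convolutional denoiser** — a residual
   encoder–bottleneck–decoder with a skip connection (patches 32×32×8,
   kernels 5×5×3, 2×2×1 max pooling, K = 16 channels), trained with the
   objective *α·L1 + β·L_edge*, where *L_edge* is the mean absolute
   mismatch of vertical first differences (edge-sensitive term) and *β*
   is auto-balanced against the L1 term at training start.
3. **Metrics** — MSE, SNR, PSNR = 10·log10(max_I²/MSE), the edge
   preservation index (EPI, correlation of mean-centered Laplacians),
   a thresholded-residual false recognition rate, and suppression time.
4. **A simulator** — layered phantoms with ellipsoidal (mostly
   hypoechoic) lesions, fully developed multiplicative gamma speckle
   with *L* looks (mean 1, variance 1/L), and SNR-calibrated additive
   white Gaussian noise.

See `vignettes/usdespeckle-methods.Rmd` for the full model description,
parameter meanings and design notes.

## Worked example

```r
library(usdespeckle)

# synthetic study: 24 speckled phantom pairs (L = 4), small network
pairs <- make_dataset(phantom_spec(shape = c(32, 32, 8), seed = 1),
                      noise_config(looks = 4), n_pairs = 24)
cfg   <- network_config(iterations = 20, seed = 1)
state <- train_denoiser(pairs, cfg)
tail(state$history, 1)

# held-out phantom through the full suppression chain
held  <- make_dataset(phantom_spec(shape = c(64, 64, 8), n_lesions = 3,
                                   seed = 9), noise_config(looks = 4), 1)[[1]]
suppressed <- denoise(state, preprocess_pipeline(held$noisy))
evaluate_pair(held$clean, held$noisy, suppressed)
```

Output (one CPU core, a few seconds of training):

```
   iteration   mse_pct false_recognition_rate total_loss    l1_term  edge_term
20        20 0.6417867              0.4775289  0.1114162 0.06080837 0.05060779
metrics: MSE 0.01683 (1.683%)  SNR 11.13 dB  PSNR 17.74 dB  EPI 0.606  FRR 0.6759  time 0.00s
```

Reading the numbers: training MSE is reported as percent of the squared
unit dynamic range (0.64% ≈ RMSE 0.08); the per-pair report compares
the suppressed image with the clean phantom (MSE/SNR/PSNR/FRR) and with
the noisy input (EPI — 0.61 means the Laplacian edge structure of the
input survives in the output well above the conventional 0.45 working
threshold). The noisy input itself scores PSNR ≈ 13.6 dB against the
clean phantom, so suppression buys ≈ 4 dB in this small example; the
package's working protocol (200 pairs, 100 iterations) reaches training
MSE ≈ 0.24% and a PSNR gain of ≈ 8 dB.

The pipeline command runs simulate → preprocess → train → denoise →
evaluate end to end and writes a self-describing, bit-reproducible run
directory (`run_pipeline()`, or `inst/cli/despeckle.R pipeline` from a
shell).

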