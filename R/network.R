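#' Denoiser network configuration
#'
#' Architecture and training hyper-parameters of the 3D convolutional
#' denoiser. The network is a fully-convolutional residual
#' encoder-bottleneck-decoder: one 3D convolution block (ReLU) followed by
#' max pooling, a bottleneck convolution at the pooled resolution (playing
#' the fully-connected role), nearest-neighbour upsampling, and a final
#' convolution over the stacked full-resolution and upsampled features
#' (a skip connection: the noise estimate is high-frequency, so the head
#' must see detail the pooling path discards) producing the noise estimate
#' that is subtracted from the input. The final layer is zero-initialized,
#' so an untrained model is the identity map.
#'
#' @param patch_shape input patch size (h, w, d); default 32 x 32 x 8.
#' @param conv_kernel 3D convolution kernel size; default 5 x 5 x 3 (odd
#'   in every dimension).
#' @param pool_shape max-pool block size; default 2 x 2 x 1. Patch dims
#'   must be divisible by the pool dims.
#' @param n_channels feature maps per convolution block (default 16).
#' @param alpha L1 data-term weight.
#' @param beta edge-loss weight; `NULL` (default) calibrates it at
#'   training start so the two loss terms start at similar magnitude, then
#'   freezes it.
#' @param use_adversarial enable the optional adversarial term (a small
#'   patch-classifier discriminator trained one ascent step per generator
#'   step). Off by default.
#' @param learning_rate Adam learning rate.
#' @param iterations training iterations; one iteration is one epoch over
#'   the training patch set.
#' @param batch_size mini-batch size.
#' @param seed seed controlling initialization, shuffling and crops.
#' @return a `network_config` list.
#' @export
network_config <- function(patch_shape = c(32L, 32L, 8L),
                           conv_kernel = c(5L, 5L, 3L),
                           pool_shape = c(2L, 2L, 1L),
                           n_channels = 16L, alpha = 1, beta = NULL,
                           use_adversarial = FALSE, learning_rate = 1e-3,
                           iterations = 100L, batch_size = 16L, seed = 1L) {
  patch_shape <- as.integer(patch_shape)
  conv_kernel <- as.integer(conv_kernel)
  pool_shape <- as.integer(pool_shape)
  stopifnot(length(patch_shape) == 3, length(conv_kernel) == 3,
            length(pool_shape) == 3)
  if (any(patch_shape < 1) || any(conv_kernel < 1) || any(pool_shape < 1))
    stop_arg("all dims must be positive")
  if (any(conv_kernel %% 2 == 0)) stop_arg("conv_kernel dims must be odd")
  bad <- which(patch_shape %% pool_shape != 0)
  if (length(bad))
    stop_arg("patch dim ", c("height", "width", "depth")[bad[1]], " (",
             patch_shape[bad[1]], ") is not divisible by its pool dim (",
             pool_shape[bad[1]], ")")
  if (alpha < 0) stop_arg("alpha must be non-negative")
  if (!is.null(beta) && (!is.finite(beta) || beta < 0))
    stop_arg("beta must be non-negative (or NULL for auto-calibration)")
  if (n_channels < 1) stop_arg("n_channels must be >= 1")
  if (iterations < 0) stop_arg("iterations must be >= 0")
  if (batch_size < 1) stop_arg("batch_size must be >= 1")
  structure(list(patch_shape = patch_shape, conv_kernel = conv_kernel,
                 pool_shape = pool_shape, n_channels = as.integer(n_channels),
                 alpha = alpha, beta = beta,
                 use_adversarial = isTRUE(use_adversarial),
                 learning_rate = learning_rate,
                 iterations = as.integer(iterations),
                 batch_size = as.integer(batch_size),
                 seed = as.integer(seed)), class = "network_config")
}

#' Build an untrained denoiser
#'
#' Initializes the network parameters (He-scaled Gaussian weights for the
#' hidden convolutions, zeros for the output head so that the untrained
#' model is the identity) deterministically from `cfg$seed`.
#'
#' @param cfg a [network_config].
#' @return a `denoiser_model` list with elements `params` and `cfg`.
#' @export
build_network <- function(cfg = network_config()) {
  stopifnot(inherits(cfg, "network_config"))
  K <- cfg$n_channels
  taps1 <- prod(cfg$conv_kernel)
  taps2 <- taps1 * K
  taps3 <- taps1 * 2 * K     # decoder head sees [encoder ; upsampled] stack
  params <- with_seed(cfg$seed, list(
    W1 = matrix(rnorm(K * taps1, 0, sqrt(2/taps1)), K, taps1),
    b1 = numeric(K),
    W2 = matrix(rnorm(K * taps2, 0, sqrt(2/taps2)), K, taps2),
    b2 = numeric(K),
    W3 = matrix(0, 1, taps3),
    b3 = numeric(1)
  ))
  structure(list(params = params, cfg = cfg), class = "denoiser_model")
}

#' 3D max pooling
#'
#' Per-channel block maximum over a 4D feature array; the channel count is
#' preserved and spatial dims shrink by the pool factors.
#'
#' @param features numeric 4D array (X, Y, Z, K); a 3D array is treated as
#'   a single channel.
#' @param pool_shape integer length-3 block size; feature dims must be
#'   divisible by it.
#' @return pooled 4D array.
#' @export
max_pool3d <- function(features, pool_shape = c(2L, 2L, 1L)) {
  if (length(dim(features)) == 3) dim(features) <- c(dim(features), 1L)
  if (length(dim(features)) != 4) stop_arg("features must be a 3D/4D array")
  pool_shape <- as.integer(pool_shape)
  if (any(dim(features)[1:3] %% pool_shape != 0))
    stop_arg("feature dims not divisible by pool dims")
  cpp_maxpool_op(features, dim(features), pool_shape)
}

diff_vertical <- function(x) {
  d <- dim(x)
  x[2:d[1], , , drop = FALSE] - x[seq_len(d[1] - 1), , , drop = FALSE]
}

#' Edge-sensitive loss
#'
#' Mean absolute mismatch of the vertical first differences of prediction
#' and target, computed per slice. Zero iff the vertical gradients agree
#' everywhere; insensitive to constant offsets. Breast anatomy is layered,
#' which makes the vertical gradient the structurally important one.
#'
#' @param pred,target images of the same shape with height >= 2.
#' @return non-negative scalar.
#' @export
edge_loss <- function(pred, target) {
  p <- as_gray_data(pred); t <- as_gray_data(target)
  check_same_shape(p, t)
  if (dim(p)[1] < 2) stop_arg("height must be >= 2 for the edge loss")
  mean(abs(diff_vertical(p) - diff_vertical(t)))
}

#' Combined training objective
#'
#' `adversarial + alpha * mean|pred - target| + beta * edge_loss`, with the
#' three addends reported separately. The adversarial term is 0 unless
#' `cfg$use_adversarial` is set and discriminator scores are supplied, in
#' which case it is the generator's non-saturating loss
#' `mean(-log D(pred))`.
#'
#' @param pred,target images of the same shape.
#' @param disc_scores optional vector of discriminator probabilities for
#'   the predicted patches.
#' @param cfg a [network_config]; `alpha` and `beta` are taken from it
#'   (`beta` must be set explicitly here, auto-calibration happens only
#'   inside [train_denoiser()]).
#' @return list with `total`, `adversarial`, `l1_term`, `edge_term`.
#' @export
total_objective <- function(pred, target, disc_scores = NULL,
                            cfg = network_config(beta = 1)) {
  if (is.null(cfg$beta))
    stop_arg("cfg$beta must be set to evaluate the objective; ",
             "auto-calibration is a training-time feature")
  l1 <- cfg$alpha * mean(abs(as_gray_data(pred) - as_gray_data(target)))
  ed <- cfg$beta * edge_loss(pred, target)
  adv <- 0
  if (cfg$use_adversarial && !is.null(disc_scores))
    adv <- mean(-log(pmax(disc_scores, 1e-12)))
  list(total = adv + l1 + ed, adversarial = adv, l1_term = l1,
       edge_term = ed)
}
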