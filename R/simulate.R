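#' Noise configuration for the simulator
#'
#' @param looks speckle looks parameter L > 0: the multiplicative intensity
#'   noise is gamma distributed with mean 1 and variance 1/L (fully
#'   developed speckle); small L means severe speckle.
#' @param awgn_snr_db optional target SNR in dB for additive white Gaussian
#'   noise applied after speckle; `Inf` disables it.
#' @param seed pseudo-random seed.
#' @return a `noise_config` list.
#' @export
noise_config <- function(looks = 4, awgn_snr_db = Inf, seed = 1L) {
  if (!is.numeric(looks) || looks <= 0) stop_arg("looks must be positive")
  if (is.na(awgn_snr_db)) stop_arg("awgn_snr_db must be a number or Inf")
  structure(list(looks = looks, awgn_snr_db = awgn_snr_db,
                 seed = as.integer(seed)), class = "noise_config")
}

#' Phantom specification
#'
#' Describes an ultrasound-like piecewise-smooth test volume: horizontal
#' intensity layers (mimicking skin/fat/gland strata) with ellipsoidal
#' inclusions of contrasting echogenicity (mostly hypoechoic, as most
#' breast lesions appear).
#'
#' @param shape integer (height, width, depth); in-plane dims >= 16.
#' @param n_lesions number of non-overlapping ellipsoidal inclusions.
#' @param background_levels ordered layer intensities in \[0, 1\], top to
#'   bottom.
#' @param seed pseudo-random seed.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c(32L, 32L, 8L), n_lesions = 2L,
                         background_levels = c(0.55, 0.35, 0.6, 0.4),
                         seed = 1L) {
  shape <- as.integer(shape)
  if (length(shape) != 3 || any(shape < 1) || any(shape[1:2] < 16))
    stop_arg("shape must be (h, w, d) with in-plane dims >= 16")
  if (n_lesions < 0) stop_arg("n_lesions must be >= 0")
  if (any(background_levels < 0 | background_levels > 1))
    stop_arg("background_levels must lie in [0, 1]")
  structure(list(shape = shape, n_lesions = as.integer(n_lesions),
                 background_levels = background_levels,
                 seed = as.integer(seed)), class = "phantom_spec")
}

#' Generate a synthetic phantom
#'
#' Builds a piecewise-smooth volume of horizontal layers at the requested
#' intensities plus `n_lesions` ellipsoids with anti-aliased borders.
#' Deterministic given the seed. The voxel-wise lesion label map is
#' attached as attribute `"lesion_mask"` (0 = background, k = k-th lesion).
#'
#' @param spec a [phantom_spec].
#' @return a [gray_image].
#' @export
make_phantom <- function(spec = phantom_spec()) {
  stopifnot(inherits(spec, "phantom_spec"))
  h <- spec$shape[1]; w <- spec$shape[2]; d <- spec$shape[3]
  lv <- spec$background_levels
  nb <- length(lv)
  # smooth layered depth profile: step profile blurred along y (~1.5 px)
  edges <- seq(0, h, length.out = nb + 1)
  prof <- lv[pmin(nb, findInterval(seq_len(h) - 0.5, edges,
                                   rightmost.closed = TRUE))]
  if (h >= 5) {
    k <- exp(-(-3:3)^2/(2 * 1.5^2)); k <- k/sum(k)
    padded <- c(rep(prof[1], 3), prof, rep(prof[h], 3))
    prof <- as.numeric(stats::filter(padded, k, sides = 2))[4:(h + 3)]
  }
  img <- array(rep(prof, times = w * d), c(h, w, d))
  mask <- array(0L, c(h, w, d))
  if (spec$n_lesions > 0) {
    with_seed(spec$seed, {
      centers <- matrix(NA_real_, spec$n_lesions, 3)
      axes <- matrix(NA_real_, spec$n_lesions, 3)
      ints <- numeric(spec$n_lesions)
      for (i in seq_len(spec$n_lesions)) {
        placed <- FALSE
        for (try in seq_len(500)) {
          ax <- c(runif(2, 0.08, 0.18) * min(h, w),
                  runif(1, max(1, d/4), max(1.5, d/2)))
          ce <- c(runif(1, ax[1] + 1, h - ax[1]),
                  runif(1, ax[2] + 1, w - ax[2]),
                  runif(1, 1, d))
          ok <- TRUE
          if (i > 1) for (j in seq_len(i - 1)) {
            gap <- sqrt(sum((ce - centers[j, ])^2))
            if (gap < max(ax[1:2]) + max(axes[j, 1:2]) + 2) ok <- FALSE
          }
          if (ok) {
            centers[i, ] <- ce; axes[i, ] <- ax
            ints[i] <- if (runif(1) < 0.75) runif(1, 0.02, 0.15)
                       else runif(1, 0.78, 0.92)
            placed <- TRUE
            break
          }
        }
        if (!placed) stop_arg("could not place ", spec$n_lesions,
                              " non-overlapping lesions in this shape")
      }
      co <- expand.grid(y = seq_len(h), x = seq_len(w), z = seq_len(d))
      for (i in seq_len(spec$n_lesions)) {
        rho <- sqrt(((co$y - centers[i, 1])/axes[i, 1])^2 +
                    ((co$x - centers[i, 2])/axes[i, 2])^2 +
                    ((co$z - centers[i, 3])/axes[i, 3])^2)
        soft <- 1.5/min(axes[i, 1:2])      # ~1.5 px anti-aliased rim
        alpha <- pmin(1, pmax(0, (1 - rho)/soft + 0.5))
        img <- (1 - alpha) * img + alpha * ints[i]
        mask[alpha > 0.5] <- i
      }
    })
  }
  out <- gray_image(clip01(img))
  attr(out, "lesion_mask") <- mask
  out
}

#' Corrupt an image with multiplicative gamma speckle
#'
#' Multiplies every voxel by an i.i.d. gamma variate with mean 1 and
#' variance `1/looks` (fully developed speckle in intensity), then clips
#' to \[0, 1\].
#'
#' @param img a [gray_image].
#' @param cfg a [noise_config]; `cfg$looks` and `cfg$seed` are used.
#' @return the speckled [gray_image]; the realized multiplier field is
#'   attached as attribute `"multiplier"`.
#' @export
add_speckle <- function(img, cfg = noise_config()) {
  stopifnot(inherits(cfg, "noise_config"))
  data <- as_gray_data(img)
  n <- with_seed(cfg$seed,
                 rgamma(length(data), shape = cfg$looks, rate = cfg$looks))
  dim(n) <- dim(data)
  out <- gray_image(clip01(data * n))
  attr(out, "multiplier") <- n
  out
}

#' Add white Gaussian noise at a target SNR
#'
#' Adds zero-mean Gaussian noise whose variance is calibrated so that
#' `10*log10(sum(img^2) / sum(noise^2))` equals `snr_db` in expectation,
#' then clips to \[0, 1\]. `snr_db = Inf` is the identity.
#'
#' @param img a [gray_image]; must not be all zero.
#' @param snr_db target SNR in decibels.
#' @param seed pseudo-random seed.
#' @return the noisy [gray_image]; the realized (pre-clip) noise field is
#'   attached as attribute `"noise_field"`.
#' @export
add_awgn <- function(img, snr_db, seed = 1L) {
  data <- as_gray_data(img)
  if (is.infinite(snr_db) && snr_db > 0) return(gray_image(data))
  psig <- mean(data^2)
  if (psig == 0) stop_arg("SNR undefined for an all-zero image")
  sigma <- sqrt(psig/10^(snr_db/10))
  noise <- with_seed(seed, rnorm(length(data), 0, sigma))
  dim(noise) <- dim(data)
  out <- gray_image(clip01(data + noise))
  attr(out, "noise_field") <- noise
  out
}

#' Generate a paired clean/noisy dataset
#'
#' Draws `n_pairs` phantoms with per-pair derived seeds and corrupts each
#' with speckle (and AWGN when `cfg$awgn_snr_db` is finite). Fully
#' reproducible from the master seed in `spec$seed`.
#'
#' @param spec a [phantom_spec]; `spec$seed` acts as the master seed.
#' @param cfg a [noise_config].
#' @param n_pairs number of pairs (>= 1).
#' @return list of `n_pairs` elements, each `list(clean =, noisy =)`;
#'   the derived seeds are attached as attribute `"seeds"`.
#' @export
make_dataset <- function(spec = phantom_spec(), cfg = noise_config(),
                         n_pairs = 1L) {
  if (n_pairs < 1) stop_arg("n_pairs must be >= 1")
  ph_seeds <- derive_seeds(spec$seed, n_pairs, salt = 11L)
  nz_seeds <- derive_seeds(spec$seed, n_pairs, salt = 23L)
  pairs <- lapply(seq_len(n_pairs), function(i) {
    sp <- spec; sp$seed <- ph_seeds[i]
    clean <- make_phantom(sp)
    nc <- cfg; nc$seed <- nz_seeds[i]
    noisy <- add_speckle(clean, nc)
    if (is.finite(cfg$awgn_snr_db))
      noisy <- add_awgn(noisy, cfg$awgn_snr_db, seed = nz_seeds[i] + 1L)
    attr(noisy, "multiplier") <- NULL
    attr(noisy, "noise_field") <- NULL
    list(clean = clean, noisy = noisy)
  })
  attr(pairs, "seeds") <- list(phantom = ph_seeds, noise = nz_seeds)
  pairs
}
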