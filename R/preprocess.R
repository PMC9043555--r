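#' Preprocessing configuration
#'
#' Constants of the contrast-enhancement and detail-enhancement stages.
#'
#' @param a log/exp transform offset coefficient.
#' @param b log/exp transform scale coefficient (must be positive).
#' @param c exponent constant in (0, 1].
#' @param m_low lower branch threshold on the 255-scale grayscale mean;
#'   below it the logarithmic stretch fires.
#' @param m_high upper branch threshold; at or above it the exponential
#'   (inverse-log) compression fires. Between the two the image passes
#'   through unchanged.
#' @param gf_radius guided-filter window radius in pixels.
#' @param gf_eps guided-filter smoothing factor (unit intensity scale).
#' @param enhance_E detail-enhancement degree: gain applied to the
#'   difference between the guide and its smoothed version.
#' @return a `preprocess_config` list.
#' @export
preprocess_config <- function(a = 0, b = 1, c = 1, m_low = 100, m_high = 180,
                              gf_radius = 2, gf_eps = 0.01, enhance_E = 1.5) {
  stopifnot(is.finite(a), is.finite(b), is.finite(c))
  if (b <= 0) stop_arg("b must be positive")
  if (c <= 0 || c > 1) stop_arg("c must lie in (0, 1]")
  if (m_low < 0 || m_high <= m_low) stop_arg("need 0 <= m_low < m_high")
  if (gf_radius < 1) stop_arg("gf_radius must be >= 1")
  if (gf_eps <= 0) stop_arg("gf_eps must be positive")
  if (enhance_E < 0) stop_arg("enhance_E must be non-negative")
  structure(list(a = a, b = b, c = c, m_low = m_low, m_high = m_high,
                 gf_radius = as.integer(gf_radius), gf_eps = gf_eps,
                 enhance_E = enhance_E), class = "preprocess_config")
}

#' Grayscale mean on the 255 scale
#'
#' The branch selector of the piecewise contrast transform: 255 times the
#' arithmetic mean of all voxels.
#'
#' @param img a [gray_image] or numeric array.
#' @return scalar in \[0, 255\].
#' @export
mean_gray <- function(img) {
  data <- as_gray_data(img)
  if (length(data) == 0) stop_arg("empty image")
  255 * mean(data)
}

#' Piecewise log/exponential contrast transform
#'
#' Applies one of three branches to every pixel according to the image's
#' 255-scale grayscale mean M: a logarithmic stretch
#' `b * log(1 + f255)^c + a` for dark images (`M < m_low`), the identity
#' for mid-range images, and the functional inverse of the log branch
#' (exponential compression) for bright images (`M >= m_high`). The branch
#' output is affinely rescaled to span the input's dynamic range, so the
#' transform changes contrast, not overall brightness range, and is
#' monotone non-decreasing on every branch.
#'
#' @param img a [gray_image].
#' @param cfg a [preprocess_config].
#' @return list with elements `image` (the transformed [gray_image]) and
#'   `branch` (`"log"`, `"identity"` or `"exp"`).
#' @export
contrast_transform <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  data <- as_gray_data(img)
  M <- 255 * mean(data)
  branch <- if (M < cfg$m_low) "log" else if (M < cfg$m_high) "identity"
            else "exp"
  out <- switch(branch,
    identity = data,
    log = {
      t <- cfg$b * log1p(data * 255)^cfg$c + cfg$a
      rescale_to_input(t, data)
    },
    exp = {
      # inverse of the log branch: f = exp(((g - a)/b)^(1/c)) - 1, computed
      # relative to exp(tmax) so that small b cannot overflow the double range
      t <- pmax(data * 255 - cfg$a, 0)/cfg$b
      t <- t^(1/cfg$c)
      tmin <- min(t); tmax <- max(t)
      if (tmax - tmin < 1e-12) data
      else {
        u <- (exp(t - tmax) - exp(tmin - tmax)) / (1 - exp(tmin - tmax))
        min(data) + u * (max(data) - min(data))
      }
    })
  out <- clip01(out)
  dim(out) <- dim(data)
  list(image = gray_image(out), branch = branch)
}

rescale_to_input <- function(t, data) {
  tmin <- min(t); tmax <- max(t)
  if (tmax - tmin < 1e-12) return(data)
  min(data) + (t - tmin)/(tmax - tmin) * (max(data) - min(data))
}

# Truncated-window box sum over a matrix: S[i,j] = sum of m over the
# (2r+1)^2 window centered at (i,j), clipped at the borders.
box_sum <- function(m, r) {
  H <- nrow(m); W <- ncol(m)
  cs <- apply(m, 2, cumsum)
  if (W == 1) cs <- matrix(cs, ncol = 1)
  hi <- pmin(seq_len(H) + r, H)
  lo <- seq_len(H) - r - 1
  rows <- cs[hi, , drop = FALSE] -
    rbind(matrix(0, sum(lo < 1), W), cs[lo[lo >= 1], , drop = FALSE])
  cs2 <- t(apply(rows, 1, cumsum))
  if (H == 1) cs2 <- matrix(cs2, nrow = 1)
  hi2 <- pmin(seq_len(W) + r, W)
  lo2 <- seq_len(W) - r - 1
  cs2[, hi2, drop = FALSE] -
    cbind(matrix(0, H, sum(lo2 < 1)), cs2[, lo2[lo2 >= 1], drop = FALSE])
}

box_count <- function(H, W, r) {
  cy <- pmin(seq_len(H) + r, H) - pmax(seq_len(H) - r, 1) + 1
  cx <- pmin(seq_len(W) + r, W) - pmax(seq_len(W) - r, 1) + 1
  outer(cy, cx)
}

#' Guided filter
#'
#' Edge-preserving smoothing of `p` steered by the guide `I`, computed
#' slice by slice with the linear-coefficient box-filter formulation:
#' within every window the output is `a_k * I + b_k` with
#' `a_k = cov(I, p) / (var(I) + eps)`, and each pixel averages the
#' coefficients of all windows containing it. Windows are truncated at the
#' image borders (position-dependent window size), which is the reading of
#' the equivalent weighted-average kernel that preserves constant images
#' everywhere. Mathematically identical to explicit evaluation of that
#' kernel (see the package tests for the brute-force cross-check).
#'
#' @param p [gray_image] to be filtered.
#' @param I guide [gray_image] of the same shape.
#' @param radius window radius in pixels (>= 1).
#' @param eps smoothing factor (> 0); large values degenerate to plain box
#'   mean filtering.
#' @return the filtered [gray_image], clipped to \[0, 1\].
#' @export
guided_filter <- function(p, I, radius = 2, eps = 0.01) {
  pd <- as_gray_data(p); Id <- as_gray_data(I)
  check_same_shape(pd, Id)
  if (radius < 1) stop_arg("radius must be >= 1")
  if (eps <= 0) stop_arg("eps must be positive")
  r <- as.integer(radius)
  d <- dim(pd)
  out <- array(0, d)
  cnt <- box_count(d[1], d[2], r)
  for (z in seq_len(d[3])) {
    ps <- pd[, , z]; Is <- Id[, , z]
    mI <- box_sum(Is, r)/cnt
    mp <- box_sum(ps, r)/cnt
    covIp <- box_sum(Is * ps, r)/cnt - mI * mp
    varI <- box_sum(Is * Is, r)/cnt - mI * mI
    a <- covIp/(varI + eps)
    b <- mp - a * mI
    out[, , z] <- (box_sum(a, r)/cnt) * Is + box_sum(b, r)/cnt
  }
  gray_image(clip01(out))
}

#' Detail enhancement
#'
#' Re-adds the detail layer removed by the guided filter with gain `E`:
#' `I' = q + E * (I - q)`. `E = 1` returns the guide, `E = 0` the smoothed
#' image; `E > 1` amplifies detail.
#'
#' @param q smoothed [gray_image] (guided-filter output).
#' @param I guide [gray_image] of the same shape.
#' @param E enhancement degree (>= 0).
#' @return [gray_image] clipped to \[0, 1\].
#' @export
detail_enhance <- function(q, I, E = 1.5) {
  qd <- as_gray_data(q); Id <- as_gray_data(I)
  check_same_shape(qd, Id)
  if (E < 0) stop_arg("E must be non-negative")
  gray_image(clip01(qd + E * (Id - qd)))
}

highpass_template <- function() {
  matrix(c(-1, -2, -1, -2, 19, -2, -1, -2, -1), 3, 3)/7
}

#' High-pass spatial filter
#'
#' Convolves every slice with the fixed 3x3 sharpening template
#' `(1/7) * [-1 -2 -1; -2 19 -2; -1 -2 -1]` (unit DC gain, negative
#' surround), with mirror (reflect) padding at the borders, to bound the
#' over-sharpening introduced by detail enhancement.
#'
#' @param img a [gray_image] with in-plane dims >= 3.
#' @return the filtered [gray_image], clipped to \[0, 1\].
#' @export
highpass_filter <- function(img) {
  data <- as_gray_data(img)
  d <- dim(data)
  if (d[1] < 3 || d[2] < 3) stop_arg("image smaller than the 3x3 kernel")
  H <- highpass_template()
  out <- array(0, d)
  iy <- c(2, seq_len(d[1]), d[1] - 1)   # mirror about the border pixel
  ix <- c(2, seq_len(d[2]), d[2] - 1)
  for (z in seq_len(d[3])) {
    pad <- data[iy, ix, z]
    acc <- matrix(0, d[1], d[2])
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + H[dy + 2, dx + 2] *
        pad[seq_len(d[1]) + 1 + dy, seq_len(d[2]) + 1 + dx]
    out[, , z] <- acc
  }
  gray_image(clip01(out))
}

#' Full preprocessing pipeline
#'
#' Composes the three preprocessing stages: contrast transform, guided
#' filtering (both guide and filter input are the contrast-transformed
#' image), detail enhancement, and high-pass sharpening control.
#'
#' @param img input [gray_image].
#' @param cfg a [preprocess_config].
#' @return the preprocessed [gray_image], with the contrast branch that
#'   fired recorded in attribute `"branch"`.
#' @export
preprocess_pipeline <- function(img, cfg = preprocess_config()) {
  ct <- contrast_transform(img, cfg)
  q <- guided_filter(ct$image, ct$image, radius = cfg$gf_radius,
                     eps = cfg$gf_eps)
  ip <- detail_enhance(q, ct$image, E = cfg$enhance_E)
  out <- highpass_filter(ip)
  attr(out, "branch") <- ct$branch
  out
}
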