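#' Mean squared error between two images
#'
#' @param ref,test [gray_image]s or arrays of the same shape.
#' @return scalar MSE on the unit intensity scale.
#' @export
img_mse <- function(ref, test) {
  r <- as_gray_data(ref); t <- as_gray_data(test)
  check_same_shape(r, t)
  mean((r - t)^2)
}

#' Peak signal-to-noise ratio
#'
#' `PSNR = 10 * log10(max_i^2 / MSE)`. Identical images give `Inf`.
#'
#' @param ref,test images of the same shape.
#' @param max_i peak intensity (1 on the unit scale, 255 for 8-bit).
#' @return PSNR in dB.
#' @export
psnr <- function(ref, test, max_i = 1) {
  if (max_i <= 0) stop_arg("max_i must be positive")
  m <- img_mse(ref, test)
  if (m == 0) return(Inf)
  10 * log10(max_i^2/m)
}

#' Signal-to-noise ratio against a reference
#'
#' Standard power-ratio definition
#' `10 * log10(sum(ref^2) / sum((ref - test)^2))`. For real data with no
#' clean reference, callers may pass the denoised image as `ref` as a
#' proxy; that convention yields a residual-noise SNR, not a ground-truth
#' one.
#'
#' @param ref reference image (must not be all zero).
#' @param test image under evaluation, same shape.
#' @return SNR in dB; `Inf` for identical images.
#' @export
snr <- function(ref, test) {
  r <- as_gray_data(ref); t <- as_gray_data(test)
  check_same_shape(r, t)
  ps <- sum(r^2)
  if (ps == 0) stop_arg("SNR undefined: reference is all zero")
  pn <- sum((r - t)^2)
  if (pn == 0) return(Inf)
  10 * log10(ps/pn)
}

laplacian <- function(data) {
  d <- dim(data)
  if (d[1] < 2 || d[2] < 2) stop_arg("image too small for the Laplacian")
  out <- array(0, d)
  iy <- c(2, seq_len(d[1]), d[1] - 1)
  ix <- c(2, seq_len(d[2]), d[2] - 1)
  for (z in seq_len(d[3])) {
    pad <- data[iy, ix, z]
    cy <- seq_len(d[1]) + 1; cx <- seq_len(d[2]) + 1
    out[, , z] <- pad[cy - 1, cx] + pad[cy + 1, cx] + pad[cy, cx - 1] +
      pad[cy, cx + 1] - 4 * pad[cy, cx]
  }
  out
}

#' Edge preservation index
#'
#' Pearson correlation between the mean-centered Laplacians
#' (4-neighbour stencil, per slice, mirror padding) of the image before
#' and after processing. 1 means edges perfectly preserved; the index is
#' invariant to adding a constant to either image.
#'
#' @param before image before processing (e.g. the noisy input).
#' @param after image after processing (e.g. the denoised output).
#' @return EPI in \[-1, 1\].
#' @export
epi <- function(before, after) {
  b <- as_gray_data(before); a <- as_gray_data(after)
  check_same_shape(b, a)
  lb <- as.numeric(laplacian(b)); la <- as.numeric(laplacian(a))
  if (stats::sd(lb) == 0 || stats::sd(la) == 0)
    stop_arg("EPI undefined: constant Laplacian (flat image)")
  min(1, max(-1, cor(lb, la)))
}

#' False recognition rate
#'
#' Fraction of voxels whose denoised value deviates from the clean
#' reference by more than `tol` (default 5% of the dynamic range). The
#' underlying method reports a "false recognition rate" without defining
#' it; this thresholded-residual definition is the package's stand-in.
#'
#' @param pred denoised image.
#' @param clean clean reference, same shape.
#' @param tol intensity tolerance (> 0, unit scale).
#' @return fraction in \[0, 1\].
#' @export
false_recognition_rate <- function(pred, clean, tol = 0.05) {
  p <- as_gray_data(pred); c <- as_gray_data(clean)
  check_same_shape(p, c)
  if (tol <= 0) stop_arg("tol must be positive")
  mean(abs(p - c) > tol)
}

#' Total suppression time
#'
#' Sum of per-image processing durations.
#'
#' @param laps numeric vector of non-negative durations in seconds.
#' @return total seconds.
#' @export
suppression_time <- function(laps) {
  if (length(laps) == 0) return(0)
  if (any(!is.finite(laps)) || any(laps < 0))
    stop_arg("laps must be finite and non-negative")
  sum(laps)
}

#' Evaluate one clean/noisy/denoised triple
#'
#' Computes every quality figure for one image pair: MSE (unit scale and
#' as percent of the squared unit dynamic range), SNR and PSNR of the
#' denoised image against the clean reference, EPI between the noisy
#' input and the denoised output, false recognition rate, and the
#' supplied wall-clock suppression time.
#'
#' Reference thresholds quoted for this class of method (recorded here as
#' named constants, both variants the literature states): SNR ideal
#' thresholds 50/60 dB, PSNR 65 dB, EPI 0.45.
#'
#' @param clean,noisy,denoised images of one shape.
#' @param elapsed_s wall-clock suppression time in seconds.
#' @return a `metrics_report` list with fields `mse`, `mse_pct`, `snr_db`,
#'   `psnr_db`, `epi`, `frr`, `elapsed_s`.
#' @export
evaluate_pair <- function(clean, noisy, denoised, elapsed_s = 0) {
  m <- img_mse(clean, denoised)
  structure(list(
    mse = m,
    mse_pct = 100 * m,
    snr_db = snr(clean, denoised),
    psnr_db = psnr(clean, denoised, max_i = 1),
    epi = epi(noisy, denoised),
    frr = false_recognition_rate(denoised, clean),
    elapsed_s = elapsed_s
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(paste0("metrics: MSE %.5f (%.3f%%)  SNR %.2f dB  PSNR %.2f dB",
                     "  EPI %.3f  FRR %.4f  time %.2fs\n"),
              x$mse, x$mse_pct, x$snr_db, x$psnr_db, x$epi, x$frr,
              x$elapsed_s))
  invisible(x)
}

#' @rdname evaluate_pair
#' @format NULL
#' @export
quality_thresholds <- c(snr_db_criterion = 50, snr_db_abstract = 60,
                        psnr_db = 65, epi = 0.45)
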