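test_that("mean_gray returns the 255-scale arithmetic mean", {
  expect_equal(mean_gray(gray_image(matrix(0, 4, 4))), 0)
  expect_equal(mean_gray(gray_image(matrix(1, 4, 4))), 255)
  expect_equal(mean_gray(gray_image(matrix(c(0, 0.2, 0.4, 1), 2, 2))), 102)
  expect_error(mean_gray(gray_image(array(0.1, c(2, 2, 1))[0, , ,
                                                           drop = FALSE])))
})

test_that("contrast transform picks the branch dictated by the mean", {
  cfg <- preprocess_config()
  # mid-range mean: identity branch leaves the image untouched
  mid <- gray_image(matrix(150/255, 8, 8))
  ct <- contrast_transform(mid, cfg)
  expect_identical(ct$branch, "identity")
  expect_equal(ct$image$data, mid$data)
  # dark image: log branch
  dark <- gray_image(matrix(50/255, 8, 8))
  expect_identical(contrast_transform(dark, cfg)$branch, "log")
  # bright image: exponential branch
  bright <- gray_image(matrix(220/255, 8, 8))
  expect_identical(contrast_transform(bright, cfg)$branch, "exp")
})

test_that("every branch is monotone non-decreasing over all 256 levels", {
  ramp <- (0:255)/255
  for (scale in list(c(0.3, "log"), c(1, "identity"))) {
    img <- gray_image(matrix(ramp * as.numeric(scale[1]), 16, 16))
    ct <- contrast_transform(img)
    expect_identical(ct$branch, scale[2])
    expect_true(all(diff(ct$image$data[order(img$data)]) >= -1e-12))
  }
  # bright ramp for the exponential branch
  img <- gray_image(matrix(0.6 + ramp * 0.4, 16, 16))
  ct <- contrast_transform(img)
  expect_identical(ct$branch, "exp")
  expect_true(all(diff(ct$image$data[order(img$data)]) >= -1e-12))
  # small b must not overflow to non-finite output
  ct2 <- contrast_transform(img, preprocess_config(b = 0.2))
  expect_true(all(is.finite(ct2$image$data)))
})

test_that("guided filter preserves constants and degenerates to mean
           filtering for large eps", {
  const <- gray_image(matrix(0.4, 9, 9))
  expect_equal(guided_filter(const, const, radius = 2, eps = 0.01)$data,
               const$data, tolerance = 1e-12)
  set.seed(3)
  p <- matrix(runif(81), 9, 9)
  img <- gray_image(p)
  q <- guided_filter(img, img, radius = 2, eps = 1e6)$data[, , 1]
  # with eps >> var(I) the linear coefficients collapse to a_k = 0,
  # b_k = window mean, so the output is the window mean of window means
  # (the coefficient-averaging pass smooths once more)
  boxmean <- function(m) {
    out <- matrix(0, nrow(m), ncol(m))
    for (y in seq_len(nrow(m))) for (x in seq_len(ncol(m))) {
      ys <- max(1, y - 2):min(nrow(m), y + 2)
      xs <- max(1, x - 2):min(ncol(m), x + 2)
      out[y, x] <- mean(m[ys, xs])
    }
    out
  }
  expect_lt(max(abs(q - boxmean(boxmean(p)))), 1e-3)
  # a constant guide is pure mean filtering of p as well
  flat <- guided_filter(img, gray_image(matrix(0.5, 9, 9)),
                        radius = 2, eps = 0.01)$data[, , 1]
  expect_lt(max(abs(flat - boxmean(boxmean(p)))), 1e-3)
})

test_that("guided filter equals the brute-force kernel oracle", {
  set.seed(11)
  for (case in list(c(5, 7, 1), c(9, 9, 1), c(9, 9, 2))) {
    h <- case[1]; w <- case[2]; r <- case[3]
    p <- matrix(runif(h * w), h, w)
    I <- matrix(runif(h * w), h, w)
    fast <- guided_filter(gray_image(p), gray_image(I), radius = r,
                          eps = 0.01)$data[, , 1]
    slow <- pmin(1, pmax(0, guided_filter_bruteforce(p, I, r, 0.01)))
    expect_lt(max(abs(fast - slow)), 1e-6)
  }
})

test_that("guided filtering with p = I does not increase total variation", {
  set.seed(21)
  base <- matrix(rep(c(0.2, 0.7), each = 8), 16, 16)
  noisy <- pmax(pmin(base + rnorm(256, 0, 0.08), 1), 0)
  img <- gray_image(noisy)
  q <- guided_filter(img, img, radius = 2, eps = 0.01)$data[, , 1]
  tv <- function(m) sum(abs(diff(m))) + sum(abs(t(diff(t(m)))))
  expect_lte(tv(q), tv(noisy))
})

test_that("detail enhancement is the algebraic blend q + E (I - q)", {
  set.seed(5)
  q <- gray_image(matrix(runif(36), 6, 6))
  I <- gray_image(matrix(runif(36), 6, 6))
  expect_equal(detail_enhance(q, I, E = 1)$data, I$data)
  expect_equal(detail_enhance(q, I, E = 0)$data, q$data)
  out <- detail_enhance(gray_image(matrix(0.1, 4, 4)),
                        gray_image(matrix(0.3, 4, 4)), E = 2)
  expect_equal(out$data, array(0.5, c(4, 4, 1)))
  expect_error(detail_enhance(q, gray_image(matrix(0.5, 3, 3))), "shape")
})

test_that("high-pass filter has unit DC gain and matches the naive loop", {
  const <- gray_image(matrix(0.6, 7, 7))
  expect_equal(highpass_filter(const)$data, const$data, tolerance = 1e-12)
  # single interior impulse is scaled by the 19/7 center coefficient
  imp <- matrix(0, 7, 7); imp[4, 4] <- 0.2
  out <- highpass_filter(gray_image(imp))$data[, , 1]
  expect_equal(out[4, 4], 0.2 * 19/7, tolerance = 1e-12)
  set.seed(13)
  m <- matrix(runif(25), 5, 5)
  expect_lt(max(abs(highpass_filter(gray_image(m))$data[, , 1] -
                      highpass_bruteforce(m))), 1e-10)
  expect_error(highpass_filter(gray_image(matrix(0.5, 2, 5))), "kernel")
})

test_that("preprocess pipeline composes its stages and preserves shape", {
  cfg <- preprocess_config()
  const <- gray_image(array(0.5, c(16, 16, 2)))   # mean 127.5: identity branch
  expect_equal(preprocess_pipeline(const, cfg)$data, const$data,
               tolerance = 1e-12)
  ph <- make_phantom(phantom_spec(shape = c(64, 64, 4), seed = 8))
  out <- preprocess_pipeline(ph, cfg)
  expect_equal(dim(out$data), c(64L, 64L, 4L))
  # equals the manually composed stages
  ct <- contrast_transform(ph, cfg)
  q <- guided_filter(ct$image, ct$image, cfg$gf_radius, cfg$gf_eps)
  ip <- detail_enhance(q, ct$image, cfg$enhance_E)
  manual <- highpass_filter(ip)
  expect_equal(out$data, manual$data)
  expect_identical(attr(out, "branch"), ct$branch)
})
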