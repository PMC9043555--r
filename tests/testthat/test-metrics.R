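test_that("PSNR and SNR match their closed forms", {
  set.seed(2)
  ref <- gray_image(matrix(runif(100), 10, 10))
  expect_identical(psnr(ref, ref), Inf)
  # MSE 0.01 at unit peak: 10 log10(1/0.01) = 20 dB
  shifted <- gray_image(matrix(0.5, 10, 10))
  test <- gray_image(shifted$data + 0.1)
  expect_equal(psnr(shifted, test, max_i = 1), 20)
  # unit power ratio gives 0 dB
  expect_equal(psnr(gray_image(matrix(0, 4, 4)),
                    gray_image(matrix(1, 4, 4)), max_i = 1), 0)
  expect_identical(snr(ref, ref), Inf)
  expect_equal(snr(gray_image(matrix(1, 6, 6)),
                   gray_image(matrix(0.9, 6, 6))), 20)
  expect_error(snr(gray_image(matrix(0, 4, 4)), ref), "all zero|shape")
})

test_that("PSNR and SNR fall as the error grows", {
  set.seed(8)
  ref <- gray_image(matrix(runif(400, 0.2, 0.8), 20, 20))
  vals <- sapply(c(0.01, 0.05, 0.1), function(s) {
    test <- gray_image(pmax(pmin(ref$data + s, 1), 0))
    c(psnr(ref, test), snr(ref, test))
  })
  expect_true(all(diff(vals[1, ]) < 0))
  expect_true(all(diff(vals[2, ]) < 0))
})

test_that("EPI is a Laplacian correlation with the stated invariances", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 2), seed = 9))
  expect_equal(epi(ph, ph), 1.0)
  # constant offsets are annihilated by the Laplacian
  shifted <- gray_image(pmax(pmin(ph$data * 0.7 + 0.2, 1), 0))
  expect_equal(epi(gray_image(ph$data * 0.7), shifted), 1.0)
  expect_error(epi(gray_image(matrix(0.5, 8, 8)), ph), "shape|constant")
  expect_error(epi(gray_image(matrix(0.5, 32, 32)),
                   gray_image(ph$data[, , 1])), "constant")
})

test_that("EPI of a blurred image matches the independent oracle", {
  ph <- make_phantom(phantom_spec(shape = c(32, 32, 2), seed = 10))
  k <- 11
  blur <- ph$data
  for (z in 1:2) {
    m <- ph$data[, , z]
    pad <- m[c(rep(1, 5), 1:32, rep(32, 5)), c(rep(1, 5), 1:32, rep(32, 5))]
    out <- matrix(0, 32, 32)
    for (y in 1:32) for (x in 1:32)
      out[y, x] <- mean(pad[y:(y + 10), x:(x + 10)])
    blur[, , z] <- out
  }
  e <- epi(ph, gray_image(blur))
  expect_lt(e, 1)
  lb <- as.numeric(laplacian_bruteforce(ph$data))
  la <- as.numeric(laplacian_bruteforce(blur))
  oracle <- sum((lb - mean(lb)) * (la - mean(la))) /
    sqrt(sum((lb - mean(lb))^2) * sum((la - mean(la))^2))
  expect_equal(e, oracle, tolerance = 1e-10)
})

test_that("false recognition rate counts out-of-tolerance voxels", {
  clean <- gray_image(array(0.5, c(10, 10, 2)))
  expect_equal(false_recognition_rate(clean, clean), 0)
  off <- gray_image(array(1, c(10, 10, 2)))
  expect_equal(false_recognition_rate(off, clean), 1)
  half <- clean$data
  half[, 1:5, ] <- 0.5 + 2 * 0.05
  expect_equal(false_recognition_rate(gray_image(half), clean, tol = 0.05),
               0.5)
})

test_that("suppression time is the sum of non-negative laps", {
  expect_equal(suppression_time(numeric(0)), 0)
  expect_equal(suppression_time(c(1.0, 2.5)), 3.5)
  laps <- runif(10)
  expect_identical(suppression_time(laps), sum(laps))
  expect_error(suppression_time(c(1, -0.1)), "non-negative")
})

test_that("evaluate_pair aggregates exactly the component metrics", {
  set.seed(14)
  clean <- make_phantom(phantom_spec(shape = c(32, 32, 2), seed = 15))
  noisy <- add_speckle(clean, noise_config(looks = 4, seed = 16))
  den <- guided_filter(noisy, noisy, radius = 2, eps = 0.05)
  rep <- evaluate_pair(clean, noisy, den, elapsed_s = 1.25)
  expect_equal(rep$mse, img_mse(clean, den))
  expect_equal(rep$mse_pct, 100 * rep$mse)
  expect_equal(rep$snr_db, snr(clean, den))
  expect_equal(rep$psnr_db, psnr(clean, den, max_i = 1))
  expect_equal(rep$epi, epi(noisy, den))
  expect_equal(rep$frr, false_recognition_rate(den, clean))
  expect_equal(rep$elapsed_s, 1.25)
  # degenerate cases
  perfect <- evaluate_pair(clean, noisy, clean)
  expect_equal(perfect$mse, 0)
  expect_equal(perfect$frr, 0)
  expect_identical(perfect$psnr_db, Inf)
  noop <- evaluate_pair(clean, noisy, noisy)
  expect_equal(noop$epi, 1.0)
})
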