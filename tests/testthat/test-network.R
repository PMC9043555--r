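test_that("network config validates dimensions and weights", {
  expect_error(network_config(patch_shape = c(31, 32, 8)),
               "not divisible")
  expect_error(network_config(conv_kernel = c(4, 5, 3)), "odd")
  expect_error(network_config(alpha = -1), "non-negative")
  expect_error(network_config(beta = -0.5), "non-negative")
})

test_that("built networks are seeded and output the patch shape", {
  cfg <- network_config(seed = 42)
  m1 <- build_network(cfg)
  m2 <- build_network(cfg)
  expect_identical(m1$params, m2$params)
  m3 <- build_network(network_config(seed = 43))
  expect_false(identical(m1$params$W1, m3$params$W1))
  x <- array(runif(32 * 32 * 8), c(32, 32, 8, 1))
  pred <- usdespeckle:::cpp_cnn_predict(x, m1$params, cfg$patch_shape,
                                        cfg$n_channels, cfg$conv_kernel,
                                        cfg$pool_shape, 1L)
  expect_equal(dim(pred), c(32L, 32L, 8L, 1L))
  # zero-initialized residual head: the untrained model is the identity
  expect_equal(pred[, , , 1], x[, , , 1], tolerance = 1e-12)
})

test_that("max pooling takes per-block maxima and preserves channels", {
  const <- array(5, c(4, 4, 2, 1))/10
  p <- max_pool3d(const, c(2, 2, 1))
  expect_equal(dim(p), c(2L, 2L, 2L, 1L))
  expect_true(all(p == 0.5))
  blk <- array(0, c(2, 2, 1, 1))
  blk[, , 1, 1] <- matrix(c(1, 7, 3, 2), 2, 2)/10
  expect_equal(as.numeric(max_pool3d(blk, c(2, 2, 1))), 0.7)
  feat <- array(runif(8 * 8 * 2 * 16), c(8, 8, 2, 16))
  expect_equal(dim(max_pool3d(feat, c(2, 2, 1)))[4], 16L)
  expect_equal(max_pool3d(feat, c(2, 2, 2))[1, 1, 1, 3],
               max(feat[1:2, 1:2, 1:2, 3]))
  expect_error(max_pool3d(array(0, c(5, 4, 2, 1)), c(2, 2, 1)),
               "divisible")
})

test_that("edge loss measures vertical-gradient mismatch", {
  set.seed(6)
  img <- gray_image(matrix(runif(16), 4, 4))
  expect_equal(edge_loss(img, img), 0)
  expect_equal(edge_loss(gray_image(matrix(0.2, 4, 4)),
                         gray_image(matrix(0.9, 4, 4))), 0)
  ramp <- gray_image(matrix(rep(seq(0, 0.3, by = 0.1), 4), 4, 4))
  expect_equal(edge_loss(ramp, gray_image(matrix(0.5, 4, 4))), 0.1)
})

test_that("edge loss is a pseudo-metric on vertical-gradient space", {
  set.seed(30)
  for (i in 1:5) {
    a <- gray_image(matrix(runif(64), 8, 8))
    b <- gray_image(matrix(runif(64), 8, 8))
    c <- gray_image(matrix(runif(64), 8, 8))
    expect_gte(edge_loss(a, b), 0)
    expect_equal(edge_loss(a, b), edge_loss(b, a))
    expect_lte(edge_loss(a, c), edge_loss(a, b) + edge_loss(b, c) + 1e-12)
  }
})

test_that("total objective decomposes exactly into its reported terms", {
  set.seed(9)
  pred <- gray_image(matrix(runif(16), 4, 4))
  target <- gray_image(matrix(runif(16), 4, 4))
  cfg <- network_config(alpha = 1, beta = 1)
  obj <- total_objective(pred, target, cfg = cfg)
  expect_equal(obj$total, obj$adversarial + obj$l1_term + obj$edge_term)
  expect_equal(total_objective(pred, pred, cfg = cfg)$total, 0)
  # pure L1 with constant error
  a <- gray_image(matrix(0.5, 4, 4)); b <- gray_image(matrix(0.3, 4, 4))
  expect_equal(total_objective(a, b, cfg = network_config(alpha = 1,
                                                          beta = 0))$total,
               0.2)
  # ramp-vs-constant: hand-computed L1 + edge sum
  ramp <- gray_image(matrix(rep(seq(0, 0.3, by = 0.1), 4), 4, 4))
  zero <- gray_image(matrix(0, 4, 4))
  obj2 <- total_objective(ramp, zero, cfg = cfg)
  expect_equal(obj2$l1_term, 0.15)
  expect_equal(obj2$edge_term, 0.1)
  expect_equal(obj2$total, 0.25)
  expect_error(total_objective(pred, target, cfg = network_config()),
               "beta")
})

test_that("training-batch diagnostics agree with the R-side losses", {
  set.seed(51)
  cfg <- tiny_net(beta = 0.8, alpha = 1.2)
  m <- build_network(cfg)
  p <- m$params
  p$W3[] <- rnorm(length(p$W3), 0, 0.05)
  B <- 2L
  x <- array(runif(prod(cfg$patch_shape) * B), c(cfg$patch_shape, B))
  y <- array(runif(prod(cfg$patch_shape) * B), c(cfg$patch_shape, B))
  fb <- usdespeckle:::cpp_cnn_train_batch(x, y, p, cfg$patch_shape,
                                          cfg$n_channels, cfg$conv_kernel,
                                          cfg$pool_shape, B, cfg$alpha,
                                          cfg$beta, 0.05)
  pr <- usdespeckle:::cpp_cnn_predict(x, p, cfg$patch_shape, cfg$n_channels,
                                      cfg$conv_kernel, cfg$pool_shape, B)
  l1 <- mean(sapply(1:B, function(k) mean(abs(pr[, , , k] - y[, , , k]))))
  dv <- function(z) z[-1, , , drop = FALSE] - z[-dim(z)[1], , , drop = FALSE]
  ed <- mean(sapply(1:B, function(k)
    mean(abs(dv(pr[, , , k]) - dv(y[, , , k])))))
  expect_equal(fb$l1, l1, tolerance = 1e-6)
  expect_equal(fb$edge, ed, tolerance = 1e-6)
  expect_equal(fb$mse,
               mean(sapply(1:B, function(k) mean((pr[, , , k] -
                                                    y[, , , k])^2))),
               tolerance = 1e-6)
})

test_that("analytic gradients match finite differences on a tiny net", {
  cfg <- network_config(patch_shape = c(8, 8, 4), conv_kernel = c(3, 3, 3),
                        pool_shape = c(2, 2, 2), n_channels = 3, seed = 7,
                        beta = 0.7, alpha = 1.3)
  m <- build_network(cfg)
  p <- m$params
  set.seed(71)
  p$W3[] <- rnorm(length(p$W3), 0, 0.05)
  p$b3[] <- 0.01
  x <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  y <- array(runif(8 * 8 * 4 * 2), c(8, 8, 4, 2))
  dims <- c(8L, 8L, 4L); kern <- c(3L, 3L, 3L); pool <- c(2L, 2L, 2L)
  fb <- usdespeckle:::cpp_cnn_train_batch(x, y, p, dims, 3L, kern, pool, 2L,
                                          1.3, 0.7, 0.05)
  lossfn <- function(pp) {
    pr <- usdespeckle:::cpp_cnn_predict(x, pp, dims, 3L, kern, pool, 2L)
    tot <- 0
    for (k in 1:2) {
      a <- pr[, , , k]; b <- y[, , , k]
      dv <- function(z) z[2:8, , ] - z[1:7, , ]
      tot <- tot + 1.3 * mean(abs(a - b)) + 0.7 * mean(abs(dv(a) - dv(b)))
    }
    tot/2
  }
  # directional derivative along a random direction per tensor; this
  # averages out the kink noise of the absolute-value terms
  set.seed(72)
  h <- 1e-3
  for (nm in c("W1", "W2", "W3", "b1", "b2", "b3")) {
    g <- fb$grads[[nm]]
    d <- array(rnorm(length(g)),
               dim = if (is.null(dim(g))) length(g) else dim(g))
    d <- d/sqrt(sum(d^2))
    analytic <- sum(g * d)
    pp <- p; pp[[nm]] <- pp[[nm]] + h * d; up <- lossfn(pp)
    pp[[nm]] <- pp[[nm]] - 2 * h * d; dn <- lossfn(pp)
    fd <- (up - dn)/(2 * h)
    expect_lt(abs(fd - analytic), 0.1 * abs(analytic) + 2e-4,
              label = paste0("directional derivative of ", nm))
  }
})
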