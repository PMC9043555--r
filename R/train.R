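#' Train the 3D convolutional denoiser
#'
#' Mini-batch Adam optimization of the L1 + edge objective on patch pairs
#' (noisy patch in, clean patch as target). One iteration is one epoch
#' over the training patch set; pairs larger than the patch shape
#' contribute one fresh random crop per epoch. When `cfg$beta` is `NULL`
#' it is calibrated on the first batch so that the edge term starts at
#' the magnitude of the L1 term, then frozen. Fully reproducible given
#' `cfg$seed`.
#'
#' @param pairs list of `list(clean =, noisy =)` pairs as produced by
#'   [make_dataset()].
#' @param cfg a [network_config].
#' @param frr_tol intensity tolerance of the false recognition rate
#'   recorded in the history.
#' @return a `train_state`: list with `params` (trained weights), `history`
#'   (one row per iteration: `iteration`, `mse_pct`,
#'   `false_recognition_rate`, `total_loss`, `l1_term`, `edge_term`),
#'   `cfg`, `beta` (the frozen weight) and `seed`.
#' @export
train_denoiser <- function(pairs, cfg = network_config(), frr_tol = 0.05) {
  stopifnot(inherits(cfg, "network_config"))
  if (length(pairs) < 1) stop_arg("need at least one training pair")
  ps <- cfg$patch_shape
  for (pr in pairs) {
    d <- dim(as_gray_data(pr$clean))
    check_same_shape(as_gray_data(pr$clean), as_gray_data(pr$noisy),
                     "clean/noisy pair")
    if (any(d < ps))
      stop_arg("pair of shape ", paste(d, collapse = "x"),
               " is smaller than the patch shape")
  }
  model <- build_network(cfg)
  params <- model$params
  n <- length(pairs)
  K <- cfg$n_channels

  # freeze beta so that beta * edge ~ alpha * L1 on the initial model
  # (whose output is the input, so the residual error is the noise itself)
  beta <- cfg$beta
  if (is.null(beta)) {
    idx0 <- seq_len(min(cfg$batch_size, n))
    l1_0 <- mean(vapply(idx0, function(i)
      mean(abs(as_gray_data(pairs[[i]]$noisy) -
                 as_gray_data(pairs[[i]]$clean))), 0))
    ed_0 <- mean(vapply(idx0, function(i)
      edge_loss(pairs[[i]]$noisy, pairs[[i]]$clean), 0))
    beta <- if (ed_0 > 0) cfg$alpha * l1_0/ed_0 else 1
  }

  opt <- lapply(params, function(p) list(m = p * 0, v = p * 0))
  step <- 0L
  hist_rows <- vector("list", cfg$iterations)
  disc <- if (cfg$use_adversarial) disc_init() else NULL

  with_seed(cfg$seed, {
    for (it in seq_len(cfg$iterations)) {
      ord <- sample(n)
      agg <- c(mse = 0, frr = 0, loss = 0, l1 = 0, edge = 0, adv = 0)
      nvox <- 0
      for (b0 in seq(1, n, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1, n)]
        B <- length(idx)
        xb <- array(0, c(ps, B)); yb <- array(0, c(ps, B))
        for (k in seq_len(B)) {
          cl <- as_gray_data(pairs[[idx[k]]]$clean)
          no <- as_gray_data(pairs[[idx[k]]]$noisy)
          d <- dim(cl)
          if (any(d > ps)) {
            off <- vapply(1:3, function(ax)
              if (d[ax] > ps[ax]) sample.int(d[ax] - ps[ax] + 1, 1) else 1L,
              1L)
            cl <- cl[off[1]:(off[1] + ps[1] - 1), off[2]:(off[2] + ps[2] - 1),
                     off[3]:(off[3] + ps[3] - 1), drop = FALSE]
            no <- no[off[1]:(off[1] + ps[1] - 1), off[2]:(off[2] + ps[2] - 1),
                     off[3]:(off[3] + ps[3] - 1), drop = FALSE]
          }
          xb[, , , k] <- no; yb[, , , k] <- cl
        }
        if (cfg$use_adversarial) {
          res <- adv_train_batch(xb, yb, params, disc, cfg, beta, frr_tol)
          disc <- res$disc
        } else {
          res <- cpp_cnn_train_batch(xb, yb, params, ps, K, cfg$conv_kernel,
                                     cfg$pool_shape, B, cfg$alpha, beta,
                                     frr_tol)
          res$adv <- 0
        }
        if (!all(vapply(res$grads, function(g) all(is.finite(g)), TRUE)) ||
            !is.finite(res$loss))
          stop_arg("non-finite loss/gradient at iteration ", it)
        step <- step + 1L
        for (nm in names(params)) {
          g <- res$grads[[nm]]
          opt[[nm]]$m <- 0.9 * opt[[nm]]$m + 0.1 * g
          opt[[nm]]$v <- 0.999 * opt[[nm]]$v + 0.001 * g^2
          mhat <- opt[[nm]]$m/(1 - 0.9^step)
          vhat <- opt[[nm]]$v/(1 - 0.999^step)
          params[[nm]] <- params[[nm]] -
            cfg$learning_rate * mhat/(sqrt(vhat) + 1e-8)
        }
        w <- B
        agg <- agg + w * c(res$mse, res$frr,
                           res$adv + cfg$alpha * res$l1 + beta * res$edge,
                           cfg$alpha * res$l1, beta * res$edge, res$adv)
        nvox <- nvox + w
      }
      agg <- agg/nvox
      hist_rows[[it]] <- data.frame(
        iteration = it, mse_pct = 100 * agg[["mse"]],
        false_recognition_rate = agg[["frr"]], total_loss = agg[["loss"]],
        l1_term = agg[["l1"]], edge_term = agg[["edge"]])
    }
  })
  history <- if (cfg$iterations > 0) do.call(rbind, hist_rows)
             else data.frame(iteration = integer(), mse_pct = numeric(),
                             false_recognition_rate = numeric(),
                             total_loss = numeric(), l1_term = numeric(),
                             edge_term = numeric())
  structure(list(params = params, history = history, cfg = cfg, beta = beta,
                 seed = cfg$seed, discriminator = disc),
            class = "train_state")
}

# ---- optional adversarial term ------------------------------------------
# A deliberately small patch-classifier discriminator: logistic regression
# on four differentiable patch statistics (mean, sd, mean |vertical diff|,
# mean |Laplacian|). One ascent step on the discriminator per generator
# step; the generator receives the non-saturating -log D(pred) gradient.

disc_init <- function() list(w = numeric(4), b = 0, lr = 0.05)

disc_features <- function(patch) {
  c(mean(patch), stats::sd(patch), mean(abs(diff_vertical(patch))),
    mean(abs(laplacian(patch))))
}

disc_score <- function(disc, feats) 1/(1 + exp(-(sum(disc$w * feats) + disc$b)))

adv_train_batch <- function(xb, yb, params, disc, cfg, beta, frr_tol) {
  ps <- cfg$patch_shape; B <- dim(xb)[4]
  pred <- cpp_cnn_predict(xb, params, ps, cfg$n_channels, cfg$conv_kernel,
                          cfg$pool_shape, B)
  N <- prod(ps)
  dpred <- array(0, dim(pred))
  l1 <- 0; ed <- 0; mse <- 0; frr <- 0; adv <- 0
  dw <- numeric(4); db <- 0
  for (k in seq_len(B)) {
    p <- pred[, , , k, drop = FALSE]; dim(p) <- ps
    y <- yb[, , , k, drop = FALSE]; dim(y) <- ps
    e <- p - y
    l1 <- l1 + mean(abs(e)); mse <- mse + mean(e^2)
    frr <- frr + mean(abs(e) > frr_tol)
    dvp <- diff_vertical(p); dvy <- diff_vertical(y)
    ed <- ed + mean(abs(dvp - dvy))
    M <- length(dvp)
    g <- array(0, ps)
    s <- sign(dvp - dvy)
    g[2:ps[1], , ] <- g[2:ps[1], , ] + beta * s/M
    g[seq_len(ps[1] - 1), , ] <- g[seq_len(ps[1] - 1), , ] - beta * s/M
    g <- g + cfg$alpha * sign(e)/N
    # discriminator: one ascent step on (clean = 1, pred = 0)
    fp <- disc_features(p); fy <- disc_features(y)
    sp <- disc_score(disc, fp); sy <- disc_score(disc, fy)
    dw <- dw + (1 - sy) * fy - sp * fp
    db <- db + (1 - sy) - sp
    # generator non-saturating term -log D(pred)
    adv <- adv - log(max(sp, 1e-12))
    gfeat <- -(1 - sp) * disc$w
    mu <- mean(p); sdv <- stats::sd(p)
    g <- g + gfeat[1]/N
    if (sdv > 0) g <- g + gfeat[2] * (p - mu)/((N - 1) * sdv)
    sv <- sign(dvp); gv <- array(0, ps)
    gv[2:ps[1], , ] <- gv[2:ps[1], , ] + sv/M
    gv[seq_len(ps[1] - 1), , ] <- gv[seq_len(ps[1] - 1), , ] - sv/M
    g <- g + gfeat[3] * gv
    lp <- laplacian(p)
    g <- g + gfeat[4] * laplacian(array(sign(lp), ps))/length(lp)
    dpred[, , , k] <- g/B
  }
  disc$w <- disc$w + disc$lr * dw/B
  disc$b <- disc$b + disc$lr * db/B
  grads <- cpp_cnn_backprop(xb, dpred, params, ps, cfg$n_channels,
                            cfg$conv_kernel, cfg$pool_shape, B)
  list(grads = grads, l1 = l1/B, edge = ed/B, mse = mse/B, frr = frr/B,
       adv = adv/B, loss = adv/B + cfg$alpha * l1/B + beta * ed/B,
       disc = disc)
}

tile_starts <- function(n, p, stride) {
  s <- seq(1L, n - p + 1L, by = stride)
  if (s[length(s)] != n - p + 1L) s <- c(s, n - p + 1L)
  s
}

mirror_depth_index <- function(D, target) {
  if (D == 1) return(rep(1L, target))
  period <- c(seq_len(D), seq(D - 1L, 2L))
  period[(seq_len(target) - 1L) %% length(period) + 1L]
}

#' Denoise an image with a trained model
#'
#' Tiled inference: overlapping patches at half-patch stride, forward
#' passes through the network, and overlap-averaged stitching with uniform
#' weights. Volumes shallower than the patch depth are mirror-padded in
#' depth. An identity (untrained) model reproduces the input exactly.
#'
#' @param state a `train_state` from [train_denoiser()] or a
#'   `denoiser_model` from [build_network()].
#' @param img a [gray_image]; in-plane dims must be at least the patch
#'   in-plane dims.
#' @return the denoised [gray_image], clipped to \[0, 1\].
#' @export
denoise <- function(state, img) {
  if (!inherits(state, c("train_state", "denoiser_model")))
    stop_arg("state must be a train_state or denoiser_model")
  cfg <- state$cfg; params <- state$params
  data <- as_gray_data(img)
  d <- dim(data)
  ps <- cfg$patch_shape
  if (d[1] < ps[1] || d[2] < ps[2])
    stop_arg("image in-plane dims (", d[1], "x", d[2],
             ") are smaller than the patch (", ps[1], "x", ps[2], ")")
  dz <- d[3]
  if (dz < ps[3]) {
    data <- data[, , mirror_depth_index(dz, ps[3]), drop = FALSE]
    d <- dim(data)
  }
  stride <- pmax(1L, ps %/% 2L)
  sy <- tile_starts(d[1], ps[1], stride[1])
  sx <- tile_starts(d[2], ps[2], stride[2])
  sz <- tile_starts(d[3], ps[3], stride[3])
  tiles <- expand.grid(y = sy, x = sx, z = sz)
  acc <- array(0, d); cnt <- array(0, d)
  bs <- cfg$batch_size
  for (b0 in seq(1, nrow(tiles), by = bs)) {
    ti <- b0:min(b0 + bs - 1, nrow(tiles))
    B <- length(ti)
    xb <- array(0, c(ps, B))
    for (k in seq_len(B)) {
      t <- tiles[ti[k], ]
      xb[, , , k] <- data[t$y:(t$y + ps[1] - 1), t$x:(t$x + ps[2] - 1),
                          t$z:(t$z + ps[3] - 1)]
    }
    pred <- cpp_cnn_predict(xb, params, ps, cfg$n_channels, cfg$conv_kernel,
                            cfg$pool_shape, B)
    for (k in seq_len(B)) {
      t <- tiles[ti[k], ]
      ry <- t$y:(t$y + ps[1] - 1); rx <- t$x:(t$x + ps[2] - 1)
      rz <- t$z:(t$z + ps[3] - 1)
      acc[ry, rx, rz] <- acc[ry, rx, rz] + pred[, , , k]
      cnt[ry, rx, rz] <- cnt[ry, rx, rz] + 1
    }
  }
  out <- acc/cnt
  if (dz < ps[3]) out <- out[, , seq_len(dz), drop = FALSE]
  gray_image(clip01(out))
}
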