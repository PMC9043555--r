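# Independent brute-force oracles used to cross-check the fast
# implementations. These deliberately re-derive every quantity from the
# definitions with naive loops; they share no code with the package paths
# they verify.

# Explicit guided-filter kernel: q_i = sum_j p_j W_ij with
# W_ij = (1/|w_i|) sum_{k: i,j in w_k} (1/|w_k|)
#          (1 + (I_i - mu_k)(I_j - mu_k)/(var_k + eps)),
# windows truncated at the borders (|w| position dependent).
guided_filter_bruteforce <- function(p, I, radius, eps) {
  H <- nrow(p); W <- ncol(p)
  win <- function(cy, cx) {
    ys <- max(1, cy - radius):min(H, cy + radius)
    xs <- max(1, cx - radius):min(W, cx + radius)
    as.matrix(expand.grid(y = ys, x = xs))
  }
  mu <- matrix(0, H, W); va <- matrix(0, H, W); nk <- matrix(0, H, W)
  for (cy in 1:H) for (cx in 1:W) {
    w <- win(cy, cx)
    v <- I[w]
    mu[cy, cx] <- mean(v)
    va[cy, cx] <- mean(v^2) - mean(v)^2
    nk[cy, cx] <- nrow(w)
  }
  q <- matrix(0, H, W)
  for (iy in 1:H) for (ix in 1:W) {
    wi <- win(iy, ix)
    acc <- 0
    for (r in seq_len(nrow(wi))) {
      k <- wi[r, ]
      wk <- win(k[1], k[2])
      inwk <- wk[, 1] + H * wk[, 2]  # linear ids of pixels in window k
      stopifnot((iy + H * ix) %in% inwk)
      kern <- (1 + (I[iy, ix] - mu[k[1], k[2]]) * (I[wk] - mu[k[1], k[2]]) /
                 (va[k[1], k[2]] + eps)) / nk[k[1], k[2]]
      acc <- acc + sum(p[wk] * kern)
    }
    q[iy, ix] <- acc / nk[iy, ix]
  }
  q
}

# Naive 9-term high-pass convolution with mirror padding (no shared code
# with highpass_filter: direct per-pixel double loop).
highpass_bruteforce <- function(m) {
  H <- matrix(c(-1, -2, -1, -2, 19, -2, -1, -2, -1), 3, 3)/7
  h <- nrow(m); w <- ncol(m)
  refl <- function(i, n) if (i < 1) 1 + (1 - i) else if (i > n) n - (i - n) else i
  out <- matrix(0, h, w)
  for (y in 1:h) for (x in 1:w) {
    acc <- 0
    for (dy in -1:1) for (dx in -1:1)
      acc <- acc + H[dy + 2, dx + 2] * m[refl(y + dy, h), refl(x + dx, w)]
    out[y, x] <- acc
  }
  pmin(1, pmax(0, out))
}

# 6-connected component count of a 3D binary mask (iterative flood fill).
count_components3d <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  ncomp <- 0L
  idx <- which(mask & lab == 0L)
  for (start in idx) {
    if (lab[start] != 0L) next
    ncomp <- ncomp + 1L
    stack <- start
    while (length(stack)) {
      v <- stack[length(stack)]; stack <- stack[-length(stack)]
      if (lab[v] != 0L) next
      lab[v] <- ncomp
      co <- arrayInd(v, d)
      for (ax in 1:3) for (s in c(-1L, 1L)) {
        nb <- co; nb[ax] <- nb[ax] + s
        if (nb[ax] >= 1 && nb[ax] <= d[ax]) {
          nv <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
          if (mask[nv] && lab[nv] == 0L) stack <- c(stack, nv)
        }
      }
    }
  }
  ncomp
}

# Naive per-slice 4-neighbour Laplacian with mirror padding.
laplacian_bruteforce <- function(a) {
  d <- dim(a)
  refl <- function(i, n) if (i < 1) 1 + (1 - i) else if (i > n) n - (i - n) else i
  out <- array(0, d)
  for (z in seq_len(d[3])) for (y in seq_len(d[1])) for (x in seq_len(d[2]))
    out[y, x, z] <- a[refl(y - 1, d[1]), x, z] + a[refl(y + 1, d[1]), x, z] +
      a[y, refl(x - 1, d[2]), z] + a[y, refl(x + 1, d[2]), z] -
      4 * a[y, x, z]
  out
}

# A deliberately small network configuration for fast train-loop tests.
tiny_net <- function(...) {
  args <- utils::modifyList(
    list(patch_shape = c(16, 16, 4), conv_kernel = c(3, 3, 3),
         pool_shape = c(2, 2, 1), n_channels = 4, batch_size = 4,
         iterations = 3, seed = 11),
    list(...))
  do.call(network_config, args)
}

tiny_pairs <- function(n = 5, looks = 4, shape = c(16, 16, 4), seed = 99) {
  make_dataset(phantom_spec(shape = shape, n_lesions = 1, seed = seed),
               noise_config(looks = looks), n_pairs = n)
}
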