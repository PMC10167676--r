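# Minimal neural-network primitives for volumetric data.
#
# Feature batches move between layers as 5-D arrays (x, y, z, channel, n).
# Kernel-2 / stride-2 convolutions act on disjoint 2x2x2 blocks, so both the
# downsampling convolution and its transposed counterpart reduce to a
# reshape/aperm plus one BLAS matrix multiply; the general strided
# convolution (kernel 3) uses a precomputed gather-index matrix. Backward
# passes are hand-derived and checked against finite differences in the
# test-suite.

# ---- kernel-2 / stride-2 block convolution -------------------------------

# (x,y,z,c,n) -> rows ordered (ox fastest, oy, oz, n); cols (kx,ky,kz,c)
im2col_k2 <- function(a) {
  d <- dim(a)
  m <- cpp_im2col_k2(a, as.integer(d))
  attr(m, "odims") <- d[1:3] %/% 2L
  m
}

# inverse scatter of im2col_k2: cols (prod(o)*n, 8c) -> (x,y,z,c,n) zero-padded
col2im_k2 <- function(cols, in_dims, n_ch, n_batch) {
  cpp_col2im_k2(cols, as.integer(c(in_dims, n_ch, n_batch)))
}

# rows (prod(o)*n, c_out) -> feature array (o, c_out, n)
rows_to_feat <- function(m, o, n_batch) {
  cpp_rows_to_feat(m, as.integer(o), as.integer(n_batch))
}

feat_to_rows <- function(a) {
  cpp_feat_to_rows(a, as.integer(dim(a)))
}

conv_down_fwd <- function(x, W, b) {
  d <- dim(x)
  cols <- im2col_k2(x)
  o <- attr(cols, "odims")
  pre <- cols %*% W
  pre <- sweep_add_rows(pre, b)
  list(out = rows_to_feat(pre, o, d[5]), cols = cols, o = o, in_dims = d[1:3],
       n_ch = d[4], n_batch = d[5])
}

conv_down_bwd <- function(cache, W, d_out) {
  d_rows <- feat_to_rows(d_out)
  dW <- crossprod(cache$cols, d_rows)
  db <- colSums(d_rows)
  d_cols <- tcrossprod(d_rows, W)
  dx <- col2im_k2(d_cols, cache$in_dims, cache$n_ch, cache$n_batch)
  list(dx = dx, dW = dW, db = db)
}

# transposed kernel-2/stride-2 convolution: each input voxel emits a 2x2x2
# block. Wt has dim (c_in, 8*c_out) with columns ordered (kx,ky,kz,c_out).
conv_up_fwd <- function(x, Wt, b, target_dims = NULL) {
  d <- dim(x)
  rows <- feat_to_rows(x)               # (prod(d)*n, c_in)
  out <- rows %*% Wt                    # (prod(d)*n, 8*c_out)
  n_out <- ncol(Wt) %/% 8L
  out <- cpp_expand_k2(out, as.integer(d[1:3]), as.integer(n_out),
                       as.integer(d[5]))
  pad <- c(0L, 0L, 0L)
  if (!is.null(target_dims)) {
    pad <- target_dims - dim(out)[1:3]
    if (any(pad < 0L) || any(pad > 1L)) stop("unreachable target dims for transposed convolution")
    if (any(pad > 0L)) out <- pad_replicate_edge(out, target_dims)
  }
  out <- sweep_channel_add(out, b)
  list(out = out, rows = rows, in_dims = d[1:3], n_batch = d[5], pad = pad)
}

conv_up_bwd <- function(cache, Wt, d_out) {
  db <- channel_sums(d_out)
  if (any(cache$pad > 0L)) d_out <- fold_replicated_edge(d_out, cache$pad)
  d <- cache$in_dims
  n <- cache$n_batch
  n_out <- dim(d_out)[4]
  d_out <- cpp_collapse_k2(d_out, as.integer(d), as.integer(n_out),
                           as.integer(n))
  dWt <- crossprod(cache$rows, d_out)
  d_rows <- tcrossprod(d_out, Wt)
  dim(d_rows) <- c(d[1], d[2], d[3], n, nrow(Wt))
  list(dx = aperm(d_rows, c(1L, 2L, 3L, 5L, 4L)), dW = dWt, db = db)
}

# replicate the last slice along axes where target exceeds current dim
pad_replicate_edge <- function(a, target_dims) {
  d <- dim(a)
  for (ax in 1:3) {
    while (d[ax] < target_dims[ax]) {
      idx <- lapply(seq_along(d), function(i) seq_len(d[i]))
      idx[[ax]] <- c(seq_len(d[ax]), d[ax])
      a <- do.call(`[`, c(list(a), idx, list(drop = FALSE)))
      d <- dim(a)
    }
  }
  a
}

take_slice <- function(a, ax, pos) {
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- pos
  do.call(`[`, c(list(a), idx, list(drop = FALSE)))
}

assign_slice <- function(a, ax, pos, value) {
  idx <- lapply(dim(a), seq_len)
  idx[[ax]] <- pos
  do.call(`[<-`, c(list(a), idx, list(value = value)))
}

# accumulate gradients from replicated edge slices back onto their source
fold_replicated_edge <- function(g, pad) {
  for (ax in 1:3) {
    if (pad[ax] > 0L) {
      n <- dim(g)[ax]
      last <- take_slice(g, ax, n)
      g <- take_slice(g, ax, seq_len(n - 1L))
      g <- assign_slice(g, ax, n - 1L, take_slice(g, ax, n - 1L) + last)
    }
  }
  g
}

# ---- general strided convolution (gather-index im2col) -------------------

# Precompute gather indices for kernel k, stride s over spatial dims d.
im2col_plan <- function(d, k, s) {
  o <- (d - k) %/% s + 1L
  if (any(o < 1L)) stop("spatial dims too small for this kernel", call. = FALSE)
  off <- as.matrix(expand.grid(kx = 0:(k - 1L), ky = 0:(k - 1L), kz = 0:(k - 1L)))
  base <- as.matrix(expand.grid(
    x = seq.int(0L, by = s, length.out = o[1]),
    y = seq.int(0L, by = s, length.out = o[2]),
    z = seq.int(0L, by = s, length.out = o[3])
  ))
  lin <- function(p) 1L + p[, 1] + d[1] * (p[, 2] + d[2] * p[, 3])
  # I[patch, offset]
  I <- outer(lin(base) - 1L, as.vector(lin(off)), `+`)
  list(I = I, o = o, k3 = k^3, d = d)
}

# x (x,y,z,c,n) -> cols (npatch*n, k3*c); rows ordered (patch fastest, n)
im2col_gather <- function(x, plan) {
  d <- dim(x)
  vox <- prod(plan$d)
  dim(x) <- c(vox, d[4] * d[5])
  g <- x[as.vector(plan$I), , drop = FALSE]       # (npatch*k3, c*n)
  np <- nrow(plan$I)
  dim(g) <- c(np, plan$k3, d[4], d[5])
  g <- aperm(g, c(1L, 4L, 2L, 3L))
  dim(g) <- c(np * d[5], plan$k3 * d[4])
  g
}

im2col_scatter <- function(d_cols, plan, n_ch, n_batch) {
  np <- nrow(plan$I)
  dim(d_cols) <- c(np, n_batch, plan$k3, n_ch)
  d_cols <- aperm(d_cols, c(1L, 3L, 4L, 2L))
  dim(d_cols) <- c(np * plan$k3, n_ch * n_batch)
  grp <- as.vector(plan$I)
  acc <- rowsum(d_cols, group = grp)
  vox <- prod(plan$d)
  out <- matrix(0, vox, n_ch * n_batch)
  out[as.integer(rownames(acc)), ] <- acc
  dim(out) <- c(plan$d, n_ch, n_batch)
  out
}

conv_gen_fwd <- function(x, W, b, plan) {
  d <- dim(x)
  cols <- im2col_gather(x, plan)
  pre <- sweep_add_rows(cols %*% W, b)
  list(out = rows_to_feat(pre, plan$o, d[5]), cols = cols,
       n_ch = d[4], n_batch = d[5])
}

conv_gen_bwd <- function(cache, W, plan, d_out) {
  d_rows <- feat_to_rows(d_out)
  dW <- crossprod(cache$cols, d_rows)
  db <- colSums(d_rows)
  d_cols <- tcrossprod(d_rows, W)
  dx <- im2col_scatter(d_cols, plan, cache$n_ch, cache$n_batch)
  list(dx = dx, dW = dW, db = db)
}

# ---- elementwise / dense pieces ------------------------------------------

sweep_add_rows <- function(m, b) m + rep(b, each = nrow(m))

sweep_channel_add <- function(a, b) {
  d <- dim(a)
  dim(a) <- c(prod(d[1:3]), d[4], d[5])
  a <- a + rep(b, each = dim(a)[1])
  dim(a) <- d
  a
}

channel_sums <- function(a) {
  d <- dim(a)
  dim(a) <- c(prod(d[1:3]), d[4], d[5])
  rowSums(colSums(a))
}

relu_fwd <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}
relu_bwd <- function(cache, d_out) d_out * cache$mask

sigmoid <- function(x) 1 / (1 + exp(-x))

# ---- batch normalization (per column of a row-major activation matrix) ---

bn_init <- function(n_ch) {
  list(gamma = rep(1, n_ch), beta = rep(0, n_ch),
       run_mean = rep(0, n_ch), run_var = rep(1, n_ch))
}

bn_fwd <- function(x, bn, training, momentum = 0.1, eps = 1e-5) {
  if (training) {
    m <- nrow(x)
    mu <- colMeans(x)
    xc <- x - rep(mu, each = m)
    v <- colMeans(xc * xc)
    inv <- 1 / sqrt(v + eps)
    xhat <- xc * rep(inv, each = m)
    bn$run_mean <- (1 - momentum) * bn$run_mean + momentum * mu
    bn$run_var <- (1 - momentum) * bn$run_var + momentum * v * m / max(1, m - 1)
    out <- xhat * rep(bn$gamma, each = m) + rep(bn$beta, each = m)
    list(out = out, bn = bn, cache = list(xhat = xhat, inv = inv))
  } else {
    m <- nrow(x)
    inv <- 1 / sqrt(bn$run_var + eps)
    out <- (x - rep(bn$run_mean, each = m)) * rep(bn$gamma * inv, each = m) +
      rep(bn$beta, each = m)
    list(out = out, bn = bn, cache = NULL)
  }
}

bn_bwd <- function(cache, bn, d_out) {
  m <- nrow(d_out)
  dgamma <- colSums(d_out * cache$xhat)
  dbeta <- colSums(d_out)
  dx <- rep(bn$gamma * cache$inv / m, each = m) *
    (m * d_out - rep(dbeta, each = m) - cache$xhat * rep(dgamma, each = m))
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

dropout_fwd <- function(x, rate, training) {
  if (!training || rate <= 0) return(list(out = x, mask = NULL))
  keep <- 1 - rate
  mask <- (matrix(stats::runif(length(x)), nrow(x)) < keep) / keep
  list(out = x * mask, mask = mask)
}
dropout_bwd <- function(cache, d_out) {
  if (is.null(cache$mask)) d_out else d_out * cache$mask
}

# ---- Adam optimizer -------------------------------------------------------

adam_init <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

adam_step <- function(params, grads, state, t, lr = 0.001,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  bc1 <- 1 - beta1^t
  bc2 <- 1 - beta2^t
  for (nm in names(params)) {
    g <- grads[[nm]]
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr * (st$m / bc1) / (sqrt(st$v / bc2) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}

# He-style initial weights
winit <- function(n_in, n_out, fan_in) {
  matrix(stats::rnorm(n_in * n_out, sd = sqrt(2 / fan_in)), n_in, n_out)
}
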