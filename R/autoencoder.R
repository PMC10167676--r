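#' Latent grid
#'
#' The 4-D channelled representation produced by the encoder: `channels`
#' volumetric feature maps over a spatially downsampled grid (default
#' 32 maps of 15 x 18 x 15 for 121 x 145 x 121 input).
#'
#' @param values A numeric 4-D array `(x, y, z, channel)`.
#' @param subject_id Optional subject identifier carried through from the
#'   input volume. Latent grids deliberately carry no site information.
#' @return A `latent_grid` object.
#' @export
latent_grid <- function(values, subject_id = NA_character_) {
  if (!is.array(values) || length(dim(values)) != 4L) {
    stop("`values` must be a 4-D array (x, y, z, channel)", call. = FALSE)
  }
  if (any(!is.finite(values))) stop("latent values must be finite", call. = FALSE)
  structure(list(values = values, subject_id = as.character(subject_id)),
            class = "latent_grid")
}

#' @export
dim.latent_grid <- function(x) dim(x$values)

#' @export
print.latent_grid <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<latent_grid> %s  %d channels x %d x %d x %d\n",
              x$subject_id, d[4], d[1], d[2], d[3]))
  invisible(x)
}

#' Latent spatial dims after three stride-2 halvings
#'
#' Kernel-2, stride-2, no-padding convolution floor-halves each axis; three
#' encoder stages give `floor(floor(floor(d/2)/2)/2)`.
#'
#' @param input_dims Integer triple.
#' @return Integer triple of latent spatial dims.
#' @export
latent_spatial_dims <- function(input_dims) {
  d <- as.integer(input_dims)
  for (i in 1:3) d <- d %/% 2L
  d
}

#' Build an undercomplete 3D convolutional autoencoder
#'
#' Encoder: three kernel-2/stride-2 convolution stages (channel pyramid
#' 1 -> `hidden_channels[1]` -> `hidden_channels[2]` -> `latent_channels`)
#' with rectifier activations. Decoder: three kernel-2/stride-2 transposed
#' convolution stages mirroring the pyramid, rectifiers on the first two and
#' a logistic sigmoid on the final layer so reconstructions live in [0, 1].
#' Weights are He-initialised from the current RNG state.
#'
#' @param input_dims Integer triple; every axis must support three halvings
#'   (each dim at least 8).
#' @param latent_channels Number of latent feature maps (default 32).
#' @param hidden_channels Intermediate encoder channel counts (length 2).
#' @return An `ae_params` object.
#' @export
build_autoencoder <- function(input_dims, latent_channels = 32L,
                              hidden_channels = c(8L, 16L)) {
  input_dims <- as.integer(input_dims)
  if (length(input_dims) != 3L || any(input_dims < 8L)) {
    stop("each input dim must be >= 8 to allow three stride-2 halvings", call. = FALSE)
  }
  c1 <- as.integer(hidden_channels[1]); c2 <- as.integer(hidden_channels[2])
  cl <- as.integer(latent_channels)
  p <- list(
    W1 = winit(8L * 1L, c1, 8),  b1 = rep(0, c1),
    W2 = winit(8L * c1, c2, 8 * c1), b2 = rep(0, c2),
    W3 = winit(8L * c2, cl, 8 * c2), b3 = rep(0, cl),
    U1 = winit(cl, 8L * c2, cl), d1 = rep(0, c2),
    U2 = winit(c2, 8L * c1, c2), d2 = rep(0, c1),
    U3 = winit(c1, 8L * 1L, c1), d3 = rep(0, 1)
  )
  structure(
    list(params = p, input_dims = input_dims, latent_channels = cl,
         hidden_channels = c(c1, c2),
         latent_dims = latent_spatial_dims(input_dims)),
    class = "ae_params"
  )
}

#' @export
print.ae_params <- function(x, ...) {
  cat(sprintf(
    "<ae_params> input %s -> latent %d x %s (%.3g%% of input)\n",
    paste(x$input_dims, collapse = "x"), x$latent_channels,
    paste(x$latent_dims, collapse = "x"),
    100 * latent_compression_fraction(x)
  ))
  invisible(x)
}

#' Latent compression fraction
#'
#' Ratio of latent element count to input voxel count; the autoencoder is
#' undercomplete so this is well below 1.
#'
#' @param p An `ae_params`.
#' @return A single number in (0, 1).
#' @export
latent_compression_fraction <- function(p) {
  (p$latent_channels * prod(p$latent_dims)) / prod(p$input_dims)
}

# batch forward through the encoder; x is (x,y,z,1,n)
ae_encode_fwd <- function(p, x, with_cache = FALSE) {
  pr <- p$params
  dims <- p$input_dims
  c1f <- conv_down_fwd(x, pr$W1, pr$b1); a1 <- relu_fwd(c1f$out)
  c2f <- conv_down_fwd(a1$out, pr$W2, pr$b2); a2 <- relu_fwd(c2f$out)
  c3f <- conv_down_fwd(a2$out, pr$W3, pr$b3); a3 <- relu_fwd(c3f$out)
  res <- list(z = a3$out)
  if (with_cache) res$cache <- list(c1 = c1f, a1 = a1, c2 = c2f, a2 = a2,
                                    c3 = c3f, a3 = a3)
  res
}

# batch forward through the decoder; z is (x,y,z,cl,n)
ae_decode_fwd <- function(p, z, with_cache = FALSE) {
  pr <- p$params
  t3 <- p$input_dims
  t2 <- t3 %/% 2L
  t1 <- t2 %/% 2L
  u1f <- conv_up_fwd(z, pr$U1, pr$d1, target_dims = t1); g1 <- relu_fwd(u1f$out)
  u2f <- conv_up_fwd(g1$out, pr$U2, pr$d2, target_dims = t2); g2 <- relu_fwd(u2f$out)
  u3f <- conv_up_fwd(g2$out, pr$U3, pr$d3, target_dims = t3)
  xhat <- sigmoid(u3f$out)
  res <- list(xhat = xhat)
  if (with_cache) res$cache <- list(u1 = u1f, g1 = g1, u2 = u2f, g2 = g2, u3 = u3f)
  res
}

# full backward pass; returns gradient list matching p$params
ae_backward <- function(p, enc, dec, d_xhat) {
  pr <- p$params
  g <- list()
  # sigmoid
  d_pre <- d_xhat * dec$xhat * (1 - dec$xhat)
  b3 <- conv_up_bwd(dec$cache$u3, pr$U3, d_pre)
  g$U3 <- b3$dW; g$d3 <- b3$db
  d <- relu_bwd(dec$cache$g2, b3$dx)
  b2 <- conv_up_bwd(dec$cache$u2, pr$U2, d)
  g$U2 <- b2$dW; g$d2 <- b2$db
  d <- relu_bwd(dec$cache$g1, b2$dx)
  b1 <- conv_up_bwd(dec$cache$u1, pr$U1, d)
  g$U1 <- b1$dW; g$d1 <- b1$db
  d <- relu_bwd(enc$cache$a3, b1$dx)
  e3 <- conv_down_bwd(enc$cache$c3, pr$W3, d)
  g$W3 <- e3$dW; g$b3 <- e3$db
  d <- relu_bwd(enc$cache$a2, e3$dx)
  e2 <- conv_down_bwd(enc$cache$c2, pr$W2, d)
  g$W2 <- e2$dW; g$b2 <- e2$db
  d <- relu_bwd(enc$cache$a1, e2$dx)
  e1 <- conv_down_bwd(enc$cache$c1, pr$W1, d)
  g$W1 <- e1$dW; g$b1 <- e1$db
  g
}

#' Stack volumes into a batch array
#'
#' @param volumes List of `jacobian_volume`s sharing dims.
#' @return A 5-D array `(x, y, z, 1, n)`.
#' @export
volumes_to_batch <- function(volumes) {
  d <- dim(volumes[[1]]$voxels)
  out <- array(0, c(d, 1L, length(volumes)))
  for (i in seq_along(volumes)) out[, , , 1L, i] <- volumes[[i]]$voxels
  out
}

#' Encode a volume into its latent grid
#'
#' Deterministic forward pass through the trained encoder (no dropout is
#' used anywhere in the autoencoder).
#'
#' @param p An `ae_params`.
#' @param x A `jacobian_volume` at stage `"scaled"` (perturbed copies with
#'   values outside \[0, 1\] are accepted), or a plain 3-D array.
#' @return A [latent_grid()].
#' @export
encode <- function(p, x) {
  stopifnot(inherits(p, "ae_params"))
  sid <- NA_character_
  if (inherits(x, "jacobian_volume")) {
    sid <- x$subject_id
    x <- x$voxels
  }
  if (!all(dim(x) == p$input_dims)) {
    stop("volume dims do not match autoencoder input dims", call. = FALSE)
  }
  xb <- x
  dim(xb) <- c(dim(x), 1L, 1L)
  z <- ae_encode_fwd(p, xb)$z
  dim(z) <- dim(z)[1:4]
  latent_grid(z, subject_id = sid)
}

#' Encode a batch of volumes at once
#'
#' @param p An `ae_params`.
#' @param xb A 5-D array `(x, y, z, 1, n)` (see [volumes_to_batch()]) or a
#'   list of `jacobian_volume`s.
#' @return A 5-D latent array `(x, y, z, channels, n)`.
#' @export
encode_batch <- function(p, xb) {
  if (is.list(xb)) xb <- volumes_to_batch(xb)
  ae_encode_fwd(p, xb)$z
}

#' Decode a latent grid back to image space
#'
#' @param p An `ae_params`.
#' @param z A [latent_grid()].
#' @return A `jacobian_volume` with dims exactly `p$input_dims`, values in
#'   \[0, 1\] (final sigmoid).
#' @export
decode <- function(p, z) {
  stopifnot(inherits(p, "ae_params"), inherits(z, "latent_grid"))
  if (!all(dim(z$values)[1:3] == p$latent_dims) ||
      dim(z$values)[4] != p$latent_channels) {
    stop("latent dims do not match autoencoder parameters", call. = FALSE)
  }
  zb <- z$values
  dim(zb) <- c(dim(z$values), 1L)
  xhat <- ae_decode_fwd(p, zb)$xhat
  dim(xhat) <- dim(xhat)[1:3]
  jacobian_volume(xhat, subject_id = z$subject_id, stage = "scaled")
}

#' Mean squared reconstruction error
#'
#' @param x,x_prime `jacobian_volume`s (or plain arrays) with equal dims.
#' @return Mean over all voxels of the squared difference.
#' @export
reconstruction_error <- function(x, x_prime) {
  a <- if (inherits(x, "jacobian_volume")) x$voxels else x
  b <- if (inherits(x_prime, "jacobian_volume")) x_prime$voxels else x_prime
  if (!all(dim(a) == dim(b))) stop("dims mismatch", call. = FALSE)
  mean((a - b)^2)
}

ae_loss_on <- function(p, xb, chunk = 16L) {
  n <- dim(xb)[5]
  tot <- 0
  for (s in seq(1L, n, by = chunk)) {
    idx <- s:min(n, s + chunk - 1L)
    sub <- xb[, , , , idx, drop = FALSE]
    xhat <- ae_decode_fwd(p, ae_encode_fwd(p, sub)$z)$xhat
    tot <- tot + sum((xhat - sub)^2)
  }
  tot / length(xb)
}

#' Train the autoencoder
#'
#' Joint stochastic-gradient (Adam) optimization of encoder and decoder to
#' minimize mean-squared reconstruction error, with the held-out partition
#' of `split` tracked for convergence monitoring.
#'
#' @param volumes List of preprocessed (`"scaled"`, masked)
#'   `jacobian_volume`s.
#' @param split A [stratified_split()] plan (or any list with `train_ids`
#'   and `test_ids` index vectors into `volumes`).
#' @param steps Number of optimizer update steps (default 2500).
#' @param learning_rate Peak Adam learning rate (default 0.01).
#' @param batch_size Minibatch size (default 8).
#' @param lr_schedule `"cosine"` (default) anneals the learning rate to
#'   zero over `steps`; `"constant"` keeps it fixed.
#' @param latent_channels,hidden_channels Architecture, see
#'   [build_autoencoder()].
#' @param eval_every Evaluate held-out loss every this many steps.
#' @param seed Integer seed controlling initialisation and batch order.
#' @return An `ae_fit`: list with `params` (`ae_params`), `trace` (a tibble
#'   with `step`, `train_loss`, `test_loss`), and `final_test_loss`.
#' @export
train_autoencoder <- function(volumes, split, steps = 2500L,
                              learning_rate = 0.01, batch_size = 8L,
                              latent_channels = 32L,
                              hidden_channels = c(8L, 16L),
                              lr_schedule = c("cosine", "constant"),
                              eval_every = 100L, seed = 1L) {
  lr_schedule <- match.arg(lr_schedule)
  tr_ids <- split$train_ids
  te_ids <- split$test_ids
  if (length(tr_ids) < 2L) stop("need at least 2 training volumes", call. = FALSE)
  if (length(te_ids) < 1L) stop("empty held-out partition", call. = FALSE)
  set.seed(seed)
  dims <- dim(volumes[[1]]$voxels)
  p <- build_autoencoder(dims, latent_channels, hidden_channels)
  xb_tr <- volumes_to_batch(volumes[tr_ids])
  xb_te <- volumes_to_batch(volumes[te_ids])
  n_tr <- length(tr_ids)
  st <- adam_init(p$params)
  trace_step <- integer(0); trace_train <- numeric(0); trace_test <- numeric(0)
  order_pool <- integer(0)
  for (t in seq_len(steps)) {
    if (length(order_pool) < batch_size) {
      order_pool <- c(order_pool, sample.int(n_tr))
    }
    idx <- order_pool[seq_len(min(batch_size, n_tr))]
    order_pool <- order_pool[-seq_len(min(batch_size, n_tr))]
    xb <- xb_tr[, , , , idx, drop = FALSE]
    enc <- ae_encode_fwd(p, xb, with_cache = TRUE)
    dec <- ae_decode_fwd(p, enc$z, with_cache = TRUE)
    resid <- dec$xhat - xb
    loss <- mean(resid^2)
    d_xhat <- 2 * resid / length(resid)
    g <- ae_backward(p, enc, dec, d_xhat)
    lr_t <- if (lr_schedule == "cosine") {
      learning_rate * 0.5 * (1 + cos(pi * (t - 1) / steps))
    } else {
      learning_rate
    }
    upd <- adam_step(p$params, g, st, t, lr = lr_t)
    p$params <- upd$params; st <- upd$state
    if (t %% eval_every == 0L || t == steps) {
      te_loss <- ae_loss_on(p, xb_te)
      trace_step <- c(trace_step, t)
      trace_train <- c(trace_train, loss)
      trace_test <- c(trace_test, te_loss)
    }
  }
  structure(
    list(
      params = p,
      trace = tibble::tibble(step = trace_step, train_loss = trace_train,
                             test_loss = trace_test),
      final_test_loss = trace_test[length(trace_test)],
      seed = seed
    ),
    class = "ae_fit"
  )
}

#' @export
print.ae_fit <- function(x, ...) {
  cat(sprintf("<ae_fit> %d steps, final held-out MSE %.3g\n",
              max(x$trace$step), x$final_test_loss))
  invisible(x)
}
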