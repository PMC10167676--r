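# Gradient correctness of the hand-written layers against central
# finite differences, on deliberately awkward (odd, cropped, padded) dims.

ns <- asNamespace("dbmnet")

num_grad <- function(f, x, eps = 1e-6) {
  g <- array(0, dim(as.array(x)))
  for (k in seq_along(x)) {
    xp <- x; xp[k] <- xp[k] + eps
    xm <- x; xm[k] <- xm[k] - eps
    g[k] <- (f(xp) - f(xm)) / (2 * eps)
  }
  g
}

test_that("stride-2 convolution gradients match finite differences (with cropping)", {
  set.seed(1)
  x <- array(rnorm(5 * 6 * 7 * 2 * 2), c(5L, 6L, 7L, 2L, 2L))
  W <- matrix(rnorm(16 * 3), 16, 3); b <- rnorm(3)
  fw <- ns$conv_down_fwd(x, W, b)
  R <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- ns$conv_down_bwd(fw, W, R)
  expect_lt(max(abs(num_grad(function(xx) sum(ns$conv_down_fwd(xx, W, b)$out * R), x) - bw$dx)), 1e-6)
  expect_lt(max(abs(num_grad(function(WW) sum(ns$conv_down_fwd(x, WW, b)$out * R), W) - bw$dW)), 1e-6)
  expect_lt(max(abs(num_grad(function(bb) sum(ns$conv_down_fwd(x, W, bb)$out * R), b) - bw$db)), 1e-6)
})

test_that("transposed convolution gradients match finite differences (with odd-dim padding)", {
  set.seed(2)
  z <- array(rnorm(3 * 3 * 3 * 2 * 2), c(3L, 3L, 3L, 2L, 2L))
  Wt <- matrix(rnorm(2 * 24), 2, 24); b <- rnorm(3)
  tgt <- c(7L, 6L, 7L)  # pads x and z by edge replication
  fw <- ns$conv_up_fwd(z, Wt, b, target_dims = tgt)
  expect_identical(dim(fw$out)[1:3], tgt)
  R <- array(rnorm(length(fw$out)), dim(fw$out))
  bw <- ns$conv_up_bwd(fw, Wt, R)
  expect_lt(max(abs(num_grad(function(zz) sum(ns$conv_up_fwd(zz, Wt, b, target_dims = tgt)$out * R), z) - bw$dx)), 1e-6)
  expect_lt(max(abs(num_grad(function(WW) sum(ns$conv_up_fwd(z, WW, b, target_dims = tgt)$out * R), Wt) - bw$dW)), 1e-6)
  expect_lt(max(abs(num_grad(function(bb) sum(ns$conv_up_fwd(z, Wt, bb, target_dims = tgt)$out * R), b) - bw$db)), 1e-6)
})

test_that("general strided im2col matches a naive loop and scatters exactly", {
  set.seed(3)
  d <- c(7L, 6L, 5L)
  x <- array(rnorm(prod(d) * 2 * 2), c(d, 2L, 2L))
  plan <- ns$im2col_plan(d, 3L, 2L)
  cols <- ns$im2col_gather(x, plan)
  # naive: for sample 1, channel 1, first patch at (1,1,1)
  patch <- x[1:3, 1:3, 1:3, 1, 1]
  expect_equal(cols[1, 1:27], as.vector(patch))
  # patch 2 advances x by stride 2
  expect_equal(cols[2, 1:27], as.vector(x[3:5, 1:3, 1:3, 1, 1]))
  # channel 2 occupies the next 27 columns
  expect_equal(cols[1, 28:54], as.vector(x[1:3, 1:3, 1:3, 2, 1]))
  # scatter-gather adjoint identity: <gather(x), C> == <x, scatter(C)>
  C <- matrix(rnorm(length(cols)), nrow(cols))
  sc <- ns$im2col_scatter(C, plan, 2L, 2L)
  expect_equal(sum(cols * C), sum(x * sc), tolerance = 1e-10)
})

test_that("full autoencoder backward pass matches finite differences", {
  set.seed(4)
  p <- build_autoencoder(c(8L, 9L, 10L), latent_channels = 3L,
                         hidden_channels = c(2L, 3L))
  for (nm in c("b1", "b2", "b3", "d1", "d2", "d3")) {
    p$params[[nm]] <- rnorm(length(p$params[[nm]]), sd = 0.1)
  }
  xb <- array(runif(8 * 9 * 10 * 2), c(8L, 9L, 10L, 1L, 2L))
  lossfn <- function(pp) {
    q <- p; q$params <- pp
    mean((ns$ae_decode_fwd(q, ns$ae_encode_fwd(q, xb)$z)$xhat - xb)^2)
  }
  enc <- ns$ae_encode_fwd(p, xb, with_cache = TRUE)
  dec <- ns$ae_decode_fwd(p, enc$z, with_cache = TRUE)
  g <- ns$ae_backward(p, enc, dec, 2 * (dec$xhat - xb) / length(xb))
  eps <- 1e-6; worst <- 0
  for (nm in names(p$params)) {
    ks <- sample(seq_along(p$params[[nm]]), min(6, length(p$params[[nm]])))
    for (k in ks) {
      pp <- p$params; pp[[nm]][k] <- pp[[nm]][k] + eps
      pm <- p$params; pm[[nm]][k] <- pm[[nm]][k] - eps
      worst <- max(worst, abs((lossfn(pp) - lossfn(pm)) / (2 * eps) - g[[nm]][k]))
    }
  }
  expect_lt(worst, 1e-6)
})

test_that("classifier backward pass matches finite differences", {
  set.seed(5)
  cp <- build_classifier(c(5L, 6L, 5L), latent_channels = 4L,
                         conv_channels = 3L, fc_units = 6L, dropout_rate = 0)
  zb <- array(rnorm(5 * 6 * 5 * 4 * 6), c(5L, 6L, 5L, 4L, 6L))
  y <- c(1, 0, 1, 1, 0, 0)
  pack <- function(q) c(q$params, list(
    bn_conv_gamma = q$bn_conv$gamma, bn_conv_beta = q$bn_conv$beta,
    bn_fc_gamma = q$bn_fc$gamma, bn_fc_beta = q$bn_fc$beta))
  lossc <- function(op) {
    q <- cp
    q$params[names(q$params)] <- op[names(q$params)]
    q$bn_conv$gamma <- op$bn_conv_gamma; q$bn_conv$beta <- op$bn_conv_beta
    q$bn_fc$gamma <- op$bn_fc_gamma; q$bn_fc$beta <- op$bn_fc_beta
    fw <- ns$cnn_fwd(q, zb, training = TRUE)
    ns$bce_loss(fw$logit, y)
  }
  fw <- ns$cnn_fwd(cp, zb, training = TRUE)
  g <- ns$cnn_bwd(cp, fw, (fw$prob - y) / length(y), with_dx = TRUE)
  op <- pack(cp); eps <- 1e-6; worst <- 0
  for (nm in names(op)) {
    ks <- sample(seq_along(op[[nm]]), min(8, length(op[[nm]])))
    for (k in ks) {
      op2 <- op; op2[[nm]][k] <- op2[[nm]][k] + eps
      om <- op; om[[nm]][k] <- om[[nm]][k] - eps
      worst <- max(worst, abs((lossc(op2) - lossc(om)) / (2 * eps) - g[[nm]][k]))
    }
  }
  expect_lt(worst, 1e-6)
  # input gradient
  worstx <- 0
  base_p <- lossc(op)
  for (k in sample(seq_along(zb), 10)) {
    zp <- zb; zp[k] <- zp[k] + eps
    zm <- zb; zm[k] <- zm[k] - eps
    fp <- ns$bce_loss(ns$cnn_fwd(cp, zp, training = TRUE)$logit, y)
    fm <- ns$bce_loss(ns$cnn_fwd(cp, zm, training = TRUE)$logit, y)
    worstx <- max(worstx, abs((fp - fm) / (2 * eps) - g$dx[k]))
  }
  expect_lt(worstx, 1e-6)
})

test_that("block reshape kernels are exact inverses", {
  set.seed(6)
  a <- array(rnorm(6 * 8 * 6 * 3 * 2), c(6L, 8L, 6L, 3L, 2L))
  cols <- ns$im2col_k2(a)
  back <- ns$col2im_k2(cols, c(6L, 8L, 6L), 3L, 2L)
  expect_equal(back, a)
  m <- matrix(rnorm(6 * 8 * 6 / 8 * 2 * 5), 6 * 8 * 6 / 8 * 2, 5)
  o <- c(3L, 4L, 3L)
  expect_equal(ns$feat_to_rows(ns$rows_to_feat(m, o, 2L)), m, ignore_attr = TRUE)
})
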