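#' Site-stratified train/test split
#'
#' Splits subjects so that each research site's cases and controls are
#' proportionally represented in the test set, preventing site-driven
#' classification shortcuts. Within every (site, group) stratum the test
#' count is `round half up(test_ratio * stratum size)`; the global test size
#' is the sum of the per-stratum counts.
#'
#' @param subjects A data frame with columns `group` (`"case"`/`"control"`)
#'   and `site`, or a `cohort` object.
#' @param test_ratio Fraction of each stratum held out, in (0, 1).
#' @param seed Integer seed; the split is deterministic given the seed.
#' @return A `split_plan`: list with integer `train_ids`, `test_ids`
#'   (row indices into `subjects`), `seed`, `test_ratio`.
#' @export
stratified_split <- function(subjects, test_ratio = 0.2, seed = 1L) {
  if (inherits(subjects, "cohort")) subjects <- subjects$subjects
  if (!is.numeric(test_ratio) || test_ratio <= 0 || test_ratio >= 1) {
    stop("`test_ratio` must lie strictly between 0 and 1", call. = FALSE)
  }
  stopifnot(all(c("group", "site") %in% names(subjects)))
  set.seed(seed)
  n <- nrow(subjects)
  strata <- split(seq_len(n), list(subjects$site, subjects$group), drop = TRUE)
  test_ids <- integer(0)
  for (ids in strata) {
    k <- floor(test_ratio * length(ids) + 0.5)  # round half up
    k <- min(k, length(ids))
    if (k > 0L) test_ids <- c(test_ids, sample(ids, k))
  }
  test_ids <- sort(test_ids)
  structure(
    list(train_ids = setdiff(seq_len(n), test_ids), test_ids = test_ids,
         seed = seed, test_ratio = test_ratio),
    class = "split_plan"
  )
}

#' @export
print.split_plan <- function(x, ...) {
  cat(sprintf("<split_plan> %d train / %d test (ratio %.2f, seed %d)\n",
              length(x$train_ids), length(x$test_ids), x$test_ratio, x$seed))
  invisible(x)
}

#' Build the latent-space CNN classifier
#'
#' One 3D convolution stage (kernel 3, stride 2, no padding; 24 output
#' channels) followed by a fully connected stage of 128 rectified units and
#' a single-logit output. Batch normalization follows the convolution and
#' the fully connected stage, each followed by dropout during training.
#'
#' @param latent_dims Integer triple of latent spatial dims (each >= 3).
#' @param latent_channels Latent channel count (default 32).
#' @param conv_channels Convolution output channels (default 24).
#' @param fc_units Fully connected width (default 128).
#' @param dropout_rate Dropout probability in training, default 0.5 (the
#'   useful range is 0.5-0.6).
#' @return A `cnn_params` object.
#' @export
build_classifier <- function(latent_dims, latent_channels = 32L,
                             conv_channels = 24L, fc_units = 128L,
                             dropout_rate = 0.5) {
  latent_dims <- as.integer(latent_dims)
  if (any(latent_dims < 3L)) stop("each latent dim must be >= 3 for a kernel-3 convolution", call. = FALSE)
  plan <- im2col_plan(latent_dims, 3L, 2L)
  n_feat <- prod(plan$o) * conv_channels
  p <- list(
    Wc = winit(27L * latent_channels, conv_channels, 27 * latent_channels),
    bc = rep(0, conv_channels),
    Wf = winit(n_feat, fc_units, n_feat), bf = rep(0, fc_units),
    Wo = winit(fc_units, 1L, fc_units), bo = 0
  )
  structure(
    list(params = p, bn_conv = bn_init(conv_channels), bn_fc = bn_init(fc_units),
         plan = plan, latent_dims = latent_dims, latent_channels = latent_channels,
         conv_channels = conv_channels, conv_out_dims = plan$o,
         fc_units = fc_units, dropout_rate = dropout_rate),
    class = "cnn_params"
  )
}

#' @export
print.cnn_params <- function(x, ...) {
  cat(sprintf(
    "<cnn_params> latent %d x %s -> conv %d @ %s -> fc %d -> 1 logit (dropout %.2f)\n",
    x$latent_channels, paste(x$latent_dims, collapse = "x"),
    x$conv_channels, paste(x$conv_out_dims, collapse = "x"),
    x$fc_units, x$dropout_rate
  ))
  invisible(x)
}

# forward through classifier; zb is (x,y,z,cl,n); returns logits and caches
cnn_fwd <- function(cp, zb, training = FALSE) {
  pr <- cp$params
  n <- dim(zb)[5]
  np <- nrow(cp$plan$I)
  cols <- im2col_gather(zb, cp$plan)
  pre <- sweep_add_rows(cols %*% pr$Wc, pr$bc)           # (np*n, conv_ch)
  bn1 <- bn_fwd(pre, cp$bn_conv, training)
  r1 <- relu_fwd(bn1$out)
  dr1 <- dropout_fwd(r1$out, cp$dropout_rate, training)
  flat <- dr1$out
  dim(flat) <- c(np, n, cp$conv_channels)
  flat <- aperm(flat, c(2L, 1L, 3L))
  dim(flat) <- c(n, np * cp$conv_channels)
  pre2 <- sweep_add_rows(flat %*% pr$Wf, pr$bf)          # (n, fc)
  bn2 <- bn_fwd(pre2, cp$bn_fc, training)
  r2 <- relu_fwd(bn2$out)
  dr2 <- dropout_fwd(r2$out, cp$dropout_rate, training)
  logit <- drop(dr2$out %*% pr$Wo) + pr$bo
  list(logit = logit, prob = sigmoid(logit),
       cache = list(cols = cols, bn1 = bn1, r1 = r1, dr1 = dr1, flat = flat,
                    bn2 = bn2, r2 = r2, dr2 = dr2, n = n, np = np),
       bn_conv = bn1$bn, bn_fc = bn2$bn)
}

cnn_bwd <- function(cp, fwd, d_logit, with_dx = FALSE) {
  pr <- cp$params
  ca <- fwd$cache
  g <- list()
  d_logit <- matrix(d_logit, ncol = 1L)
  g$Wo <- crossprod(ca$dr2$out, d_logit)
  g$bo <- sum(d_logit)
  d <- tcrossprod(d_logit, pr$Wo)
  d <- dropout_bwd(ca$dr2, d)
  d <- relu_bwd(ca$r2, d)
  b2 <- bn_bwd(ca$bn2$cache, cp$bn_fc, d)
  g$bn_fc_gamma <- b2$dgamma; g$bn_fc_beta <- b2$dbeta
  d <- b2$dx
  g$Wf <- crossprod(ca$flat, d)
  g$bf <- colSums(d)
  d <- tcrossprod(d, pr$Wf)                               # (n, np*conv)
  dim(d) <- c(ca$n, ca$np, cp$conv_channels)
  d <- aperm(d, c(2L, 1L, 3L))
  dim(d) <- c(ca$np * ca$n, cp$conv_channels)
  d <- dropout_bwd(ca$dr1, d)
  d <- relu_bwd(ca$r1, d)
  b1 <- bn_bwd(ca$bn1$cache, cp$bn_conv, d)
  g$bn_conv_gamma <- b1$dgamma; g$bn_conv_beta <- b1$dbeta
  d <- b1$dx
  g$Wc <- crossprod(ca$cols, d)
  g$bc <- colSums(d)
  if (with_dx) {
    d_cols <- tcrossprod(d, pr$Wc)
    g$dx <- im2col_scatter(d_cols, cp$plan, cp$latent_channels, ca$n)
  }
  g
}

bce_loss <- function(logit, y) {
  # numerically stable binary cross-entropy on the logit
  mean(pmax(logit, 0) - logit * y + log1p(exp(-abs(logit))))
}

latents_to_batch <- function(latents) {
  if (is.array(latents) && length(dim(latents)) == 5L) return(latents)
  d <- dim(latents[[1]]$values)
  out <- array(0, c(d, length(latents)))
  for (i in seq_along(latents)) out[, , , , i] <- latents[[i]]$values
  out
}

normalize_labels <- function(labels) {
  if (is.character(labels) || is.factor(labels)) {
    as.integer(as.character(labels) == "case")
  } else {
    as.integer(labels)
  }
}

#' Train the latent-space CNN classifier
#'
#' Binary cross-entropy on the single output logit, Adam optimization,
#' batch statistics for normalization and inverted dropout during training.
#' The held-out loss is checked every `check_every` update steps; training
#' stops early once the held-out loss has failed to improve on its running
#' minimum for `patience` consecutive checks while the train loss is
#' non-increasing, and the parameters from the best held-out checkpoint are
#' returned.
#'
#' @param latents List of [latent_grid()]s (or a 5-D array) for all
#'   subjects.
#' @param labels Binary labels (1/`"case"` = positive class).
#' @param split A [stratified_split()] plan.
#' @param learning_rate Adam learning rate (default 0.001).
#' @param check_every Steps between held-out loss checks (default 200).
#' @param dropout_rate Dropout probability, default 0.5.
#' @param batch_size Minibatch size (default 16).
#' @param max_steps Upper bound on update steps (default 4000).
#' @param patience Consecutive non-improving checks that trigger the stop.
#' @param weight_decay Decoupled L2 decay applied to the weight matrices
#'   (not biases or normalization parameters) each step (default 0.2,
#'   multiplied by the learning rate). Latent positions that are constant
#'   across training subjects (e.g. outside the brain mask) provide no
#'   gradient signal, and without decay the weights attached to them drift
#'   to arbitrary magnitudes under Adam, making predictions spuriously
#'   sensitive to perturbations there.
#' @param seed Integer seed for initialisation, batching and dropout.
#' @return A `cnn_fit`: `params` (`cnn_params` at the best checkpoint),
#'   `trace` tibble (`step`, `train_loss`, `test_loss`), `best_step`,
#'   `stopped_early`.
#' @export
train_classifier <- function(latents, labels, split, learning_rate = 0.001,
                             check_every = 200L, dropout_rate = 0.5,
                             batch_size = 16L, max_steps = 4000L,
                             patience = 5L, weight_decay = 0.2, seed = 1L) {
  y <- normalize_labels(labels)
  zb <- latents_to_batch(latents)
  tr <- split$train_ids; te <- split$test_ids
  if (length(unique(y[tr])) < 2L) stop("training labels contain a single class", call. = FALSE)
  set.seed(seed)
  cp <- build_classifier(dim(zb)[1:3], latent_channels = dim(zb)[4],
                         dropout_rate = dropout_rate)
  zb_tr <- zb[, , , , tr, drop = FALSE]; y_tr <- y[tr]
  zb_te <- zb[, , , , te, drop = FALSE]; y_te <- y[te]
  n_tr <- length(tr)
  opt_params <- c(cp$params, list(
    bn_conv_gamma = cp$bn_conv$gamma, bn_conv_beta = cp$bn_conv$beta,
    bn_fc_gamma = cp$bn_fc$gamma, bn_fc_beta = cp$bn_fc$beta
  ))
  st <- adam_init(opt_params)
  best <- list(loss = Inf, cp = cp, step = 0L)
  streak <- 0L
  prev_train <- Inf
  run_train <- 0; run_n <- 0L
  trace_step <- integer(0); trace_train <- numeric(0); trace_test <- numeric(0)
  stopped_early <- FALSE
  for (t in seq_len(max_steps)) {
    idx <- sample.int(n_tr, min(batch_size, n_tr))
    fw <- cnn_fwd(cp, zb_tr[, , , , idx, drop = FALSE], training = TRUE)
    cp$bn_conv <- fw$bn_conv; cp$bn_fc <- fw$bn_fc
    loss <- bce_loss(fw$logit, y_tr[idx])
    run_train <- run_train + loss; run_n <- run_n + 1L
    d_logit <- (fw$prob - y_tr[idx]) / length(idx)
    g <- cnn_bwd(cp, fw, d_logit)
    upd <- adam_step(opt_params, g, st, t, lr = learning_rate)
    opt_params <- upd$params; st <- upd$state
    if (weight_decay > 0) {
      shrink <- 1 - learning_rate * weight_decay
      for (nm in c("Wc", "Wf", "Wo")) opt_params[[nm]] <- opt_params[[nm]] * shrink
    }
    cp$params[names(cp$params)] <- opt_params[names(cp$params)]
    cp$bn_conv$gamma <- opt_params$bn_conv_gamma
    cp$bn_conv$beta <- opt_params$bn_conv_beta
    cp$bn_fc$gamma <- opt_params$bn_fc_gamma
    cp$bn_fc$beta <- opt_params$bn_fc_beta
    if (t %% check_every == 0L || t == max_steps) {
      te_fw <- cnn_fwd(cp, zb_te, training = FALSE)
      te_loss <- bce_loss(te_fw$logit, y_te)
      tr_loss <- run_train / max(1L, run_n)
      run_train <- 0; run_n <- 0L
      trace_step <- c(trace_step, t)
      trace_train <- c(trace_train, tr_loss)
      trace_test <- c(trace_test, te_loss)
      if (te_loss < best$loss) {
        best <- list(loss = te_loss, cp = cp, step = t)
        streak <- 0L
      } else if (tr_loss <= prev_train + 1e-12) {
        streak <- streak + 1L
      }
      prev_train <- tr_loss
      if (streak >= patience) { stopped_early <- TRUE; break }
    }
  }
  structure(
    list(params = best$cp,
         trace = tibble::tibble(step = trace_step, train_loss = trace_train,
                                test_loss = trace_test),
         best_step = best$step, best_test_loss = best$loss,
         stopped_early = stopped_early, seed = seed),
    class = "cnn_fit"
  )
}

#' @export
print.cnn_fit <- function(x, ...) {
  cat(sprintf("<cnn_fit> best held-out loss %.4f at step %d%s\n",
              x$best_test_loss, x$best_step,
              if (x$stopped_early) " (early stop)" else ""))
  invisible(x)
}

#' Predict the case probability for a latent grid
#'
#' Deterministic inference: dropout disabled, batch normalization uses its
#' stored running statistics. The probability is the logistic sigmoid of the
#' single output logit; the hard label uses a 0.5 threshold.
#'
#' @param p A `cnn_params` or `cnn_fit`.
#' @param z A [latent_grid()], a list of them, or a 5-D array.
#' @return A tibble with `subject_id`, `probability`, `hard_label`.
#' @export
predict_probability <- function(p, z) {
  if (inherits(p, "cnn_fit")) p <- p$params
  stopifnot(inherits(p, "cnn_params"))
  sids <- NA_character_
  if (inherits(z, "latent_grid")) {
    sids <- z$subject_id
    zb <- z$values; dim(zb) <- c(dim(zb), 1L)
  } else if (is.list(z)) {
    sids <- vapply(z, function(g) g$subject_id, character(1))
    zb <- latents_to_batch(z)
  } else {
    zb <- z
    sids <- rep(NA_character_, dim(zb)[5])
  }
  if (!all(dim(zb)[1:3] == p$latent_dims) || dim(zb)[4] != p$latent_channels) {
    stop("latent dims do not match classifier parameters", call. = FALSE)
  }
  fw <- cnn_fwd(p, zb, training = FALSE)
  tibble::tibble(
    subject_id = sids,
    probability = as.numeric(fw$prob),
    hard_label = ifelse(fw$prob >= 0.5, "case", "control")
  )
}
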