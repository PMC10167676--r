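#' PCA dimensionality reduction of volumes
#'
#' Flattens volumes to vectors, centers on the training mean and uses the
#' singular value decomposition to retain the smallest number of components
#' whose cumulative explained variance reaches `variance_retained`. The
#' basis is fitted on training volumes only; any other volume is projected
#' with the training mean and rotation.
#'
#' @param volumes List of `jacobian_volume`s (or a numeric matrix, one row
#'   per subject).
#' @param variance_retained Fraction of variance to keep, in (0, 1\];
#'   default 0.90.
#' @param train_ids Rows used to fit the basis (default: all).
#' @return A list with `features` (tibble `subject_id` + `PC*` columns for
#'   all volumes), `basis` (`center`, `rotation`, `explained_variance`,
#'   `n_components`).
#' @export
pca_reduce <- function(volumes, variance_retained = 0.90, train_ids = NULL) {
  if (variance_retained <= 0 || variance_retained > 1) {
    stop("`variance_retained` must lie in (0, 1]", call. = FALSE)
  }
  if (is.list(volumes) && inherits(volumes[[1]], "jacobian_volume")) {
    sids <- vapply(volumes, function(v) v$subject_id, character(1))
    X <- do.call(rbind, lapply(volumes, function(v) as.vector(v$voxels)))
  } else {
    X <- as.matrix(volumes)
    sids <- rownames(X) %||% sprintf("S%03d", seq_len(nrow(X)))
  }
  if (nrow(X) < 2L) stop("need at least 2 volumes", call. = FALSE)
  if (is.null(train_ids)) train_ids <- seq_len(nrow(X))
  Xtr <- X[train_ids, , drop = FALSE]
  ctr <- colMeans(Xtr)
  Xc <- sweep(Xtr, 2L, ctr)
  sv <- svd(Xc, nu = 0)
  ev <- sv$d^2 / (nrow(Xtr) - 1)
  ev <- ev[ev > max(ev) * 1e-12]
  if (length(ev) == 0L) stop("degenerate input: all volumes identical", call. = FALSE)
  cum <- cumsum(ev) / sum(ev)
  k <- which(cum >= variance_retained - 1e-12)[1]
  rot <- sv$v[, seq_len(k), drop = FALSE]
  scores <- sweep(X, 2L, ctr) %*% rot
  feats <- tibble::as_tibble(scores, .name_repair = ~ sprintf("PC%d", seq_len(k)))
  feats <- dplyr::bind_cols(tibble::tibble(subject_id = sids), feats)
  list(
    features = feats,
    basis = list(center = ctr, rotation = rot, explained_variance = ev,
                 cumulative_variance = cum, n_components = k)
  )
}

#' Flatten a latent grid to a feature vector
#'
#' Channel-major ordering: all voxels of channel 1 first (x slowest, z
#' fastest within a channel), then channel 2, and so on; the inverse
#' operation is [unflatten_latent()].
#'
#' @param z A [latent_grid()].
#' @return Numeric vector of length `channels * prod(spatial_dims)`.
#' @export
flatten_latent <- function(z) {
  stopifnot(inherits(z, "latent_grid"))
  # (x,y,z,c) -> (c,x,y,z) then flatten with z fastest inside each channel:
  # aperm to (z,y,x,c) reversed gives index = ((c*X + x)*Y + y)*Z + z
  as.vector(aperm(z$values, c(3L, 2L, 1L, 4L)))
}

#' @rdname flatten_latent
#' @param v Numeric vector from [flatten_latent()].
#' @param spatial_dims,channels Latent geometry.
#' @export
unflatten_latent <- function(v, spatial_dims, channels) {
  a <- array(v, c(rev(spatial_dims), channels))
  latent_grid(aperm(a, c(3L, 2L, 1L, 4L)))
}

#' Fit a reference classifier on feature vectors
#'
#' `margin_classifier` is a support vector machine at its documented
#' defaults (RBF kernel, cost 1, gamma `1/p`); `tree_ensemble` is a random
#' forest at its documented defaults (500 trees, `mtry = floor(sqrt(p))`).
#' The model is fitted on the split's training rows and evaluated on its
#' test rows.
#'
#' @param features Numeric matrix or data frame of features (rows =
#'   subjects; a `subject_id` column is dropped automatically).
#' @param labels Binary labels (`"case"` positive).
#' @param split A [stratified_split()] plan.
#' @param model `"margin_classifier"` or `"tree_ensemble"`.
#' @return A [confusion_metrics()] tibble for the test rows, with a
#'   `model` column and the fitted probabilities attached as
#'   `attr(, "predictions")`.
#' @export
fit_baseline <- function(features, labels, split,
                         model = c("margin_classifier", "tree_ensemble")) {
  model <- match.arg(model)
  if (is.data.frame(features)) {
    features <- as.matrix(features[setdiff(names(features), "subject_id")])
  }
  y <- factor(normalize_labels(labels), levels = c(0L, 1L))
  tr <- split$train_ids; te <- split$test_ids
  if (length(unique(y[tr])) < 2L) stop("training labels contain a single class", call. = FALSE)
  if (model == "margin_classifier") {
    # constant features carry no information and break the SVM's default
    # feature scaling; drop them based on the training partition
    keep <- apply(features[tr, , drop = FALSE], 2L, function(col) stats::var(col) > 0)
    if (!any(keep)) stop("all features are constant on the training partition", call. = FALSE)
    features <- features[, keep, drop = FALSE]
    fit <- e1071::svm(features[tr, , drop = FALSE], y[tr], probability = TRUE)
    pr <- attr(stats::predict(fit, features[te, , drop = FALSE], probability = TRUE),
               "probabilities")[, "1"]
  } else {
    fit <- randomForest::randomForest(features[tr, , drop = FALSE], y[tr])
    pr <- stats::predict(fit, features[te, , drop = FALSE], type = "prob")[, "1"]
  }
  m <- confusion_metrics(pr, as.integer(as.character(y[te])))
  m$model <- model
  attr(m, "predictions") <- tibble::tibble(row = te, probability = as.numeric(pr))
  m
}

full_cnn_fwd <- function(front, cp, xb, training = FALSE, with_cache = FALSE) {
  c1 <- conv_down_fwd(xb, front$F1, front$g1); a1 <- relu_fwd(c1$out)
  c2 <- conv_down_fwd(a1$out, front$F2, front$g2); a2 <- relu_fwd(c2$out)
  c3 <- conv_down_fwd(a2$out, front$F3, front$g3); a3 <- relu_fwd(c3$out)
  head <- cnn_fwd(cp, a3$out, training = training)
  res <- list(logit = head$logit, prob = head$prob, head = head)
  if (with_cache) res$cache <- list(c1 = c1, a1 = a1, c2 = c2, a2 = a2,
                                    c3 = c3, a3 = a3)
  res
}

#' CNN on full-dimensional volumes (no autoencoder)
#'
#' The latent-space classifier generalized to raw volumes: three extra
#' kernel-2 / stride-2 rectified convolution stages (channel pyramid
#' 8, 16, 32) downsample the volume, after which the standard classifier
#' head (kernel-3 convolution, batch norm, dropout, 128-unit fully
#' connected layer, single logit) is applied. The whole network is trained
#' end-to-end with the same loss, optimizer and early-stopping conventions
#' as [train_classifier()].
#'
#' @param volumes List of processed `jacobian_volume`s (each dim >= 24).
#' @param labels Binary labels (`"case"` positive).
#' @param split A [stratified_split()] plan.
#' @param learning_rate,check_every,dropout_rate,batch_size,max_steps,patience
#'   As in [train_classifier()].
#' @param seed Integer seed.
#' @return A list with `metrics` (test-set [confusion_metrics()] with
#'   `model` column), `predictions` tibble, `trace`, `best_step`.
#' @export
cnn_no_reduction <- function(volumes, labels, split, learning_rate = 0.001,
                             check_every = 200L, dropout_rate = 0.5,
                             batch_size = 16L, max_steps = 4000L,
                             patience = 5L, seed = 1L) {
  y <- normalize_labels(labels)
  dims <- dim(volumes[[1]]$voxels)
  if (any(dims < 24L)) stop("dims unsupported: each axis must be >= 24", call. = FALSE)
  if (length(unique(y[split$train_ids])) < 2L) {
    stop("training labels contain a single class", call. = FALSE)
  }
  set.seed(seed)
  ch <- c(8L, 16L, 32L)
  front <- list(
    F1 = winit(8L, ch[1], 8), g1 = rep(0, ch[1]),
    F2 = winit(8L * ch[1], ch[2], 8 * ch[1]), g2 = rep(0, ch[2]),
    F3 = winit(8L * ch[2], ch[3], 8 * ch[2]), g3 = rep(0, ch[3])
  )
  down_dims <- latent_spatial_dims(dims)
  cp <- build_classifier(down_dims, latent_channels = ch[3],
                         dropout_rate = dropout_rate)
  xb <- volumes_to_batch(volumes)
  tr <- split$train_ids; te <- split$test_ids
  xb_tr <- xb[, , , , tr, drop = FALSE]; y_tr <- y[tr]
  xb_te <- xb[, , , , te, drop = FALSE]; y_te <- y[te]
  n_tr <- length(tr)
  opt <- c(front, cp$params, list(
    bn_conv_gamma = cp$bn_conv$gamma, bn_conv_beta = cp$bn_conv$beta,
    bn_fc_gamma = cp$bn_fc$gamma, bn_fc_beta = cp$bn_fc$beta
  ))
  st <- adam_init(opt)
  best <- list(loss = Inf, front = front, cp = cp, step = 0L)
  streak <- 0L; prev_train <- Inf; run_train <- 0; run_n <- 0L
  trace_step <- integer(0); trace_train <- numeric(0); trace_test <- numeric(0)
  for (t in seq_len(max_steps)) {
    idx <- sample.int(n_tr, min(batch_size, n_tr))
    fw <- full_cnn_fwd(front, cp, xb_tr[, , , , idx, drop = FALSE],
                       training = TRUE, with_cache = TRUE)
    cp$bn_conv <- fw$head$bn_conv; cp$bn_fc <- fw$head$bn_fc
    loss <- bce_loss(fw$logit, y_tr[idx])
    run_train <- run_train + loss; run_n <- run_n + 1L
    g <- cnn_bwd(cp, fw$head, (fw$prob - y_tr[idx]) / length(idx), with_dx = TRUE)
    d <- relu_bwd(fw$cache$a3, g$dx); g$dx <- NULL
    b3 <- conv_down_bwd(fw$cache$c3, front$F3, d)
    g$F3 <- b3$dW; g$g3 <- b3$db
    d <- relu_bwd(fw$cache$a2, b3$dx)
    b2 <- conv_down_bwd(fw$cache$c2, front$F2, d)
    g$F2 <- b2$dW; g$g2 <- b2$db
    d <- relu_bwd(fw$cache$a1, b2$dx)
    b1 <- conv_down_bwd(fw$cache$c1, front$F1, d)
    g$F1 <- b1$dW; g$g1 <- b1$db
    upd <- adam_step(opt, g, st, t, lr = learning_rate)
    opt <- upd$params; st <- upd$state
    front[names(front)] <- opt[names(front)]
    cp$params[names(cp$params)] <- opt[names(cp$params)]
    cp$bn_conv$gamma <- opt$bn_conv_gamma; cp$bn_conv$beta <- opt$bn_conv_beta
    cp$bn_fc$gamma <- opt$bn_fc_gamma; cp$bn_fc$beta <- opt$bn_fc_beta
    if (t %% check_every == 0L || t == max_steps) {
      te_loss <- bce_loss(full_cnn_fwd(front, cp, xb_te)$logit, y_te)
      tr_loss <- run_train / max(1L, run_n); run_train <- 0; run_n <- 0L
      trace_step <- c(trace_step, t); trace_train <- c(trace_train, tr_loss)
      trace_test <- c(trace_test, te_loss)
      if (te_loss < best$loss) {
        best <- list(loss = te_loss, front = front, cp = cp, step = t)
        streak <- 0L
      } else if (tr_loss <= prev_train + 1e-12) streak <- streak + 1L
      prev_train <- tr_loss
      if (streak >= patience) break
    }
  }
  probs <- as.numeric(full_cnn_fwd(best$front, best$cp, xb_te)$prob)
  m <- confusion_metrics(probs, y_te)
  m$model <- "cnn_no_reduction"
  list(metrics = m,
       predictions = tibble::tibble(row = te, probability = probs),
       trace = tibble::tibble(step = trace_step, train_loss = trace_train,
                              test_loss = trace_test),
       best_step = best$step)
}

#' Benchmark the AE + CNN against reference methods on shared splits
#'
#' Runs, over `n_splits` shared site-stratified splits: the AE + CNN, a
#' margin classifier and tree ensemble on PCA features, the same two on
#' flattened autoencoder latents, and the CNN without dimensionality
#' reduction. Every method sees the identical split in each repetition so
#' accuracies are comparable pairwise.
#'
#' @param cohort A [generate_cohort()] cohort.
#' @param ae_fit A trained [train_autoencoder()] fit (frozen across splits).
#' @param n_splits Number of shared splits (default 20).
#' @param test_ratio Held-out fraction per split.
#' @param cnn_args List of extra arguments for [train_classifier()].
#' @param full_cnn_args List of extra arguments for [cnn_no_reduction()];
#'   its default step budget is smaller than the latent CNN's because a
#'   full-dimensional update step costs roughly thirty times more — the
#'   budgets equalize wall-clock training effort across methods.
#' @param seed Integer seed; split seeds are derived from it.
#' @return A `benchmark_result`: tibble of per-split per-method metrics
#'   (`split_id`, `method`, `accuracy`, `precision`, `recall`, `auc`).
#' @export
run_benchmark <- function(cohort, ae_fit, n_splits = 20L, test_ratio = 0.2,
                          cnn_args = list(max_steps = 1000L),
                          full_cnn_args = list(max_steps = 300L,
                                               check_every = 100L,
                                               batch_size = 8L),
                          seed = 1L) {
  y <- normalize_labels(cohort$subjects$group)
  latents <- encode_batch(ae_fit$params, volumes_to_batch(cohort$volumes))
  flat <- t(apply(latents, 5L, as.vector))
  rows <- list()
  for (s in seq_len(n_splits)) {
    sp <- stratified_split(cohort$subjects, test_ratio, seed = seed * 1000L + s)
    y_te <- y[sp$test_ids]
    add <- function(method, probs) {
      m <- confusion_metrics(probs, y_te)
      m$auc <- roc_auc(probs, y_te)$auc
      m$method <- method; m$split_id <- s
      rows[[length(rows) + 1L]] <<- m
    }
    cnn <- do.call(train_classifier,
                   c(list(latents, y, sp, seed = seed * 1000L + s), cnn_args))
    add("ae_cnn", predict_probability(
      cnn, latents[, , , , sp$test_ids, drop = FALSE])$probability)

    pca <- pca_reduce(cohort$volumes, 0.90, train_ids = sp$train_ids)
    pf <- as.matrix(pca$features[-1])
    add("pca_svm", attr(fit_baseline(pf, y, sp, "margin_classifier"),
                        "predictions")$probability)
    add("pca_rf", attr(fit_baseline(pf, y, sp, "tree_ensemble"),
                       "predictions")$probability)
    add("ae_svm", attr(fit_baseline(flat, y, sp, "margin_classifier"),
                       "predictions")$probability)
    add("ae_rf", attr(fit_baseline(flat, y, sp, "tree_ensemble"),
                      "predictions")$probability)

    nr <- do.call(cnn_no_reduction,
                  c(list(cohort$volumes, y, sp, seed = seed * 1000L + s),
                    full_cnn_args))
    add("cnn_no_reduction", nr$predictions$probability)
  }
  out <- dplyr::bind_rows(rows)
  out <- dplyr::select(out, dplyr::all_of(c("split_id", "method", "accuracy",
                                            "precision", "recall", "auc")))
  class(out) <- c("benchmark_result", class(out))
  out
}
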