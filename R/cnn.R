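# A compact trainable 3D convolutional network, written against base R linear
# algebra. Convolutions use same-padding im2col + GEMM; each block is
# conv -> ReLU -> 2x2x2 max-pool; the head is flatten -> FC -> ReLU ->
# dropout -> FC -> softmax, with dropout also applied to the input during
# training. Backpropagation reaches the input, so gradient-times-input
# attribution is exact.

#' 3D CNN architecture specification
#'
#' The default architecture is three convolutional blocks with kernels
#' 5,3,3 and 8,16,32 filters, each followed by ReLU and 2x2x2 max-pooling,
#' then fully connected layers of width `fc_width` and `n_classes` with a
#' softmax output. Convolutions use same padding, so pooling alone halves the
#' spatial dimensions; the input must be divisible by `2^(number of blocks)`.
#'
#' @param input_shape Integer length-3 spatial dimensions.
#' @param conv_blocks List of `c(kernel, filters)` pairs.
#' @param fc_width Width of the penultimate fully connected layer.
#' @param n_classes Number of output classes.
#' @param dropout_keep Keep-probability for dropout at the input and before
#'   the final layer (training only).
#' @return An object of class `cnn_spec`.
#' @export
cnn_spec <- function(input_shape = c(24L, 24L, 24L),
                     conv_blocks = list(c(5L, 8L), c(3L, 16L), c(3L, 32L)),
                     fc_width = 1024L, n_classes = 2L, dropout_keep = 0.5) {
  input_shape <- as.integer(input_shape)
  nb <- length(conv_blocks)
  if (any(input_shape %% (2L^nb) != 0L))
    stop_format("input shape (%s) must be divisible by 2^%d for %d pooling stages",
                paste(input_shape, collapse = "x"), nb, nb)
  for (b in conv_blocks) {
    if (length(b) != 2L || b[1] %% 2L != 1L)
      stop_format("each conv block is c(odd_kernel, filters)")
  }
  if (dropout_keep <= 0 || dropout_keep > 1) stop_format("dropout_keep must be in (0,1]")
  structure(list(input_shape = input_shape, conv_blocks = conv_blocks,
                 fc_width = as.integer(fc_width), n_classes = as.integer(n_classes),
                 dropout_keep = dropout_keep),
            class = "cnn_spec")
}

#' Layer output shapes implied by a `cnn_spec`
#'
#' Pure shape arithmetic (no weight allocation): spatial size is preserved by
#' the same-padding convolutions and halved by each pooling stage.
#'
#' @param spec A [cnn_spec()].
#' @return Data frame with one row per layer (layer, spatial, channels,
#'   flat_length for the flatten row).
#' @export
model_shapes <- function(spec) {
  sp <- spec$input_shape
  rows <- list(data.frame(layer = "input", spatial = paste(sp, collapse = "x"),
                          channels = 1L))
  ch <- 1L
  for (i in seq_along(spec$conv_blocks)) {
    ch <- spec$conv_blocks[[i]][2]
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("conv%d (k=%d)", i, spec$conv_blocks[[i]][1]),
      spatial = paste(sp, collapse = "x"), channels = ch)
    sp <- sp %/% 2L
    rows[[length(rows) + 1L]] <- data.frame(
      layer = sprintf("pool%d", i), spatial = paste(sp, collapse = "x"),
      channels = ch)
  }
  flat <- prod(sp) * ch
  rows[[length(rows) + 1L]] <- data.frame(layer = "flatten",
                                          spatial = as.character(flat), channels = 1L)
  rows[[length(rows) + 1L]] <- data.frame(layer = "fc1",
                                          spatial = as.character(spec$fc_width), channels = 1L)
  rows[[length(rows) + 1L]] <- data.frame(layer = "softmax",
                                          spatial = as.character(spec$n_classes), channels = 1L)
  out <- do.call(rbind, rows)
  attr(out, "flat_length") <- flat
  out
}

# --- im2col / pooling index precomputation -----------------------------------

# Index tables for one same-padding conv layer on an (n1,n2,n3) grid with C_in
# channels: `gather` is (nvox x k^3*C_in) linear indices into the zero-padded
# (np1,np2,np3,C_in) array; `inner` maps the unpadded voxels of channel 1 into
# the padded array.
conv_indices <- function(shape, k, c_in) {
  p <- (k - 1L) %/% 2L
  np <- shape + 2L * p
  npvox <- prod(np)
  nvox <- prod(shape)
  ix <- seq_len(shape[1])
  iy <- seq_len(shape[2])
  iz <- seq_len(shape[3])
  # linear index into padded grid of voxel (x+p, y+p, z+p)
  base <- outer(outer(ix + p, (iy + p - 1L) * np[1], "+"),
                (iz + p - 1L) * np[1] * np[2], "+")
  base <- as.integer(base)
  offs <- as.matrix(expand.grid(a = -p:p, b = -p:p, c = -p:p))
  k3 <- nrow(offs)
  gather1 <- matrix(0L, nvox, k3)
  for (j in seq_len(k3)) {
    gather1[, j] <- base + offs[j, 1] + offs[j, 2] * np[1] +
      offs[j, 3] * np[1] * np[2]
  }
  gather <- matrix(0L, nvox, k3 * c_in)
  for (ch in seq_len(c_in)) {
    gather[, (ch - 1L) * k3 + seq_len(k3)] <- gather1 + (ch - 1L) * npvox
  }
  list(gather = gather, inner = base, np = np, npvox = npvox, k3 = k3,
       c_in = c_in, nvox = nvox, shape = shape)
}

# 2x2x2 max-pool index table: (nout x 8) rows into the pre-pool voxel grid.
pool_indices <- function(shape) {
  out <- shape %/% 2L
  nout <- prod(out)
  ox <- seq_len(out[1])
  oy <- seq_len(out[2])
  oz <- seq_len(out[3])
  child <- matrix(0L, nout, 8L)
  j <- 0L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    j <- j + 1L
    child[, j] <- as.integer(
      outer(outer(2L * ox - 1L + dx, (2L * oy - 2L + dy) * shape[1], "+"),
            (2L * oz - 2L + dz) * shape[1] * shape[2], "+"))
  }
  list(child = child, nout = nout, out_shape = out)
}

#' Build an untrained 3D CNN
#'
#' Weights use He initialization; biases start at zero. Index tables for the
#' im2col convolutions and pooling stages are precomputed for the spec's input
#' shape.
#'
#' @param spec A [cnn_spec()].
#' @param seed RNG seed for weight initialization.
#' @return An object of class `cnn_model`.
#' @export
build_model <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "cnn_spec"))
  shape <- spec$input_shape
  c_in <- 1L
  conv <- list()
  for (i in seq_along(spec$conv_blocks)) {
    k <- as.integer(spec$conv_blocks[[i]][1])
    c_out <- as.integer(spec$conv_blocks[[i]][2])
    ci <- conv_indices(shape, k, c_in)
    pi <- pool_indices(shape)
    conv[[i]] <- list(k = k, c_in = c_in, c_out = c_out, idx = ci, pool = pi)
    shape <- shape %/% 2L
    c_in <- c_out
  }
  flat <- prod(shape) * c_in
  params <- list()
  with_seed(seed, {
    for (i in seq_along(conv)) {
      fan_in <- conv[[i]]$idx$k3 * conv[[i]]$c_in
      params[[paste0("Wc", i)]] <- matrix(
        stats::rnorm(fan_in * conv[[i]]$c_out, sd = sqrt(2 / fan_in)),
        fan_in, conv[[i]]$c_out)
      params[[paste0("bc", i)]] <- numeric(conv[[i]]$c_out)
    }
    params$W1 <- matrix(stats::rnorm(flat * spec$fc_width, sd = sqrt(2 / flat)),
                        flat, spec$fc_width)
    params$b1 <- numeric(spec$fc_width)
    params$W2 <- matrix(stats::rnorm(spec$fc_width * spec$n_classes,
                                     sd = sqrt(2 / spec$fc_width)),
                        spec$fc_width, spec$n_classes)
    params$b2 <- numeric(spec$n_classes)
  })
  structure(list(spec = spec, conv = conv, params = params, flat = flat),
            class = "cnn_model")
}

# Forward pass for one volume (vector of length nvox). Returns logits and,
# when `keep_cache`, the intermediates needed for backprop. Dropout masks are
# drawn from the current RNG stream when `train = TRUE`.
cnn_forward <- function(model, x, train = FALSE, keep_cache = FALSE) {
  p <- model$params
  keep <- model$spec$dropout_keep
  cache <- list()
  a <- matrix(as.numeric(x), ncol = 1L)
  if (train && keep < 1) {
    m_in <- (stats::runif(length(a)) < keep) / keep
    a <- a * m_in
    cache$m_in <- m_in
  }
  for (i in seq_along(model$conv)) {
    L <- model$conv[[i]]
    xpad <- numeric(L$idx$npvox * L$c_in)
    for (ch in seq_len(L$c_in)) {
      xpad[L$idx$inner + (ch - 1L) * L$idx$npvox] <- a[, ch]
    }
    cols <- .gather_cols(xpad, L$idx$gather)
    pre <- cols %*% p[[paste0("Wc", i)]]
    pre <- pre + rep(p[[paste0("bc", i)]], each = L$idx$nvox)
    act <- pre
    act[act < 0] <- 0
    # max-pool with argmax bookkeeping
    ch1 <- act[L$pool$child[, 1L], , drop = FALSE]
    best <- ch1
    bestk <- matrix(1L, L$pool$nout, L$c_out)
    for (j in 2:8) {
      cand <- act[L$pool$child[, j], , drop = FALSE]
      upd <- cand > best
      best[upd] <- cand[upd]
      bestk[upd] <- j
    }
    if (keep_cache) cache[[paste0("conv", i)]] <- list(cols = cols, pre = pre,
                                                       bestk = bestk)
    a <- best
  }
  flat <- as.numeric(a)
  h1_pre <- as.numeric(crossprod(p$W1, flat)) + p$b1
  h1 <- pmax(h1_pre, 0)
  h1d <- h1
  if (train && keep < 1) {
    m_fc <- (stats::runif(length(h1)) < keep) / keep
    h1d <- h1 * m_fc
    cache$m_fc <- m_fc
  }
  logits <- as.numeric(crossprod(p$W2, h1d)) + p$b2
  if (keep_cache) {
    cache$flat <- flat
    cache$h1_pre <- h1_pre
    cache$h1d <- h1d
  }
  list(logits = logits, cache = cache)
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Backward pass from d(loss)/d(logits). Returns parameter gradients and
# (optionally) the gradient with respect to the input volume.
cnn_backward <- function(model, fwd, dlogits, want_input_grad = FALSE) {
  p <- model$params
  cache <- fwd$cache
  grads <- list()
  grads$W2 <- outer(cache$h1d, dlogits)
  grads$b2 <- dlogits
  dh1d <- as.numeric(p$W2 %*% dlogits)
  if (!is.null(cache$m_fc)) dh1d <- dh1d * cache$m_fc
  dh1 <- dh1d * (cache$h1_pre > 0)
  grads$W1 <- outer(cache$flat, dh1)
  grads$b1 <- dh1
  dflat <- as.numeric(p$W1 %*% dh1)
  nb <- length(model$conv)
  L <- model$conv[[nb]]
  da <- matrix(dflat, L$pool$nout, L$c_out)
  for (i in rev(seq_along(model$conv))) {
    L <- model$conv[[i]]
    cc <- cache[[paste0("conv", i)]]
    # un-pool: gradient to argmax child
    dact <- matrix(0, L$idx$nvox, L$c_out)
    nout <- L$pool$nout
    rows <- L$pool$child[cbind(rep.int(seq_len(nout), L$c_out), as.vector(cc$bestk))]
    dact[rows + rep((seq_len(L$c_out) - 1L) * L$idx$nvox, each = nout)] <- as.vector(da)
    dpre <- dact * (cc$pre > 0)
    grads[[paste0("Wc", i)]] <- crossprod(cc$cols, dpre)
    grads[[paste0("bc", i)]] <- colSums(dpre)
    if (i > 1L || want_input_grad) {
      dcols <- dpre %*% t(p[[paste0("Wc", i)]])
      dxpad <- .scatter_add(L$idx$npvox * L$c_in, L$idx$gather, dcols)
      da <- matrix(0, L$idx$nvox, L$c_in)
      for (ch in seq_len(L$c_in)) {
        da[, ch] <- dxpad[L$idx$inner + (ch - 1L) * L$idx$npvox]
      }
    }
  }
  if (want_input_grad) {
    dinput <- da[, 1L]
    if (!is.null(cache$m_in)) dinput <- dinput * cache$m_in
    grads$input <- dinput
  }
  grads
}

#' Training configuration
#'
#' Adadelta with learning-rate multiplier 0.05 and accumulator decay 0.95,
#' categorical cross-entropy loss, batch size 32, early stopping when the
#' validation loss fails to improve for `patience` consecutive epochs; the
#' epoch with the highest validation accuracy is checkpointed.
#'
#' @param lr Adadelta learning-rate multiplier.
#' @param rho Adadelta accumulator decay rate.
#' @param epsilon Adadelta numerical floor.
#' @param batch_size Minibatch size.
#' @param max_epochs Maximum number of epochs (desk-scale default 40).
#' @param patience Early-stopping patience in epochs.
#' @param seed RNG seed covering shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(lr = 0.05, rho = 0.95, epsilon = 1e-6,
                         batch_size = 32L, max_epochs = 40L, patience = 10L,
                         seed = 1L) {
  if (batch_size < 1L) stop_format("batch_size must be >= 1")
  if (patience < 1L) stop_format("patience must be >= 1")
  structure(list(lr = lr, rho = rho, epsilon = epsilon,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), seed = as.integer(seed)),
            class = "train_config")
}

adadelta_update <- function(params, grads, state, cfg) {
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(state$Eg2[[nm]])) {
      state$Eg2[[nm]] <- g * 0
      state$Edx2[[nm]] <- g * 0
    }
    state$Eg2[[nm]] <- cfg$rho * state$Eg2[[nm]] + (1 - cfg$rho) * g^2
    dx <- -sqrt(state$Edx2[[nm]] + cfg$epsilon) /
      sqrt(state$Eg2[[nm]] + cfg$epsilon) * g
    state$Edx2[[nm]] <- cfg$rho * state$Edx2[[nm]] + (1 - cfg$rho) * dx^2
    params[[nm]] <- params[[nm]] + cfg$lr * dx
  }
  list(params = params, state = state)
}

#' Train a 3D CNN classifier
#'
#' Minimizes categorical cross-entropy with Adadelta on the training split,
#' monitors the validation split each epoch, stops early after `patience`
#' non-improving epochs (validation loss), and returns the parameters of the
#' epoch with the highest validation accuracy. Deterministic for a fixed seed
#' under single-threaded BLAS.
#'
#' @param model A [build_model()] result.
#' @param dataset A [labeled_dataset()] with nonempty train and val splits.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch progress.
#' @param eval_override Internal testing hook: a function
#'   `(model, epoch) -> list(loss, acc)` replacing validation evaluation.
#' @return An object of class `cnn_classifier` with elements `model`
#'   (best-validation weights), `history` (per-epoch data frame), `best_epoch`.
#' @export
train_cnn <- function(model, dataset, cfg = train_config(), verbose = FALSE,
                      eval_override = NULL) {
  tr <- dataset_split(dataset, "train")
  va <- dataset_split(dataset, "val")
  if (length(tr$index) == 0L) stop_format("training split is empty")
  if (length(va$index) == 0L && is.null(eval_override))
    stop_format("validation split is empty")
  n <- length(tr$volumes)
  params <- model$params
  state <- list(Eg2 = list(), Edx2 = list())
  history <- data.frame()
  best <- list(acc = -Inf, loss = Inf, params = params, epoch = 0L)
  wait <- 0L
  best_loss <- Inf
  with_seed(cfg$seed, {
    for (epoch in seq_len(cfg$max_epochs)) {
      ord <- sample.int(n)
      tr_loss <- 0
      tr_correct <- 0L
      for (start in seq(1L, n, by = cfg$batch_size)) {
        bidx <- ord[start:min(start + cfg$batch_size - 1L, n)]
        gacc <- NULL
        bloss <- 0
        for (s in bidx) {
          model$params <- params
          fwd <- cnn_forward(model, tr$volumes[[s]], train = TRUE, keep_cache = TRUE)
          pr <- softmax(fwd$logits)
          y <- tr$classes[s] + 1L
          bloss <- bloss - log(max(pr[y], 1e-12))
          if (which.max(fwd$logits) == y) tr_correct <- tr_correct + 1L
          dlogits <- pr
          dlogits[y] <- dlogits[y] - 1
          g <- cnn_backward(model, fwd, dlogits)
          if (is.null(gacc)) gacc <- g
          else for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] + g[[nm]]
        }
        for (nm in names(gacc)) gacc[[nm]] <- gacc[[nm]] / length(bidx)
        upd <- adadelta_update(params, gacc, state, cfg)
        params <- upd$params
        state <- upd$state
        tr_loss <- tr_loss + bloss
      }
      tr_loss <- tr_loss / n
      model$params <- params
      if (is.null(eval_override)) {
        ev <- evaluate_cnn(model, va$volumes, va$classes)
      } else {
        ev <- eval_override(model, epoch)
      }
      history <- rbind(history, data.frame(
        epoch = epoch, train_loss = tr_loss, train_acc = tr_correct / n,
        val_loss = ev$loss, val_acc = ev$acc))
      if (verbose)
        message(sprintf("epoch %3d  train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                        epoch, tr_loss, tr_correct / n, ev$loss, ev$acc))
      if (ev$acc > best$acc || (ev$acc == best$acc && ev$loss < best$loss)) {
        best <- list(acc = ev$acc, loss = ev$loss, params = params, epoch = epoch)
      }
      if (ev$loss < best_loss - 1e-9) {
        best_loss <- ev$loss
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= cfg$patience) break
      }
    }
  })
  model$params <- best$params
  structure(list(model = model, history = history, best_epoch = best$epoch,
                 cfg = cfg),
            class = "cnn_classifier")
}

evaluate_cnn <- function(model, volumes, classes) {
  loss <- 0
  correct <- 0L
  for (i in seq_along(volumes)) {
    fwd <- cnn_forward(model, volumes[[i]], train = FALSE)
    pr <- softmax(fwd$logits)
    y <- classes[i] + 1L
    loss <- loss - log(max(pr[y], 1e-12))
    if (which.max(fwd$logits) == y) correct <- correct + 1L
  }
  list(loss = loss / length(volumes), acc = correct / length(volumes))
}

#' @export
print.cnn_classifier <- function(x, ...) {
  cat(sprintf("<cnn_classifier> input %s, %d conv blocks, trained %d epochs (best epoch %d, val acc %.3f)\n",
              paste(x$model$spec$input_shape, collapse = "x"),
              length(x$model$conv), nrow(x$history), x$best_epoch,
              max(x$history$val_acc)))
  invisible(x)
}

#' @export
summary.cnn_classifier <- function(object, ...) {
  print(object)
  print(utils::tail(object$history, 5L))
  invisible(object$history)
}

#' Predict class probabilities or labels
#'
#' @param object A trained `cnn_classifier`.
#' @param volumes List of 3D arrays (or a single array).
#' @param type `"prob"` for the softmax matrix, `"class"` for 0/1 labels.
#' @param ... Unused.
#' @return Matrix `n x n_classes` of probabilities, or integer labels.
#' @export
predict.cnn_classifier <- function(object, volumes, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.array(volumes) && !is.list(volumes)) volumes <- list(volumes)
  pr <- t(vapply(volumes, function(v) {
    softmax(cnn_forward(object$model, v, train = FALSE)$logits)
  }, numeric(object$model$spec$n_classes)))
  if (type == "prob") pr else as.integer(max.col(pr) - 1L)
}

#' Gradient of a class logit with respect to the input
#'
#' @param clf A trained classifier.
#' @param v Input volume.
#' @param target_class Class (0-based) whose logit is differentiated.
#' @return 3D array of the same shape as `v`.
#' @export
input_gradient <- function(clf, v, target_class = 1L) UseMethod("input_gradient")

#' @export
input_gradient.cnn_classifier <- function(clf, v, target_class = 1L) {
  fwd <- cnn_forward(clf$model, v, train = FALSE, keep_cache = TRUE)
  dlogits <- numeric(clf$model$spec$n_classes)
  dlogits[target_class + 1L] <- 1
  g <- cnn_backward(clf$model, fwd, dlogits, want_input_grad = TRUE)
  array(g$input, dim = dim(v))
}

# --- masked evaluation -------------------------------------------------------

#' Masked classification accuracy
#'
#' Multiplies every volume by the binary mask (voxels outside the mask set to
#' `fill`, default 0 — the least-informative constant for standardized data),
#' predicts with the classifier, and reports the confusion counts and the
#' accuracy `f1 = (TP + TN) / (TP + TN + FP + FN)` with class 1 as positive.
#'
#' @param clf A classifier with a `predict` method (`cnn_classifier` or
#'   [template_classifier()]).
#' @param volumes List of 3D arrays.
#' @param classes Integer labels 0/1.
#' @param mask A [build_mask()] result or 0/1 array matching the volume shape.
#' @param fill Fill value outside the mask.
#' @return List with `counts` (TP, FP, TN, FN) and `f1`.
#' @export
masked_accuracy <- function(clf, volumes, classes, mask, fill = 0) {
  mk <- if (inherits(mask, "brain_mask")) mask$mask else mask
  masked <- lapply(volumes, function(v) apply_mask(v, mk, fill))
  pred <- predict(clf, masked, type = "class")
  confusion(pred, classes)
}

confusion <- function(pred, truth) {
  counts <- c(TP = sum(pred == 1L & truth == 1L),
              FP = sum(pred == 1L & truth == 0L),
              TN = sum(pred == 0L & truth == 0L),
              FN = sum(pred == 0L & truth == 1L))
  list(counts = counts, f1 = (counts[["TP"]] + counts[["TN"]]) / sum(counts))
}

# --- template (matched-filter) surrogate classifier --------------------------

#' Linear template classifier
#'
#' A deterministic surrogate for the CNN in unit tests and fast experiments:
#' the score of a volume is `<w, v> + b` with `w` the voxelwise class-mean
#' difference over the training split (optionally restricted to `voxel_set`,
#' recovering a thresholded voxel-set mean) and `b` placing the boundary at
#' the midpoint of the class score means. Being linear, it has an exact
#' input gradient and works with every attribution backend.
#'
#' @param dataset A [labeled_dataset()]; the template is fitted on its train
#'   split.
#' @param voxel_set Optional logical/0-1 array restricting the template
#'   support.
#' @return An object of class `template_classifier` with elements `w`, `b`.
#' @export
template_classifier <- function(dataset, voxel_set = NULL) {
  tr <- dataset_split(dataset, "train")
  if (length(tr$index) == 0L) stop_format("training split is empty")
  i1 <- tr$classes == 1L
  mu1 <- Reduce(`+`, tr$volumes[i1]) / sum(i1)
  mu0 <- Reduce(`+`, tr$volumes[!i1]) / sum(!i1)
  w <- mu1 - mu0
  if (!is.null(voxel_set)) {
    keep <- as_binary3d(voxel_set)
    w[!keep] <- 0
  }
  s1 <- mean(vapply(tr$volumes[i1], function(v) sum(w * v), numeric(1)))
  s0 <- mean(vapply(tr$volumes[!i1], function(v) sum(w * v), numeric(1)))
  structure(list(w = w, b = -(s1 + s0) / 2, shape = dim(w)),
            class = "template_classifier")
}

#' @export
print.template_classifier <- function(x, ...) {
  cat(sprintf("<template_classifier> %s grid, %d nonzero template voxels\n",
              paste(x$shape, collapse = "x"), sum(x$w != 0)))
  invisible(x)
}

#' @export
predict.template_classifier <- function(object, volumes,
                                        type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.array(volumes) && !is.list(volumes)) volumes <- list(volumes)
  score <- vapply(volumes, function(v) sum(object$w * v) + object$b, numeric(1))
  if (type == "class") return(as.integer(score > 0))
  p1 <- 1 / (1 + exp(-score))
  cbind(`0` = 1 - p1, `1` = p1)
}

#' @export
input_gradient.template_classifier <- function(clf, v, target_class = 1L) {
  sgn <- if (target_class == 1L) 1 else -1
  array(sgn * clf$w, dim = dim(clf$w))
}

# Scalar margin output used as the model function for Shapley backends.
classifier_margin_fn <- function(clf, target_class = 1L) {
  if (inherits(clf, "template_classifier")) {
    sgn <- if (target_class == 1L) 1 else -1
    function(v) sgn * (sum(clf$w * v) + clf$b)
  } else {
    function(v) {
      lg <- cnn_forward(clf$model, v, train = FALSE)$logits
      lg[target_class + 1L] - max(lg[-(target_class + 1L)])
    }
  }
}
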