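# Convolutional network for 40x40 heart sound spectrograms:
# conv(5x5, 8) -> ReLU -> maxpool(2x2) -> conv(5x5, 16) -> ReLU ->
# maxpool(2x2) -> dense(ReLU) -> readout(5) with softmax cross-entropy,
# trained by Adam. Implemented directly on BLAS matrix products via
# im2col so the whole network runs efficiently in base R: a batch of
# images is kept as a (pixels x batch) matrix and every convolution is a
# single matrix multiplication of gathered patches.

#' Classifier configuration
#'
#' Fixed architectural facts: two 5x5 convolution/max-pool blocks with 8
#' and 16 kernels, a dense layer, and a 5-node softmax readout; Adam at
#' learning rate 0.001.
#'
#' @param dense_units Width of the fully connected layer.
#' @param learning_rate Adam step size.
#' @param batch_size Minibatch size.
#' @param epochs Maximum training epochs.
#' @param early_stop Stop once training accuracy has held at 100% for
#'   three consecutive epochs (the loss surface is then flat for the
#'   purposes of classification); set `FALSE` to always run all epochs.
#' @param seed RNG seed for initialization and batch shuffling.
#' @return List of class `classifier_config`.
#' @export
classifier_config <- function(dense_units = 128, learning_rate = 0.001,
                              batch_size = 32, epochs = 30,
                              early_stop = TRUE, seed = 1L) {
  if (learning_rate < 0) abort_config("learning_rate must be >= 0",
                                      "learning_rate")
  if (dense_units < 1 || batch_size < 1 || epochs < 0) {
    abort_config("dense_units and batch_size must be >= 1, epochs >= 0")
  }
  structure(list(input_side = 40L, kernel = 5L,
                 kernels_block1 = 8L, kernels_block2 = 16L,
                 n_classes = 5L, dense_units = as.integer(dense_units),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs),
                 early_stop = isTRUE(early_stop),
                 seed = as.integer(seed)),
            class = "classifier_config")
}

# patch-gather index for a valid 5x5 convolution over a square grid
conv_index <- function(side, k) {
  out <- side - k + 1L
  oi <- rep(seq_len(out), times = out)        # row (time) index
  oj <- rep(seq_len(out), each = out)
  idx <- matrix(0L, out * out, k * k)
  for (dj in seq_len(k)) for (di in seq_len(k)) {
    idx[, di + (dj - 1L) * k] <- (oi + di - 1L) + (oj + dj - 2L) * side
  }
  idx
}

# 2x2/stride-2 max pool: four source indices per output cell
pool_index <- function(side) {
  out <- side %/% 2L
  oi <- rep(seq_len(out), times = out)
  oj <- rep(seq_len(out), each = out)
  cbind((2L * oi - 1L) + (2L * oj - 2L) * side,
        (2L * oi) + (2L * oj - 2L) * side,
        (2L * oi - 1L) + (2L * oj - 1L) * side,
        (2L * oi) + (2L * oj - 1L) * side)
}

# expand a per-image index column set to a whole batch (rows grouped by
# image, position varying fastest)
batch_index <- function(idx, B, stride) {
  offs <- (seq_len(B) - 1L) * stride
  m <- nrow(idx)
  out <- matrix(0L, m * B, ncol(idx))
  for (c in seq_len(ncol(idx))) out[, c] <- outer(idx[, c], offs, "+")
  out
}

cnn_geometry <- function(cfg) {
  s1 <- cfg$input_side - cfg$kernel + 1L       # 36
  p1 <- s1 %/% 2L                              # 18
  s2 <- p1 - cfg$kernel + 1L                   # 14
  p2 <- s2 %/% 2L                              # 7
  list(conv1 = conv_index(cfg$input_side, cfg$kernel),
       pool1 = pool_index(s1),
       conv2 = conv_index(p1, cfg$kernel),
       pool2 = pool_index(s2),
       s1 = s1, p1 = p1, s2 = s2, p2 = p2,
       flat = p2 * p2 * cfg$kernels_block2)
}

#' Build (initialize) the CNN
#'
#' He-initialized weights, deterministic given `config$seed`; the forward
#' pass maps a 40x40 input to 5 logits.
#'
#' @param config A [classifier_config()].
#' @return List of class `pcg_cnn` holding parameters and geometry.
#' @export
build_model <- function(config = classifier_config()) {
  if (!inherits(config, "classifier_config")) {
    abort_config("config must be a classifier_config")
  }
  g <- cnn_geometry(config)
  k2 <- config$kernel^2
  set.seed(config$seed)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, 0, sqrt(2 / nr)),
                                nr, nc)
  params <- list(
    W1 = he(k2, config$kernels_block1), b1 = numeric(config$kernels_block1),
    W2 = he(k2 * config$kernels_block1, config$kernels_block2),
    b2 = numeric(config$kernels_block2),
    W3 = he(g$flat, config$dense_units), b3 = numeric(config$dense_units),
    W4 = he(config$dense_units, config$n_classes),
    b4 = numeric(config$n_classes)
  )
  structure(list(params = params, config = config, geom = g,
                 idx_cache = new.env(parent = emptyenv()),
                 trained = FALSE),
            class = "pcg_cnn")
}

# All gather/scatter index sets for one batch size are precomputed as
# flat linear indices, so every convolution patch extraction and pooling
# step is a single vector subset plus a dim() re-interpretation.
batch_indices_for <- function(model, B) {
  key <- as.character(B)
  cache <- model$idx_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  g <- model$geom
  nk1 <- model$config$kernels_block1
  nk2 <- model$config$kernels_block2

  pool_lin <- function(pidx, B, in_side2, F) {
    bp <- batch_index(pidx, B, in_side2)          # (B*out) x 4 row indices
    nr <- nrow(bp); in_rows <- B * in_side2
    colofs <- rep.int((0:(F - 1)) * in_rows, rep.int(nr, F))
    lin <- lapply(1:4, function(k) as.integer(bp[, k] + colofs))
    list(bp = bp, lin = lin, colofs = as.integer(colofs),
         in_rows = in_rows, F = F, nr = nr)
  }

  conv2_bp <- batch_index(g$conv2, B, g$p1^2)     # (B*196) x 25 rows
  conv2v <- as.integer(conv2_bp)                  # grouping for rowsum
  nprow <- length(conv2v)                         # B*196*25
  conv2lin <- as.integer(conv2v +
    rep.int((0:(nk1 - 1)) * (B * g$p1^2), rep.int(nprow, nk1)))

  bi <- list(
    conv1v = as.integer(batch_index(g$conv1, B, model$config$input_side^2)),
    conv1_nr = B * nrow(g$conv1),
    pool1 = pool_lin(g$pool1, B, g$s1^2, nk1),
    conv2v = conv2v,
    conv2lin = conv2lin,
    conv2_nr = B * nrow(g$conv2),
    pool2 = pool_lin(g$pool2, B, g$s2^2, nk2)
  )
  cache[[key]] <- bi
  bi
}

maxpool_fwd <- function(A, pl) {
  Y <- A[pl$lin[[1]]]
  amax <- rep.int(1L, length(Y))
  for (k in 2:4) {
    Yk <- A[pl$lin[[k]]]
    m <- Yk > Y
    Y[m] <- Yk[m]
    amax[m] <- k
  }
  dim(Y) <- c(pl$nr, pl$F)
  list(Y = Y, amax = amax)
}

maxpool_bwd <- function(dY, amax, pl) {
  # each input cell feeds exactly one pooled cell, so scatter is a plain
  # assignment at the argmax positions
  sel <- (amax - 1L) * pl$nr + seq_len(pl$nr)     # recycles over columns
  bpv <- as.integer(pl$bp)
  dest <- bpv[sel] + pl$colofs
  dA <- numeric(pl$in_rows * pl$F)
  dA[dest] <- dY
  dim(dA) <- c(pl$in_rows, pl$F)
  dA
}

add_bias <- function(Z, b) Z + rep(b, each = nrow(Z))

# X: (1600 x B) matrix of flattened 40x40 images (column-major pixels)
cnn_forward <- function(model, X, keep = FALSE) {
  p <- model$params; g <- model$geom
  B <- ncol(X)
  bi <- batch_indices_for(model, B)
  k2 <- model$config$kernel^2

  P1 <- X[bi$conv1v]
  dim(P1) <- c(bi$conv1_nr, k2)
  Z1 <- add_bias(P1 %*% p$W1, p$b1)
  A1 <- Z1 * (Z1 > 0)
  pl1 <- maxpool_fwd(A1, bi$pool1)

  P2 <- pl1$Y[bi$conv2lin]
  dim(P2) <- c(bi$conv2_nr, k2 * model$config$kernels_block1)
  Z2 <- add_bias(P2 %*% p$W2, p$b2)
  A2 <- Z2 * (Z2 > 0)
  pl2 <- maxpool_fwd(A2, bi$pool2)

  X3 <- matrix(aperm(array(pl2$Y, c(g$p2^2, B, model$config$kernels_block2)),
                     c(2, 1, 3)), B, g$flat)
  Z3 <- add_bias(X3 %*% p$W3, p$b3)
  A3 <- Z3 * (Z3 > 0)
  Z4 <- add_bias(A3 %*% p$W4, p$b4)

  m <- Z4[, 1]
  for (j in 2:ncol(Z4)) m <- pmax(m, Z4[, j])
  E <- exp(Z4 - m)
  P <- E / rowSums(E)

  if (!keep) return(P)
  list(P = P, X = X, P1 = P1, Z1 = Z1, pl1 = pl1, P2 = P2, Z2 = Z2,
       pl2 = pl2, X3 = X3, Z3 = Z3, A3 = A3, bi = bi, B = B)
}

cnn_backward <- function(model, fw, y_onehot) {
  p <- model$params; g <- model$geom
  B <- fw$B; bi <- fw$bi
  nk1 <- model$config$kernels_block1
  nk2 <- model$config$kernels_block2

  dZ4 <- (fw$P - y_onehot) / B
  gW4 <- crossprod(fw$A3, dZ4); gb4 <- colSums(dZ4)
  dA3 <- tcrossprod(dZ4, p$W4)
  dZ3 <- dA3 * (fw$Z3 > 0)
  gW3 <- crossprod(fw$X3, dZ3); gb3 <- colSums(dZ3)
  dX3 <- tcrossprod(dZ3, p$W3)

  dP2pool <- matrix(aperm(array(dX3, c(B, g$p2^2, nk2)), c(2, 1, 3)),
                    B * g$p2^2, nk2)
  dA2 <- maxpool_bwd(dP2pool, fw$pl2$amax, bi$pool2)
  dZ2 <- dA2 * (fw$Z2 > 0)
  gW2 <- crossprod(fw$P2, dZ2); gb2 <- colSums(dZ2)
  dP2 <- tcrossprod(dZ2, p$W2)

  # scatter-add patch gradients back onto the pooled block-1 activations;
  # every 18x18 cell is covered by some patch, so the rowsum groups are
  # exactly 1..(B*324) in order
  dim(dP2) <- c(length(bi$conv2v), nk1)
  dPl1 <- rowsum(dP2, bi$conv2v)

  dA1 <- maxpool_bwd(dPl1, fw$pl1$amax, bi$pool1)
  dZ1 <- dA1 * (fw$Z1 > 0)
  gW1 <- crossprod(fw$P1, dZ1); gb1 <- colSums(dZ1)

  list(W1 = gW1, b1 = gb1, W2 = gW2, b2 = gb2,
       W3 = gW3, b3 = gb3, W4 = gW4, b4 = gb4)
}

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / (1 - beta1^state$t)
    vhat <- state$v[[nm]] / (1 - beta2^state$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

# features: list of spectrogram_feature (or 40x40 matrices) -> 1600 x N
features_to_matrix <- function(features, side = 40L) {
  if (inherits(features, "spectrogram_feature") || is.matrix(features)) {
    features <- list(features)
  }
  cols <- lapply(features, function(f) {
    M <- if (inherits(f, "spectrogram_feature")) f$matrix else f
    if (!is.matrix(M) || any(dim(M) != side)) {
      abort_data(sprintf("feature must be a %dx%d matrix", side, side),
                 "pcgdx_feature_error")
    }
    as.vector(M)
  })
  do.call(cbind, cols)
}

#' Train the CNN with Adam and softmax cross-entropy
#'
#' Minibatch gradient descent with the Adam optimizer; batches are
#' reshuffled every epoch with the seeded RNG, so training is fully
#' reproducible given `(data, config)`.
#'
#' @param model A `pcg_cnn` from [build_model()].
#' @param features List of `spectrogram_feature`s (or a pre-built
#'   `1600 x N` matrix).
#' @param labels Character vector of [PCG_CLASSES] (or integers 1..5),
#'   one per feature.
#' @param config Optional [classifier_config()] overriding the model's.
#' @return The trained `pcg_cnn`, with a `log` data frame
#'   (`epoch`, `loss`, `accuracy`) attached.
#' @export
train_cnn <- function(model, features, labels, config = NULL) {
  cfg <- if (is.null(config)) model$config else config
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  y <- if (is.character(labels) || is.factor(labels)) {
    match(as.character(labels), PCG_CLASSES)
  } else as.integer(labels)
  if (any(is.na(y)) || any(y < 1 | y > cfg$n_classes)) {
    abort_config("labels must be valid classes", "labels")
  }
  if (length(y) != ncol(X)) {
    abort_data("features and labels differ in length")
  }
  if (length(unique(y)) < 2) {
    abort_config("need at least 2 classes to train", "labels")
  }
  N <- ncol(X)
  Y <- matrix(0, N, cfg$n_classes); Y[cbind(seq_len(N), y)] <- 1

  state <- adam_init(model$params)
  log <- data.frame(epoch = integer(), loss = numeric(),
                    accuracy = numeric())
  set.seed(cfg$seed + 1L)
  for (ep in seq_len(cfg$epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; ep_hits <- 0
    for (b0 in seq(1, N, by = cfg$batch_size)) {
      sel <- ord[b0:min(b0 + cfg$batch_size - 1, N)]
      fw <- cnn_forward(model, X[, sel, drop = FALSE], keep = TRUE)
      probs <- fw$P
      ep_loss <- ep_loss - sum(log(pmax(
        probs[cbind(seq_along(sel), y[sel])], 1e-12)))
      ep_hits <- ep_hits + sum(max.col(probs) == y[sel])
      gr <- cnn_backward(model, fw, Y[sel, , drop = FALSE])
      upd <- adam_step(model$params, gr, state, cfg$learning_rate)
      model$params <- upd$params; state <- upd$state
    }
    log <- rbind(log, data.frame(epoch = ep, loss = ep_loss / N,
                                 accuracy = ep_hits / N))
    if (isTRUE(cfg$early_stop) && nrow(log) >= 3 &&
        all(utils::tail(log$accuracy, 3) == 1)) break
  }
  model$trained <- TRUE
  model$log <- log
  model
}

#' Class probabilities for one cycle feature
#'
#' @param model A `pcg_cnn`.
#' @param feature A `spectrogram_feature` or bare 40x40 matrix.
#' @return Named numeric vector of 5 probabilities (sums to 1).
#' @export
predict_cycle <- function(model, feature) {
  X <- features_to_matrix(feature)
  P <- cnn_forward(model, X)
  stats::setNames(as.numeric(P[1, ]), PCG_CLASSES)
}

#' Class probabilities for a batch of features
#'
#' @param model A `pcg_cnn`.
#' @param features List of features or a `1600 x N` matrix.
#' @return `N x 5` matrix of probabilities, columns named by class.
#' @export
predict_proba <- function(model, features) {
  X <- if (is.matrix(features)) features else features_to_matrix(features)
  P <- cnn_forward(model, X)
  colnames(P) <- PCG_CLASSES
  P
}

#' Diagnose a whole recording from its per-cycle features
#'
#' The recording-level probability vector is the arithmetic mean of the
#' per-cycle probability vectors; the diagnosis is its argmax. When the
#' true class is supplied, the diagnosis counts as correct iff the
#' aggregated probability of the true class is at least 50%.
#'
#' @param model A trained `pcg_cnn`.
#' @param features Non-empty list of cycle features.
#' @param truth Optional true class (one of [PCG_CLASSES]).
#' @return List of class `recording_diagnosis`: `per_cycle` (matrix),
#'   `aggregate`, `predicted_class`, `correct_given_truth`.
#' @export
diagnose_recording <- function(model, features, truth = NULL) {
  if (is.list(features) && !length(features)) {
    abort_data("no features to diagnose")
  }
  P <- predict_proba(model, features)
  agg <- colMeans(P)
  pred <- PCG_CLASSES[which.max(agg)]
  correct <- if (!is.null(truth)) {
    truth <- match.arg(truth, PCG_CLASSES)
    unname(agg[truth] >= 0.5)
  } else NA
  structure(list(per_cycle = P, aggregate = agg, predicted_class = pred,
                 correct_given_truth = correct),
            class = "recording_diagnosis")
}

#' @export
print.recording_diagnosis <- function(x, ...) {
  cat("<recording_diagnosis>", x$predicted_class, "\n")
  print(round(x$aggregate, 3))
  invisible(x)
}

#' Save / load a trained model
#'
#' The checkpoint is a plain serialized list (parameters + config); the
#' index caches are rebuilt on load.
#'
#' @param model A `pcg_cnn`.
#' @param path File path.
#' @return `load_model` returns the restored `pcg_cnn`.
#' @export
save_model <- function(model, path) {
  saveRDS(list(params = model$params, config = model$config,
               trained = model$trained,
               log = model$log), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  m <- build_model(obj$config)
  m$params <- obj$params
  m$trained <- obj$trained
  m$log <- obj$log
  m
}
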