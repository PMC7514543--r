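# Shallow convolutional classifier with full-height 1D kernels.
#
# Architecture: the Nv x Nt input image is correlated (stride 1, no
# padding) with NF kernels of size Nv x kernel_time_width, so each kernel
# slides along time only and emits a 1D feature map of length
# Nt - kernel_time_width + 1. ReLU, then non-overlapping max-pooling by
# `pool_factor` (remainder discarded), then a fully connected softmax layer
# over the two classes. Training is plain mini-batch gradient descent on
# softmax cross-entropy with seeded initialisation and batch shuffling.
# At the default sizes the dimension chain is
# 93 x 32 -> 30 maps x 30 -> 30 x 3 -> 90 features -> 2 logits.

#' CNN hyperparameter configuration
#'
#' @param n_kernels Number of convolution kernels NF.
#' @param kernel_time_width Kernel width along the time axis (columns); the
#'   kernel height is bound to the input image height at build time.
#' @param pool_factor Max-pooling subsampling factor (no zero padding; a
#'   trailing remainder shorter than the factor is discarded).
#' @param stride Convolution stride (only 1 is supported, as used here).
#' @param batch_size Mini-batch size.
#' @param epochs Training epochs.
#' @param learning_rate Gradient-descent step size.
#' @param seed Seed for weight initialisation and batch shuffling.
#' @param n_classes Number of output classes (2).
#' @return Object of class `cnn_config`.
#' @export
cnn_config <- function(n_kernels = 30L, kernel_time_width = 3L,
                       pool_factor = 10L, stride = 1L, batch_size = 50L,
                       epochs = 300L, learning_rate = 0.01, seed = 1L,
                       n_classes = 2L) {
  if (stride != 1L) stop_input("only stride 1 is supported")
  if (n_classes != 2L) stop_input("this classifier is two-class")
  cfg <- list(n_kernels = as.integer(n_kernels),
              kernel_time_width = as.integer(kernel_time_width),
              pool_factor = as.integer(pool_factor), stride = 1L,
              batch_size = as.integer(batch_size),
              epochs = as.integer(epochs),
              learning_rate = learning_rate, seed = as.integer(seed),
              n_classes = 2L)
  if (any(vapply(cfg[c(1, 2, 3, 5, 6)], function(v) v < 1L, TRUE)))
    stop_input("n_kernels, kernel_time_width, pool_factor, batch_size, epochs must be >= 1")
  structure(cfg, class = "cnn_config")
}

## Zero-mean uniform initialisation scaled by fan-in. Assumes the caller
## controls the RNG stream.
init_weights <- function(config, input_dim) {
  nv <- input_dim[1L]; nt <- input_dim[2L]
  kw <- config$kernel_time_width
  if (nt < kw) stop_input("image has %d columns, narrower than the kernel (%d)", nt, kw)
  L <- nt - kw + 1L
  P <- L %/% config$pool_factor
  if (P < 1L) stop_input("feature maps (%d) shorter than pool_factor (%d)",
                         L, config$pool_factor)
  nf <- config$n_kernels
  a1 <- sqrt(1 / (nv * kw))
  a2 <- sqrt(1 / (nf * P))
  structure(
    list(conv_w = matrix(stats::runif(nv * kw * nf, -a1, a1), nv * kw, nf),
         conv_b = numeric(nf),
         fc_w = matrix(stats::runif(nf * P * 2L, -a2, a2), nf * P, 2L),
         fc_b = numeric(2L),
         config = config, input_dim = input_dim,
         conv_len = L, pooled_len = P,
         classes = c("left", "right"), loss_history = numeric(0)),
    class = "cnn_model")
}

#' Initialise an untrained CNN model
#'
#' Weights are drawn from a zero-mean uniform distribution scaled by
#' fan-in, from the seed in `config`; biases start at zero.
#'
#' @param config A [cnn_config()].
#' @param input_dim `c(Nv, Nt)` of the input images.
#' @return Object of class `cnn_model` with fields `conv_w`
#'   (`(Nv * kernel_time_width) x NF`, one flattened kernel per column),
#'   `conv_b`, `fc_w`, `fc_b`, `config`, `conv_len`, `pooled_len`.
#' @export
cnn_init <- function(config = cnn_config(), input_dim) {
  with_seed(config$seed, init_weights(config, input_dim))
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf(paste0("<cnn_model: %d x %d input -> %d maps x %d -> x %d ",
                     "-> %d features -> 2 classes%s>\n"),
              x$input_dim[1], x$input_dim[2], x$config$n_kernels, x$conv_len,
              x$pooled_len, x$config$n_kernels * x$pooled_len,
              if (length(x$loss_history))
                sprintf(", trained %d epochs", length(x$loss_history)) else ""))
  invisible(x)
}

image_values <- function(img) {
  if (inherits(img, "mi_image")) img$values else as.matrix(img)
}

## Patch matrix: column i holds the flattened Nv x kw patch starting at
## time column i, so convolution becomes one crossprod.
im2col <- function(values, kw) {
  nv <- nrow(values); nt <- ncol(values)
  L <- nt - kw + 1L
  out <- matrix(0, nv * kw, L)
  for (j in seq_len(kw))
    out[((j - 1L) * nv + 1L):(j * nv), ] <- values[, j:(j + L - 1L)]
  out
}

#' Rectified linear unit
#'
#' @param a Numeric vector, matrix or array.
#' @return `max(a, 0)` elementwise.
#' @export
relu <- function(a) pmax(a, 0)

#' Convolutional layer forward pass
#'
#' Valid (no padding) correlation of the image with each kernel along time
#' at stride 1, bias added, ReLU applied.
#'
#' @param img An `mi_image` or numeric matrix whose height equals the
#'   model's kernel height.
#' @param model A `cnn_model`.
#' @return `NF x (Nt - kernel_time_width + 1)` matrix of post-ReLU feature
#'   maps.
#' @export
conv_forward <- function(img, model) {
  v <- image_values(img)
  if (nrow(v) != model$input_dim[1L])
    stop_input("image height %d does not match kernel height %d",
               nrow(v), model$input_dim[1L])
  Z <- im2col(v, model$config$kernel_time_width)
  relu(crossprod(model$conv_w, Z) + model$conv_b)
}

#' Non-overlapping max-pooling along time
#'
#' @param maps `NF x L` matrix of feature maps.
#' @param pool_factor Window length; windows do not overlap and a trailing
#'   remainder shorter than the window is discarded (no zero padding).
#' @return `NF x floor(L / pool_factor)` matrix of window maxima.
#' @export
maxpool <- function(maps, pool_factor) {
  maps <- as.matrix(maps)
  L <- ncol(maps)
  if (L < pool_factor)
    stop_input("map length %d shorter than pool_factor %d", L, pool_factor)
  P <- L %/% pool_factor
  arr <- array(maps[, seq_len(P * pool_factor), drop = FALSE],
               c(nrow(maps), pool_factor, P))
  apply(arr, c(1L, 3L), max)
}

## Batched pooling with argmax bookkeeping for backprop.
## H: NF x (L * B) post-ReLU maps for B images. Returns features
## ((NF * P) x B) and the linear indices of each pooled maximum in H.
pool_batch <- function(H, L, B, pf) {
  NF <- nrow(H)
  P <- L %/% pf
  keep <- as.vector(outer(seq_len(P * pf), (seq_len(B) - 1L) * L, `+`))
  arr <- array(H[, keep, drop = FALSE], c(NF, pf, P, B))
  m <- matrix(aperm(arr, c(2L, 1L, 3L, 4L)), nrow = pf)  # pf x (NF*P*B)
  amax <- max.col(t(m), ties.method = "first")
  vals <- m[cbind(amax, seq_along(amax))]
  q <- seq_along(amax) - 1L
  i <- q %% NF + 1L
  r <- q %/% NF
  k <- r %% P + 1L
  b <- r %/% P + 1L
  cols <- (b - 1L) * L + (k - 1L) * pf + amax
  list(feats = matrix(vals, NF * P, B),
       lin = (cols - 1L) * NF + i, P = P)
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2L, apply(logits, 2L, max))
  e <- exp(z)
  sweep(e, 2L, colSums(e), `/`)
}

## Loss and analytic gradients for one mini-batch.
## Zcat: (Nv*kw) x (L*B) patch matrix; y: integer class labels (1/2).
cnn_loss_grad <- function(model, Zcat, y) {
  NF <- model$config$n_kernels
  L <- model$conv_len
  pf <- model$config$pool_factor
  B <- length(y)
  A <- crossprod(model$conv_w, Zcat) + model$conv_b
  H <- relu(A)
  pool <- pool_batch(H, L, B, pf)
  logits <- crossprod(model$fc_w, pool$feats) + model$fc_b
  prob <- softmax_cols(logits)
  picked <- prob[cbind(y, seq_len(B))]
  loss <- -mean(log(pmax(picked, 1e-300)))
  dlog <- prob
  dlog[cbind(y, seq_len(B))] <- dlog[cbind(y, seq_len(B))] - 1
  dlog <- dlog / B
  g_fc_w <- pool$feats %*% t(dlog)
  g_fc_b <- rowSums(dlog)
  dfeat <- model$fc_w %*% dlog
  dH <- matrix(0, NF, L * B)
  dH[pool$lin] <- as.vector(dfeat)
  dA <- dH * (A > 0)
  g_conv_w <- Zcat %*% t(dA)
  g_conv_b <- rowSums(dA)
  list(loss = loss,
       grads = list(conv_w = g_conv_w, conv_b = g_conv_b,
                    fc_w = g_fc_w, fc_b = g_fc_b))
}

labels_to_y <- function(labels, classes) {
  y <- match(labels, classes)
  if (anyNA(y)) stop_input("labels outside classes (%s)",
                           paste(classes, collapse = ", "))
  y
}

#' Full forward pass for one image
#'
#' Convolution + ReLU, max-pooling, flattening, fully connected layer and
#' softmax.
#'
#' @inheritParams conv_forward
#' @return Named probability vector over the two classes (sums to 1).
#' @export
cnn_forward <- function(img, model) {
  maps <- conv_forward(img, model)
  pooled <- maxpool(maps, model$config$pool_factor)
  feat <- as.vector(pooled)
  logits <- as.vector(crossprod(model$fc_w, feat)) + model$fc_b
  p <- exp(logits - max(logits))
  p <- p / sum(p)
  names(p) <- model$classes
  p
}

#' Train the CNN by mini-batch gradient descent
#'
#' Softmax cross-entropy loss, plain gradient descent, seeded weight
#' initialisation and per-epoch batch shuffling. Identical inputs and seed
#' give identical models and loss histories.
#'
#' @param images List of `mi_image` (or plain matrices) of equal size.
#' @param labels Class labels, one per image; taken from the images'
#'   `label` fields when omitted. Both classes must be present.
#' @param config A [cnn_config()].
#' @return A trained `cnn_model` with `loss_history` of length
#'   `config$epochs` (mean batch loss per epoch, computed before each
#'   update).
#' @export
cnn_train <- function(images, labels = NULL, config = cnn_config()) {
  if (length(images) < 2L) stop_input("need at least 2 training images")
  if (is.null(labels))
    labels <- vapply(images, function(im) im$label %||% NA_character_, "")
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) != 2L)
    stop_input("training set must contain exactly 2 classes, got: %s",
               paste(classes, collapse = ", "))
  vals <- lapply(images, image_values)
  dims <- vapply(vals, dim, integer(2L))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop_input("all images must share the same dimensions")
  input_dim <- dims[, 1L]
  n <- length(images)
  y_all <- labels_to_y(labels, classes)
  kw <- config$kernel_time_width
  with_seed(config$seed, {
    model <- init_weights(config, input_dim)
    model$classes <- classes
    L <- model$conv_len
    Zall <- do.call(cbind, lapply(vals, im2col, kw = kw))
    lr <- config$learning_rate
    loss_history <- numeric(config$epochs)
    for (ep in seq_len(config$epochs)) {
      perm <- sample.int(n)
      starts <- seq(1L, n, by = config$batch_size)
      ep_loss <- 0
      for (st in starts) {
        batch <- perm[st:min(st + config$batch_size - 1L, n)]
        cols <- as.vector(outer(seq_len(L), (batch - 1L) * L, `+`))
        lg <- cnn_loss_grad(model, Zall[, cols, drop = FALSE], y_all[batch])
        ep_loss <- ep_loss + lg$loss * length(batch)
        model$conv_w <- model$conv_w - lr * lg$grads$conv_w
        model$conv_b <- model$conv_b - lr * lg$grads$conv_b
        model$fc_w <- model$fc_w - lr * lg$grads$fc_w
        model$fc_b <- model$fc_b - lr * lg$grads$fc_b
      }
      loss_history[ep] <- ep_loss / n
    }
    model$loss_history <- loss_history
    model
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Predict class labels and probabilities
#'
#' @param object A `cnn_model`.
#' @param images List of images (or a single image) matching the model's
#'   input size.
#' @param ... Unused.
#' @return List with `labels` (character) and `probabilities` (n x 2
#'   matrix, columns named by class). Ties break toward the first class.
#' @export
predict.cnn_model <- function(object, images, ...) {
  if (inherits(images, "mi_image") || is.matrix(images)) images <- list(images)
  probs <- t(vapply(images, function(im) cnn_forward(im, object),
                    numeric(2L)))
  colnames(probs) <- object$classes
  idx <- max.col(probs, ties.method = "first")
  list(labels = object$classes[idx], probabilities = probs)
}
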