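#' Training protocol for the small CNN
#'
#' The optimizer protocol follows the source study's settings: stochastic
#' gradient descent with momentum, initial learning rate 1e-4, 30 epochs.
#' The momentum coefficient (0.9), the batch size (8), and an exponential
#' decay of the learning rate (x0.91 per epoch) are this package's
#' defaults; the decay quiets the late-epoch oscillation of plain SGDM when
#' training from random initialization.
#'
#' @param initial_learning_rate SGD learning rate at epoch 1.
#' @param max_epochs training epochs.
#' @param momentum momentum coefficient.
#' @param batch_size minibatch size.
#' @param decay_factor,decay_every piecewise schedule: the learning rate is
#'   multiplied by `decay_factor` after every `decay_every` epochs
#'   (`decay_factor = 1` disables the schedule).
#' @param seed integer seed for initialization and shuffling.
#' @return object of class `train_config`.
#' @export
train_config <- function(initial_learning_rate = 1e-4, max_epochs = 30L,
                         momentum = 0.9, batch_size = 8L,
                         decay_factor = 0.91, decay_every = 1L, seed = 1L) {
  stopifnot(initial_learning_rate > 0, max_epochs >= 1,
            decay_factor > 0, decay_factor <= 1, decay_every >= 1)
  structure(list(initial_learning_rate = initial_learning_rate,
                 max_epochs = as.integer(max_epochs), momentum = momentum,
                 batch_size = as.integer(batch_size),
                 decay_factor = decay_factor,
                 decay_every = as.integer(decay_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Crop and resample a phase map for CNN input
#'
#' Extracts a fixed-size window (`window` pixels, zero-padded at field
#' edges) centered on the centroid of the high-phase region — in practice
#' the sperm head, with the midpiece and proximal tail around it — and
#' resamples it to `size` x `size` with bilinear interpolation. The fixed
#' physical window keeps scale and position consistent across cells, so
#' pose variation reduces to rotation. Phase values stay in radians — no
#' 8-bit quantization, preserving the quantitative signal.
#'
#' @param map a [phase_map()].
#' @param size output side length (pixels).
#' @param window physical crop side length (pixels in the source map).
#' @return numeric `size` x `size` matrix.
#' @export
preprocess_for_cnn <- function(map, size = 64L, window = 128L) {
  v <- map$values
  mx <- max(v)
  idx <- which(v > 0.5 * mx, arr.ind = TRUE)
  if (mx <= 0 || nrow(idx) == 0) {
    ctr <- c(nrow(v), ncol(v)) %/% 2L
  } else {
    ctr <- round(colMeans(idx))
  }
  half <- window %/% 2L
  sq <- matrix(0, window, window)
  r1 <- ctr[1] - half + 1L; c1 <- ctr[2] - half + 1L
  rs <- max(1L, r1):min(nrow(v), r1 + window - 1L)
  cs <- max(1L, c1):min(ncol(v), c1 + window - 1L)
  sq[rs - r1 + 1L, cs - c1 + 1L] <- v[rs, cs]
  as.matrix(EBImage::resize(EBImage::Image(sq), w = size, h = size))
}

init_cnn_params <- function(channels = c(8L, 16L, 32L, 64L), input = 64L,
                            hidden = 64L, nclass = 4L, seed = 1L) {
  with_seed(seed, {
    ic <- 1L
    side <- input
    conv_W <- list(); conv_b <- list()
    for (l in seq_along(channels)) {
      oc <- channels[l]
      w <- array(rnorm(9 * ic * oc, sd = sqrt(2 / (9 * ic))),
                 dim = c(3, 3, ic, oc))
      conv_W[[l]] <- w
      conv_b[[l]] <- numeric(oc)
      ic <- oc
      side <- side %/% 2L
    }
    flat <- ic * side * side
    list(conv_W = conv_W, conv_b = conv_b,
         fc1_W = matrix(rnorm(hidden * flat, sd = sqrt(2 / flat)),
                        hidden, flat),
         fc1_b = numeric(hidden),
         fc2_W = matrix(rnorm(nclass * hidden, sd = sqrt(2 / hidden)),
                        nclass, hidden),
         fc2_b = numeric(nclass))
  })
}

# in-place-style SGDM update over the nested parameter list
sgdm_update <- function(params, velocity, grads, lr, momentum) {
  upd <- function(p, v, g) {
    v2 <- momentum * v - lr * g
    list(p = p + v2, v = v2)
  }
  for (l in seq_along(params$conv_W)) {
    r <- upd(params$conv_W[[l]], velocity$conv_W[[l]], grads$conv_W[[l]])
    params$conv_W[[l]] <- r$p; velocity$conv_W[[l]] <- r$v
    r <- upd(params$conv_b[[l]], velocity$conv_b[[l]], grads$conv_b[[l]])
    params$conv_b[[l]] <- r$p; velocity$conv_b[[l]] <- r$v
  }
  for (nm in c("fc1_W", "fc1_b", "fc2_W", "fc2_b")) {
    r <- upd(params[[nm]], velocity[[nm]], grads[[nm]])
    params[[nm]] <- r$p; velocity[[nm]] <- r$v
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) {
  rapply(params, function(x) x * 0, how = "replace")
}

#' Train the small CNN on phase images
#'
#' Trains a 4-block convolutional network (3x3 convolutions, ReLU, 2x2
#' max-pooling; two fully connected layers; softmax) from random
#' initialization with SGD-with-momentum on the stratified training split,
#' and evaluates the confusion matrix on the test split. Inputs are
#' cropped/resampled phase images standardized by the training mean and
#' standard deviation.
#'
#' @param maps list of [phase_map()]s (or a `phantom_dataset`).
#' @param labels factor of class labels (taken from the dataset if omitted).
#' @param config a [train_config()].
#' @param spec a [split_spec()].
#' @param input_size CNN input side length.
#' @param channels per-block channel counts.
#' @return object of class `spermqpi_cnn`: trained `params`, per-epoch
#'   `history` (`loss` = training loss evaluated at the end of each epoch,
#'   `batch_loss` = running mean over that epoch's minibatches, training
#'   accuracy), test `confusion`, `metrics`, `accuracy`, the `split` and
#'   normalization constants.
#' @export
train_cnn <- function(maps, labels = NULL, config = train_config(),
                      spec = split_spec(), input_size = 64L,
                      channels = c(8L, 16L, 32L, 64L)) {
  if (inherits(maps, "phantom_dataset")) {
    if (is.null(labels)) labels <- maps$labels
    maps <- maps$maps
  }
  labels <- droplevels(as.factor(labels))
  stopifnot(length(maps) == length(labels))
  n <- length(maps)
  X <- array(0, dim = c(input_size, input_size, n))
  for (i in seq_len(n)) X[, , i] <- preprocess_for_cnn(maps[[i]], input_size)
  split <- split_dataset(labels, spec)
  mu <- mean(X[, , split$train]); sig <- sd(X[, , split$train])
  if (sig == 0) sig <- 1
  X <- (X - mu) / sig
  y <- as.integer(labels) - 1L

  params <- init_cnn_params(channels, input_size, nclass = nlevels(labels),
                            seed = config$seed)
  velocity <- zero_like(params)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        batch_loss = numeric(), train_accuracy = numeric())
  order_seeds <- derive_seeds(config$seed + 1L, config$max_epochs)
  for (ep in seq_len(config$max_epochs)) {
    lr <- config$initial_learning_rate *
      config$decay_factor^((ep - 1) %/% config$decay_every)
    idx <- with_seed(order_seeds[ep], sample(split$train))
    batches <- split(idx, ceiling(seq_along(idx) / config$batch_size))
    ep_loss <- 0; ep_acc <- 0
    for (b in batches) {
      res <- cpp_cnn_batch(params, X, as.integer(b - 1L),
                           as.integer(y[b]), TRUE)
      if (!is.finite(res$loss)) {
        stop("non-finite loss at epoch ", ep, "; aborting training")
      }
      st <- sgdm_update(params, velocity, res$grads, lr, config$momentum)
      params <- st$params; velocity <- st$velocity
      ep_loss <- ep_loss + res$loss * length(b)
      ep_acc <- ep_acc + res$accuracy * length(b)
    }
    # training loss of the state reached at the end of the epoch
    ev <- cpp_cnn_batch(params, X, as.integer(split$train - 1L),
                        as.integer(y[split$train]), FALSE)
    history <- rbind(history, data.frame(
      epoch = ep, loss = ev$loss, batch_loss = ep_loss / length(idx),
      train_accuracy = ev$accuracy))
  }
  probs <- cpp_cnn_predict(params, X, as.integer(split$test - 1L))
  pred <- factor(levels(labels)[max.col(probs, ties.method = "first")],
                 levels = levels(labels))
  cm <- confusion_matrix(labels[split$test], pred, levels = levels(labels))
  structure(list(params = params, history = history, confusion = cm,
                 metrics = confusion_metrics(cm),
                 accuracy = sum(diag(cm)) / sum(cm), split = split,
                 normalization = c(center = mu, scale = sig),
                 input_size = input_size, channels = channels,
                 class_levels = levels(labels)),
            class = "spermqpi_cnn")
}

#' @export
print.spermqpi_cnn <- function(x, ...) {
  cat(sprintf("<spermqpi_cnn> %s blocks, test accuracy %.3f\n",
              paste(x$channels, collapse = "-"), x$accuracy))
  invisible(x)
}

#' Predict classes for new phase maps with a trained CNN
#'
#' @param object a trained `spermqpi_cnn`.
#' @param maps list of [phase_map()]s.
#' @param ... unused.
#' @return factor of predicted classes.
#' @export
predict.spermqpi_cnn <- function(object, maps, ...) {
  n <- length(maps)
  X <- array(0, dim = c(object$input_size, object$input_size, n))
  for (i in seq_len(n)) {
    X[, , i] <- preprocess_for_cnn(maps[[i]], object$input_size)
  }
  X <- (X - object$normalization["center"]) / object$normalization["scale"]
  probs <- cpp_cnn_predict(object$params, X, as.integer(seq_len(n) - 1L))
  factor(object$class_levels[max.col(probs, ties.method = "first")],
         levels = object$class_levels)
}
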