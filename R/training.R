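#' Training configuration
#'
#' Defaults follow the study protocol: 100 epochs of SGD at batch size 64 on
#' 224 x 224 inputs, initial learning rate 0.01 decayed by 0.95 every 2
#' epochs (the "95-Gradient" step schedule). Momentum (0.9) and weight decay
#' (0) are exposed because the protocol names only "SGD".
#'
#' @param epochs number of training epochs.
#' @param batch_size minibatch size.
#' @param input_size square input resolution fed to the network.
#' @param lr0 initial learning rate (> 0).
#' @param decay_rate multiplicative decay factor in (0, 1].
#' @param decay_every decay period in epochs (>= 1).
#' @param momentum SGD momentum.
#' @param weight_decay L2 penalty coefficient.
#' @param rng_seed seed for shuffling and noise.
#' @return list of class `"train_config"`.
#' @export
train_config <- function(epochs = 100L, batch_size = 64L, input_size = 224L,
                         lr0 = 0.01, decay_rate = 0.95, decay_every = 2L,
                         momentum = 0.9, weight_decay = 0, rng_seed = 0L) {
  if (lr0 <= 0) stopf("lr0 must be > 0")
  if (decay_rate <= 0 || decay_rate > 1) stopf("decay_rate must be in (0, 1]")
  if (decay_every < 1) stopf("decay_every must be >= 1")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 input_size = as.integer(input_size), lr0 = lr0,
                 decay_rate = decay_rate, decay_every = as.integer(decay_every),
                 momentum = momentum, weight_decay = weight_decay,
                 rng_seed = as.integer(rng_seed)),
            class = "train_config")
}

#' Step-decay learning rate ("95-Gradient")
#'
#' `lr(e) = lr0 * decay_rate ^ floor(e / decay_every)`: constant within each
#' `decay_every`-epoch window, multiplied by `decay_rate` between windows.
#' Epochs are 0-indexed, so `lr(0) = lr0`.
#'
#' @param e epoch index (>= 0; vectorised).
#' @param config a [train_config()].
#' @return learning rate(s).
#' @examples
#' lr_at_epoch(0, train_config())  # 0.01
#' lr_at_epoch(5, train_config())  # 0.009025
#' @export
lr_at_epoch <- function(e, config = train_config()) {
  if (any(e < 0)) stopf("epoch index must be >= 0")
  config$lr0 * config$decay_rate^(e %/% config$decay_every)
}

#' Multiclass cross-entropy loss
#'
#' `L = -sum_c y_c log p_c = -log p_label` for a one-hot label. Probabilities
#' are clamped at `eps` so an exactly-zero predicted probability yields a
#' large finite loss rather than `Inf`.
#'
#' @param probs probability vector over classes (sums to 1).
#' @param label true class index (1-based).
#' @param eps clamping epsilon.
#' @return non-negative scalar loss; 0 iff `probs[label] == 1`.
#' @examples
#' cross_entropy(c(0.5, 0.5), 1)      # log(2)
#' cross_entropy(rep(1/8, 8), 3)      # log(8)
#' @export
cross_entropy <- function(probs, label, eps = 1e-12) {
  if (label < 1 || label > length(probs)) stopf("label out of range")
  -log(max(probs[label], eps))
}

softmax_cols <- function(logits) {
  z <- sweep(logits, 2, apply(logits, 2, max), "-")
  ez <- exp(z)
  sweep(ez, 2, colSums(ez), "/")
}

# Mean cross-entropy and gradient wrt logits for a batch (labels 1-based).
batch_ce_grad <- function(logits, labels, eps = 1e-12) {
  p <- softmax_cols(logits)
  n <- ncol(logits)
  idx <- cbind(labels, seq_len(n))
  loss <- -mean(log(pmax(p[idx], eps)))
  d <- p
  d[idx] <- d[idx] - 1
  list(loss = loss, dlogits = d / n, probs = p)
}

#' Load the images of a manifest into a batch tensor
#'
#' @param manifest data.frame with `path` and `label` columns.
#' @param size square side images are resized to (bilinear) when needed.
#' @param class_levels ordered class names defining the label indices;
#'   default: sorted unique labels of the manifest.
#' @return list with `x` (size x size x 3 x N array), `y` (integer labels),
#'   `class_levels`.
#' @export
load_manifest_images <- function(manifest, size, class_levels = NULL) {
  class_levels <- class_levels %||% sort(unique(manifest$label))
  n <- nrow(manifest)
  if (n == 0) stopf("empty manifest")
  x <- array(0, dim = c(size, size, 3L, n))
  for (i in seq_len(n)) {
    img <- read_image(manifest$path[i])
    if (!all(dim(img)[1:2] == c(size, size))) {
      img <- EBImage::resize(img, w = size, h = size)
      img <- array(img, dim = c(size, size, 3L))
    }
    x[, , , i] <- img
  }
  y <- match(manifest$label, class_levels)
  if (anyNA(y)) stopf("manifest contains labels outside class_levels")
  list(x = x, y = y, class_levels = class_levels)
}

#' Train a model with SGD and the step-decay schedule
#'
#' Runs `config$epochs` epochs of momentum SGD on softmax cross-entropy,
#' evaluating on the validation manifest after every epoch. The best
#' checkpoint is the epoch with the highest validation accuracy (ties broken
#' by lower validation loss). Fully seeded: the same config and seed
#' reproduce the same history.
#'
#' @param model a `"seednet_model"` (its input size should match
#'   `config$input_size`).
#' @param train_manifest,val_manifest manifests with `path`, `label`.
#' @param config a [train_config()].
#' @param verbose print one line per epoch.
#' @return list with `history` (data.frame: epoch, lr, train_loss, train_acc,
#'   val_loss, val_acc), `best_model`, `best_epoch`, `final_model`,
#'   `class_levels`.
#' @export
train_model <- function(model, train_manifest, val_manifest,
                        config = train_config(), verbose = FALSE) {
  if (nrow(train_manifest) == 0 || nrow(val_manifest) == 0)
    stopf("empty train or validation split")
  tr <- load_manifest_images(train_manifest, config$input_size)
  va <- load_manifest_images(val_manifest, config$input_size, tr$class_levels)
  set.seed(config$rng_seed)
  n <- length(tr$y)
  state <- NULL
  hist <- vector("list", config$epochs)
  best <- list(acc = -Inf, loss = Inf, model = model, epoch = 0L)
  for (e in seq_len(config$epochs) - 1L) {
    lr <- lr_at_epoch(e, config)
    ord <- sample.int(n)
    tl <- 0; tc <- 0
    for (b in seq_len(ceiling(n / config$batch_size))) {
      sel <- ord[((b - 1) * config$batch_size + 1):min(b * config$batch_size, n)]
      xb <- tr$x[, , , sel, drop = FALSE]
      yb <- tr$y[sel]
      fw <- model_forward(model, xb, training = TRUE)
      model <- fw$model
      ce <- batch_ce_grad(fw$out, yb)
      if (!is.finite(ce$loss))
        stopf("non-finite training loss at epoch %d, batch %d (lr = %g)",
              e, b, lr)
      bw <- model_backward(model, fw$caches, ce$dlogits)
      up <- sgd_update_model(model, bw$grads, state, lr, config$momentum,
                             config$weight_decay)
      model <- up$model
      state <- up$state
      tl <- tl + ce$loss * length(sel)
      tc <- tc + sum(apply(ce$probs, 2, which.max) == yb)
    }
    ev <- evaluate_batch(model, va$x, va$y, config$batch_size)
    hist[[e + 1L]] <- data.frame(epoch = e, lr = lr, train_loss = tl / n,
                                 train_acc = tc / n, val_loss = ev$loss,
                                 val_acc = ev$acc)
    if (ev$acc > best$acc || (ev$acc == best$acc && ev$loss < best$loss)) {
      best <- list(acc = ev$acc, loss = ev$loss, model = model,
                   epoch = e)
    }
    if (verbose)
      message(sprintf("epoch %3d  lr %.6f  train %.4f/%.3f  val %.4f/%.3f",
                      e, lr, tl / n, tc / n, ev$loss, ev$acc))
  }
  list(history = do.call(rbind, hist), best_model = best$model,
       best_epoch = best$epoch, final_model = model,
       class_levels = tr$class_levels)
}

# Forward a dataset in inference mode; mean loss and accuracy.
evaluate_batch <- function(model, x, y, batch_size = 64L) {
  n <- length(y)
  loss <- 0; correct <- 0
  preds <- integer(n)
  for (b in seq_len(ceiling(n / batch_size))) {
    sel <- ((b - 1) * batch_size + 1):min(b * batch_size, n)
    out <- model_forward(model, x[, , , sel, drop = FALSE],
                         training = FALSE)$out
    ce <- batch_ce_grad(out, y[sel])
    loss <- loss + ce$loss * length(sel)
    preds[sel] <- apply(ce$probs, 2, which.max)
    correct <- correct + sum(preds[sel] == y[sel])
  }
  list(loss = loss / n, acc = correct / n, preds = preds)
}

#' Predict class labels for a manifest
#'
#' @param model trained `"seednet_model"`.
#' @param manifest manifest with `path`, `label`.
#' @param class_levels ordered class names used at training time.
#' @param input_size resolution to evaluate at.
#' @param batch_size evaluation batch size.
#' @return list with `pred` (integer), `truth` (integer), `loss`, `acc`.
#' @export
predict_manifest <- function(model, manifest, class_levels,
                             input_size = 224L, batch_size = 64L) {
  d <- load_manifest_images(manifest, input_size, class_levels)
  ev <- evaluate_batch(model, d$x, d$y, batch_size)
  list(pred = ev$preds, truth = d$y, loss = ev$loss, acc = ev$acc)
}
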