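#' Confusion matrix
#'
#' Rows are the actual class, columns the predicted class; cell (i, j) counts
#' samples of class i predicted as class j.
#'
#' @param predicted,actual equal-length label vectors (1-based integers, or
#'   values matching `levels`).
#' @param n_classes number of classes M (default: inferred).
#' @param levels optional class names for dimnames.
#' @return M x M integer matrix of class `"confusion_matrix"`.
#' @export
confusion_matrix <- function(predicted, actual, n_classes = NULL,
                             levels = NULL) {
  if (length(predicted) != length(actual))
    stopf("predicted and actual differ in length (%d vs %d)",
          length(predicted), length(actual))
  if (!is.null(levels)) {
    predicted <- match(predicted, levels)
    actual <- match(actual, levels)
    n_classes <- n_classes %||% length(levels)
  }
  n_classes <- n_classes %||% max(predicted, actual, 0L)
  if (length(predicted) &&
      (anyNA(predicted) || anyNA(actual) ||
       any(predicted < 1 | predicted > n_classes) ||
       any(actual < 1 | actual > n_classes)))
    stopf("labels out of range 1..%d", n_classes)
  cm <- matrix(0L, n_classes, n_classes)
  for (i in seq_along(actual))
    cm[actual[i], predicted[i]] <- cm[actual[i], predicted[i]] + 1L
  if (!is.null(levels)) dimnames(cm) <- list(actual = levels, predicted = levels)
  class(cm) <- c("confusion_matrix", class(cm))
  cm
}

#' F1 score from precision and recall
#'
#' `F1 = 2PR / (P + R)` — algebraically equal to `2TP / (2TP + FP + FN)`.
#' Returns 0 when `P + R` is 0.
#'
#' @param p,r precision and recall in `[0, 1]` (vectorised).
#' @return F1 in `[0, 1]`.
#' @examples
#' round(f1_score(0.937, 0.950), 3)  # 0.943
#' @export
f1_score <- function(p, r) ifelse(p + r > 0, 2 * p * r / (p + r), 0)

#' Per-class and macro metrics from a confusion matrix
#'
#' One-vs-rest TP/FP/FN/TN per class give accuracy
#' `(TP + TN) / (TP + FP + FN + TN)`, precision `TP / (TP + FP)`, recall
#' `TP / (TP + FN)` and `F1 = 2TP / (2TP + FP + FN)`. Macro averages are
#' unweighted class means; overall accuracy is `trace / total`. Classes with
#' a zero denominator report the metric as 0 and are flagged (`undefined`),
#' keeping the report schema stable.
#'
#' @param cm square count matrix (rows = actual).
#' @return list of class `"class_metrics"`: `per_class` data.frame (tp, fp,
#'   fn, tn, acc, precision, recall, f1, undefined), `macro` (named vector),
#'   `accuracy` (overall), `total`.
#' @export
metrics_from_confusion <- function(cm) {
  if (nrow(cm) != ncol(cm)) stopf("confusion matrix must be square")
  if (any(cm < 0)) stopf("confusion matrix counts must be >= 0")
  total <- sum(cm)
  tp <- diag(cm)
  fp <- colSums(cm) - tp
  fn <- rowSums(cm) - tp
  tn <- total - tp - fp - fn
  undef <- (tp + fp == 0) | (tp + fn == 0)
  if (any(undef))
    warning(sprintf("class(es) %s have no predictions or no samples; metrics reported as 0",
                    paste(which(undef), collapse = ", ")), call. = FALSE)
  precision <- ifelse(tp + fp > 0, tp / (tp + fp), 0)
  recall <- ifelse(tp + fn > 0, tp / (tp + fn), 0)
  f1 <- ifelse(2 * tp + fp + fn > 0, 2 * tp / (2 * tp + fp + fn), 0)
  acc <- if (total > 0) (tp + tn) / total else rep(0, nrow(cm))
  per_class <- data.frame(
    class = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    tp = tp, fp = fp, fn = fn, tn = tn, acc = acc,
    precision = precision, recall = recall, f1 = f1, undefined = undef)
  structure(list(
    per_class = per_class,
    macro = c(precision = mean(precision), recall = mean(recall),
              f1 = mean(f1)),
    accuracy = if (total > 0) sum(tp) / total else 0,
    total = total), class = "class_metrics")
}

#' @export
print.class_metrics <- function(x, ...) {
  cat(sprintf("accuracy: %.4f over %d samples\n", x$accuracy, x$total))
  df <- x$per_class
  df[c("acc", "precision", "recall", "f1")] <-
    round(df[c("acc", "precision", "recall", "f1")], 3)
  print(df[c("class", "precision", "recall", "f1", "acc")], row.names = FALSE)
  cat(sprintf("macro: P %.3f  R %.3f  F1 %.3f\n",
              x$macro["precision"], x$macro["recall"], x$macro["f1"]))
  invisible(x)
}

#' Grad-CAM class-activation heatmap
#'
#' Backpropagates the target-class logit to a convolutional layer's feature
#' maps, averages the gradients spatially to get per-channel weights,
#' rectifies the weighted sum of the maps, min-max normalises it to `[0, 1]`
#' and upsamples (bilinear) to the input resolution. A constant map (e.g.
#' all-zero input through a bias-free model) normalises to all zeros.
#'
#' @param model a `"seednet_model"` (trained or freshly initialised).
#' @param image H x W x 3 array matching the model's input size.
#' @param target_class class index (1-based).
#' @param layer index of the tapped top-level layer; default the last
#'   bottleneck. The layer must output spatial feature maps.
#' @return H x W heatmap in `[0, 1]`.
#' @export
grad_cam <- function(model, image, target_class, layer = NULL) {
  layer <- layer %||% model$tap_default
  if (model$layers[[layer]]$kind %in% c("classifier"))
    stopf("layer %d has no spatial feature maps", layer)
  x <- image
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  fw <- model_forward(model, x, training = FALSE, tap = layer)
  k <- nrow(fw$out)
  if (target_class < 1 || target_class > k)
    stopf("target_class must lie in 1..%d", k)
  dout <- matrix(0, k, 1)
  dout[target_class, 1] <- 1
  bw <- model_backward(fw$model, fw$caches, dout, stop_at = layer + 1L)
  A <- fw$tap_out[, , , 1, drop = FALSE]          # H' x W' x C x 1
  G <- bw$dx[, , , 1, drop = FALSE]
  C <- dim(A)[3]
  wts <- colMeans(matrix(G, ncol = C))            # spatial mean per channel
  cam <- matrix(0, dim(A)[1], dim(A)[2])
  for (c in seq_len(C)) cam <- cam + wts[c] * A[, , c, 1]
  cam <- pmax(cam, 0)
  rng <- range(cam)
  cam <- if (rng[2] > rng[1]) (cam - rng[1]) / (rng[2] - rng[1]) else cam * 0
  H <- dim(image)[1]; W <- dim(image)[2]
  out <- EBImage::resize(cam, w = H, h = W)
  pmin(pmax(matrix(out, H, W), 0), 1)
}
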