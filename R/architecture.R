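#' Inverted-residual stage table and network specification
#'
#' `mobilenet_stages()` returns the canonical seven-stage table of the
#' MobileNetV2 backbone: each row gives the expansion factor `t`, output
#' channels `c`, repeat count `n` and first-repeat stride `s`. Together with a
#' 3x3/stride-2 stem conv to 32 channels, a 1x1 head conv to 1280 channels,
#' global average pooling and a k-way classifier this fully determines the
#' network (17 bottlenecks in total).
#'
#' `network_spec()` bundles the stage table with the input size, class count
#' and variant flag. `variant = "baseline"` is the unmodified backbone with
#' ReLU6 activations; `variant = "hp"` inserts a DMS gating block after the
#' depthwise batch norm and an ECA block after the projection batch norm of
#' every bottleneck, and replaces ReLU6 with Mish everywhere.
#'
#' @param stages data.frame with columns t, c, n, s.
#' @param n_classes number of output classes.
#' @param input_size square input resolution in pixels.
#' @param variant `"baseline"` or `"hp"`.
#' @param stem_channels,head_channels stem / head conv widths.
#' @return `network_spec()` returns a list of class `"network_spec"`.
#' @export
mobilenet_stages <- function() {
  data.frame(
    t = c(1L, 6L, 6L, 6L, 6L, 6L, 6L),
    c = c(16L, 24L, 32L, 64L, 96L, 160L, 320L),
    n = c(1L, 2L, 3L, 4L, 3L, 3L, 1L),
    s = c(1L, 2L, 2L, 2L, 1L, 2L, 1L)
  )
}

#' @rdname mobilenet_stages
#' @export
network_spec <- function(n_classes = 8L, input_size = 224L,
                         variant = c("baseline", "hp"),
                         stages = mobilenet_stages(),
                         stem_channels = 32L, head_channels = 1280L) {
  variant <- match.arg(variant)
  stopifnot(is.data.frame(stages),
            all(c("t", "c", "n", "s") %in% names(stages)))
  if (any(stages$t < 1) || any(stages$n < 1) || !all(stages$s %in% c(1L, 2L)))
    stopf("malformed stage table: need t >= 1, n >= 1, s in {1, 2}")
  structure(list(n_classes = as.integer(n_classes),
                 input_size = as.integer(input_size),
                 variant = variant, stages = stages,
                 stem_channels = as.integer(stem_channels),
                 head_channels = as.integer(head_channels)),
            class = "network_spec")
}

#' Adaptive 1-D kernel size for efficient channel attention
#'
#' The ECA kernel width grows logarithmically with the channel count:
#' `k = | (log2(C) + b) / gamma |_odd` with `gamma = 2`, `b = 1`. The odd
#' mapping is the canonical one: truncate to an integer and, if even, step up
#' to the next odd number (so C = 64 with s = 3.5 gives k = 3).
#'
#' @param C channel count (>= 1).
#' @param gamma,b schedule coefficients.
#' @return odd integer kernel size, at least 1.
#' @examples
#' eca_kernel_size(32)   # 3
#' eca_kernel_size(320)  # 5
#' @export
eca_kernel_size <- function(C, gamma = 2, b = 1) {
  if (any(C < 1)) stopf("channel count must be >= 1")
  s <- (log2(C) + b) / gamma
  k <- floor(abs(s))
  k <- ifelse(k %% 2 == 0, k + 1, k)
  as.integer(pmax(k, 1))
}

#' Construct an efficient channel attention (ECA) block
#'
#' Global average pooling reduces the H x W x C input to a length-C channel
#' descriptor, a width-k 1-D convolution (no bias) mixes neighbouring
#' channels, a logistic map squashes the result to (0, 1), and the input is
#' reweighted channel-wise. Adds exactly k learnable weights.
#'
#' @param C channel count the block operates on.
#' @param gamma,b kernel-size schedule coefficients (see [eca_kernel_size()]).
#' @return an ECA layer object.
#' @export
build_eca_block <- function(C, gamma = 2, b = 1) {
  k <- eca_kernel_size(C, gamma, b)
  list(kind = "eca", c = C, k = k,
       params = list(w = rnorm(k, sd = sqrt(1 / k))))
}

#' Construct a DMS (depthwise Mish/Sigmoid) gating block
#'
#' The block downsamples its input by adaptive average pooling to a small
#' `pooled_size` x `pooled_size` grid, extracts features with two depthwise
#' 3x3 convolutions (bias on the first only) activated by Mish and Sigmoid
#' respectively, upsamples the resulting (0, 1) gate back to the input
#' resolution (nearest neighbour), and joins residually:
#' `out = x + x * gate`. Learnable parameters: 9C + C + 9C = 19C.
#'
#' @param channels operating channel count (the bottleneck's expanded width).
#' @param pooled_size side of the pooled grid (default 5).
#' @return a DMS layer object.
#' @export
build_dms_block <- function(channels, pooled_size = 5L) {
  if (channels < 1) stopf("channels must be positive")
  list(kind = "dms", c = channels, pooled_size = as.integer(pooled_size),
       sub = list(
         conv1 = new_conv_layer(channels, channels, 3L, stride = 1L, pad = 1L,
                                groups = channels, bias = TRUE),
         conv2 = new_conv_layer(channels, channels, 3L, stride = 1L, pad = 1L,
                                groups = channels, bias = FALSE)),
       params = list())
}

#' Construct an inverted-residual bottleneck
#'
#' The baseline block expands channels with a 1x1 conv (+BN+activation),
#' filters spatially with a depthwise 3x3 conv (+BN+activation, stride `s`),
#' and projects back down with a linear 1x1 conv (+BN). The shortcut is added
#' only when `stride == 1` and `in_c == out_c`. When `t == 1` the expansion
#' conv is omitted (the depthwise conv operates on the input directly).
#'
#' The `"hp"` variant inserts a DMS block right after the depthwise batch
#' norm and an ECA block after the projection batch norm, and uses Mish
#' wherever the baseline uses ReLU6.
#'
#' @param in_c,out_c input / output channels.
#' @param t expansion factor (>= 1).
#' @param stride 1 or 2.
#' @param variant `"baseline"` or `"hp"`.
#' @param dms_pooled_size pooled grid side for the DMS block.
#' @return a bottleneck layer object.
#' @export
build_bottleneck <- function(in_c, out_c, t, stride, variant = "baseline",
                             dms_pooled_size = 5L) {
  if (!stride %in% c(1L, 2L)) stopf("stride must be 1 or 2, got %s", stride)
  if (t < 1) stopf("expansion factor must be >= 1")
  act <- if (variant == "hp") "mish" else "relu6"
  hidden <- as.integer(t * in_c)
  sub <- list()
  if (t != 1) {
    sub$expand_conv <- new_conv_layer(in_c, hidden, 1L)
    sub$expand_bn <- new_bn_layer(hidden)
    sub$expand_act <- new_act_layer(act)
  }
  sub$dw_conv <- new_conv_layer(hidden, hidden, 3L, stride = stride, pad = 1L,
                                groups = hidden)
  sub$dw_bn <- new_bn_layer(hidden)
  if (variant == "hp") sub$dms <- build_dms_block(hidden, dms_pooled_size)
  sub$dw_act <- new_act_layer(act)
  sub$proj_conv <- new_conv_layer(hidden, out_c, 1L)
  sub$proj_bn <- new_bn_layer(out_c)
  if (variant == "hp") sub$eca <- build_eca_block(out_c)
  list(kind = "bottleneck", in_c = in_c, out_c = out_c, t = t,
       stride = as.integer(stride), hidden = hidden, variant = variant,
       use_shortcut = stride == 1L && in_c == out_c,
       sub = sub, params = list())
}

#' Build a network from a specification
#'
#' Assembles stem conv, the bottleneck stages (within a stage only the first
#' repeat uses the stage stride), head conv, global average pooling and the
#' classifier. Weights are initialised Kaiming-normal (convs), (1, 0) (batch
#' norm); call `set.seed()` beforehand for reproducible initialisation.
#'
#' @param spec a [network_spec()].
#' @return a model object of class `"seednet_model"`.
#' @examples
#' set.seed(1)
#' m <- build_network(network_spec(n_classes = 8, variant = "baseline"))
#' model_params(m)  # 2234120
#' @export
build_network <- function(spec) {
  if (!inherits(spec, "network_spec")) stopf("spec must be a network_spec")
  act <- if (spec$variant == "hp") "mish" else "relu6"
  layers <- list(
    stem_conv = new_conv_layer(3L, spec$stem_channels, 3L, stride = 2L, pad = 1L),
    stem_bn = new_bn_layer(spec$stem_channels),
    stem_act = new_act_layer(act))
  cin <- spec$stem_channels
  bi <- 0L
  for (r in seq_len(nrow(spec$stages))) {
    st <- spec$stages[r, ]
    for (i in seq_len(st$n)) {
      bi <- bi + 1L
      layers[[sprintf("bottleneck_%02d", bi)]] <-
        build_bottleneck(cin, st$c, st$t, if (i == 1L) st$s else 1L,
                         variant = spec$variant)
      cin <- st$c
    }
  }
  layers$head_conv <- new_conv_layer(cin, spec$head_channels, 1L)
  layers$head_bn <- new_bn_layer(spec$head_channels)
  layers$head_act <- new_act_layer(act)
  layers$classifier <- new_classifier_layer(spec$head_channels, spec$n_classes)
  structure(list(layers = layers, spec = spec,
                 tap_default = grep("^bottleneck_", names(layers)) |> max()),
            class = "seednet_model")
}

#' Run a model forward on a batch of images
#'
#' @param model a `"seednet_model"`.
#' @param x numeric array, either `H x W x 3` (one image) or `H x W x 3 x N`.
#' @param training logical; use batch statistics and update running stats.
#' @return matrix of logits, `n_classes x N`.
#' @export
predict_logits <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  model_forward(model, x, training = training)$out
}

#' Count every learnable scalar in a model
#'
#' Enumerates the actual parameter arrays (conv weights and biases, batch-norm
#' scale/shift, ECA kernels, classifier weights) rather than evaluating closed
#' forms, so it serves as the independent check on [conv_param_count()].
#'
#' @param model a `"seednet_model"` (or any layer tree).
#' @return integer number of learnable scalars.
#' @export
model_params <- function(model) {
  sum(vapply(model$layers, count_layer_params, 0))
}

#' @export
print.seednet_model <- function(x, ...) {
  s <- x$spec
  cat(sprintf("<seednet_model> variant=%s classes=%d input=%d params=%s\n",
              s$variant, s$n_classes, s$input_size,
              format(model_params(x), big.mark = ",")))
  invisible(x)
}
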