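#' Closed-form convolution parameter and FLOP counts
#'
#' Standard, grouped and depthwise convolutions share one pair of closed
#' forms: a layer with kernel side K, `c_in` input channels, `c_out` output
#' channels and G groups has `K^2 * (c_in / G) * c_out` weights (plus `c_out`
#' biases if present), and costs `K^2 * (c_in / G) * c_out * H * W`
#' multiply-accumulates for an H x W output. `G = 1` is a standard conv;
#' `G = c_in` (with `c_out` a multiple of `c_in`) is depthwise, reducing the
#' weight count to `K^2 * c_out`.
#'
#' @param k kernel side.
#' @param c_in,c_out input / output channel counts.
#' @param groups group count G; both channel counts must be divisible by it.
#' @param bias logical, count `c_out` bias terms.
#' @param h_out,w_out output spatial size (FLOPs only).
#' @return integer-valued count (as a double to avoid overflow).
#' @examples
#' conv_param_count(3, 16, 32)                 # 4608
#' conv_param_count(3, 96, 96, groups = 96)    # 864 (depthwise)
#' @export
conv_param_count <- function(k, c_in, c_out, groups = 1, bias = FALSE) {
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stopf("channel counts (%d, %d) must be divisible by groups = %d",
          c_in, c_out, groups)
  k^2 * (c_in / groups) * c_out + if (bias) c_out else 0
}

#' @rdname conv_param_count
#' @export
conv_flop_count <- function(k, c_in, c_out, h_out, w_out, groups = 1) {
  if (c_in %% groups != 0 || c_out %% groups != 0)
    stopf("channel counts (%d, %d) must be divisible by groups = %d",
          c_in, c_out, groups)
  k^2 * (c_in / groups) * c_out * h_out * w_out
}

conv_out_size <- function(h, k, stride, pad) (h + 2 * pad - k) %/% stride + 1

# Analytic cost of one layer at input side h; returns list(flops, h_out, rows).
profile_layer <- function(layer, h, bn_ops) {
  rows <- NULL
  flops <- 0
  switch(layer$kind,
    conv = {
      ho <- conv_out_size(h, layer$k, layer$stride, layer$pad)
      flops <- conv_flop_count(layer$k, layer$in_c, layer$out_c, ho, ho,
                               layer$groups)
      rows <- data.frame(layer = sprintf("conv %dx%d %d->%d/g%d", layer$k,
                                         layer$k, layer$in_c, layer$out_c,
                                         layer$groups),
                         params = count_layer_params(layer), flops = flops,
                         out_size = ho)
      h <- ho
    },
    bn = {
      flops <- bn_ops * h^2 * layer$c
      rows <- data.frame(layer = sprintf("bn %d", layer$c),
                         params = count_layer_params(layer), flops = flops,
                         out_size = h)
    },
    act = {
      rows <- data.frame(layer = paste0("act ", layer$fun), params = 0,
                         flops = 0, out_size = h)
    },
    eca = {
      flops <- layer$k * layer$c
      rows <- data.frame(layer = sprintf("eca k=%d C=%d", layer$k, layer$c),
                         params = count_layer_params(layer), flops = flops,
                         out_size = h)
    },
    dms = {
      s <- layer$pooled_size
      flops <- 2 * conv_flop_count(3, layer$c, layer$c, s, s, groups = layer$c)
      rows <- data.frame(layer = sprintf("dms C=%d pool=%d", layer$c, s),
                         params = count_layer_params(layer), flops = flops,
                         out_size = h)
    },
    classifier = {
      flops <- layer$in_c * layer$n_classes
      rows <- data.frame(layer = sprintf("gap+linear %d->%d", layer$in_c,
                                         layer$n_classes),
                         params = count_layer_params(layer), flops = flops,
                         out_size = 1)
      h <- 1
    },
    bottleneck = {
      hh <- h
      for (sl in layer$sub) {
        r <- profile_layer(sl, hh, bn_ops)
        flops <- flops + r$flops
        hh <- r$h_out
      }
      rows <- data.frame(layer = sprintf("bottleneck t=%d %d->%d s=%d%s",
                                         layer$t, layer$in_c, layer$out_c,
                                         layer$stride,
                                         if (layer$variant == "hp") " [dms+eca]" else ""),
                         params = count_layer_params(layer), flops = flops,
                         out_size = hh)
      h <- hh
    },
    stopf("unknown layer kind '%s'", layer$kind))
  list(flops = flops, h_out = h, rows = rows)
}

#' Profile a model: exact parameter count and FLOPs
#'
#' Parameters are counted by enumerating every learnable scalar in the model.
#' FLOPs are multiply-accumulate counts of the conv/linear layers from the
#' closed forms in [conv_flop_count()], plus a per-element cost for batch
#' normalisation set by `bn_ops_per_element`. The default of 4 corresponds to
#' an unfused batch norm (subtract mean, divide by standard deviation, scale,
#' shift, per element); activations, pooling and elementwise residual/gating
#' arithmetic are excluded. Under this convention the unmodified 8-class
#' baseline reports 2.234 M / 0.326 G and the hp variant 2.370 M / 0.329 G.
#'
#' @param model a `"seednet_model"`.
#' @param input_size square input resolution (defaults to the spec's).
#' @param bn_ops_per_element per-element batch-norm cost switch.
#' @return list of class `"model_profile"`: `params`, `flops` (exact counts),
#'   `params_M`, `flops_G` (rounded to 3 decimals), and a per-layer `table`.
#' @examples
#' set.seed(1)
#' pr <- model_profile(build_network(network_spec(8, variant = "baseline")))
#' pr$params_M  # 2.234
#' @export
model_profile <- function(model, input_size = NULL,
                          bn_ops_per_element = 4) {
  h <- input_size %||% model$spec$input_size
  flops <- 0
  tabs <- list()
  for (i in seq_along(model$layers)) {
    r <- profile_layer(model$layers[[i]], h, bn_ops_per_element)
    flops <- flops + r$flops
    h <- r$h_out
    tabs[[i]] <- r$rows
  }
  params <- model_params(model)
  structure(list(params = params, flops = flops,
                 params_M = round(params / 1e6, 3),
                 flops_G = round(flops / 1e9, 3),
                 table = do.call(rbind, tabs)),
            class = "model_profile")
}

#' @export
print.model_profile <- function(x, ...) {
  cat(sprintf("params: %s (%.3f M)   flops: %s (%.3f G)\n",
              format(x$params, big.mark = ","), x$params_M,
              format(x$flops, big.mark = ","), x$flops_G))
  invisible(x)
}

#' Profile the baseline and hp variants side by side
#'
#' @param n_classes number of classes.
#' @param input_size input resolution.
#' @param seed integer seed for (irrelevant to counting) weight init.
#' @return data.frame with one row per variant plus a delta row.
#' @export
profile_variants <- function(n_classes = 8L, input_size = 224L, seed = 0L) {
  set.seed(seed)
  base <- model_profile(build_network(
    network_spec(n_classes, input_size, "baseline")))
  hp <- model_profile(build_network(
    network_spec(n_classes, input_size, "hp")))
  data.frame(
    variant = c("baseline", "hp", "delta"),
    params_M = round(c(base$params, hp$params, hp$params - base$params) / 1e6, 3),
    flops_G = round(c(base$flops, hp$flops, hp$flops - base$flops) / 1e9, 3))
}
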