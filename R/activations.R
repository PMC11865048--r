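#' Activation functions
#'
#' Elementwise activations used by the networks. `mish(x) = x * tanh(softplus(x))`
#' is smooth and non-monotonic (global minimum about -0.3088 near x = -1.19),
#' asymptotically the identity for large x and 0 for very negative x.
#' `relu6` clamps to `[0, 6]`. `sigmoid` is the logistic map.
#'
#' @param x numeric vector or array.
#' @return numeric object of the same shape.
#' @examples
#' mish(0)        # 0
#' relu6(c(-2, 3, 8))  # 0 3 6
#' @export
mish <- function(x) x * tanh(softplus(x))

#' @rdname mish
#' @export
relu6 <- function(x) pmin(pmax(x, 0), 6)

#' @rdname mish
#' @export
sigmoid <- function(x) 1 / (1 + exp(-x))

#' @rdname mish
#' @export
softplus <- function(x) {
  # numerically stable log(1 + exp(x))
  pmax(x, 0) + log1p(exp(-abs(x)))
}

mish_grad <- function(x) {
  sp <- softplus(x)
  t <- tanh(sp)
  t + x * (1 - t^2) * sigmoid(x)
}

relu6_grad <- function(x) as.numeric(x > 0 & x < 6)

sigmoid_grad_from_y <- function(y) y * (1 - y)

act_fun <- function(name) {
  switch(name,
    mish = mish, relu6 = relu6, sigmoid = sigmoid, linear = identity,
    stopf("unknown activation '%s'", name))
}
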