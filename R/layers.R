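# Minimal layer engine used by the networks.
#
# A "layer" is a plain list with a $kind, learnable arrays in $params,
# non-learnable state in $buffers, and hyperparameters at the top level.
# Batches are numeric arrays with dim = c(H, W, C, N). Forward passes return
# list(y, cache, layer); the layer is returned because batch-norm updates its
# running statistics during training. Backward passes return list(dx, grads)
# with grads mirroring $params (and $sub for composite layers).

new_conv_layer <- function(in_c, out_c, k, stride = 1L, pad = 0L,
                           groups = 1L, bias = FALSE) {
  if (in_c %% groups != 0 || out_c %% groups != 0)
    stopf("channel counts (%d -> %d) not divisible by groups = %d",
          in_c, out_c, groups)
  fan_in <- k * k * in_c / groups
  w <- array(rnorm(k * k * (in_c / groups) * out_c, sd = sqrt(2 / fan_in)),
             dim = c(k, k, in_c / groups, out_c))
  params <- list(w = w)
  if (bias) params$b <- numeric(out_c)
  list(kind = "conv", in_c = in_c, out_c = out_c, k = k, stride = as.integer(stride),
       pad = as.integer(pad), groups = as.integer(groups), bias = bias,
       params = params)
}

new_bn_layer <- function(c, eps = 1e-5, momentum = 0.1) {
  list(kind = "bn", c = c, eps = eps, momentum = momentum,
       params = list(gamma = rep(1, c), beta = numeric(c)),
       buffers = list(mean = numeric(c), var = rep(1, c)))
}

new_act_layer <- function(fun) list(kind = "act", fun = fun, params = list())

new_classifier_layer <- function(in_c, n_classes) {
  list(kind = "classifier", in_c = in_c, n_classes = n_classes,
       params = list(w = matrix(rnorm(in_c * n_classes, sd = sqrt(2 / in_c)),
                                in_c, n_classes),
                     b = numeric(n_classes)))
}

# ---- pooling / resampling helpers (torch-style adaptive windows) ------------

adaptive_bounds <- function(n_in, n_out) {
  lo <- floor((0:(n_out - 1)) * n_in / n_out) + 1
  hi <- ceiling((1:n_out) * n_in / n_out)
  cbind(lo, hi)
}

adaptive_avg_pool_fwd <- function(x, s) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  bh <- adaptive_bounds(H, s); bw <- adaptive_bounds(W, s)
  y <- array(0, dim = c(s, s, C, N))
  for (j in seq_len(s)) for (i in seq_len(s)) {
    blk <- x[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE]
    y[i, j, , ] <- colMeans(matrix(blk, nrow = prod(dim(blk)[1:2])))
  }
  y
}

adaptive_avg_pool_bwd <- function(dy, in_dim) {
  H <- in_dim[1]; W <- in_dim[2]; C <- in_dim[3]; N <- in_dim[4]
  s <- dim(dy)[1]
  bh <- adaptive_bounds(H, s); bw <- adaptive_bounds(W, s)
  dx <- array(0, dim = in_dim)
  for (j in seq_len(s)) for (i in seq_len(s)) {
    nh <- bh[i, 2] - bh[i, 1] + 1L; nw <- bw[j, 2] - bw[j, 1] + 1L
    v <- dy[i, j, , ] / (nh * nw)                     # length C*N
    dx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , ] <-
      dx[bh[i, 1]:bh[i, 2], bw[j, 1]:bw[j, 2], , , drop = FALSE] +
      array(rep(v, each = nh * nw), dim = c(nh, nw, C, N))
  }
  dx
}

upsample_nearest_fwd <- function(g, H, W) {
  s <- dim(g)[1]
  ih <- floor((0:(H - 1)) * s / H) + 1
  iw <- floor((0:(W - 1)) * s / W) + 1
  g[ih, iw, , , drop = FALSE]
}

upsample_nearest_bwd <- function(dY, s) {
  d <- dim(dY); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  ih <- floor((0:(H - 1)) * s / H) + 1
  iw <- floor((0:(W - 1)) * s / W) + 1
  dg <- array(0, dim = c(s, s, C, N))
  hs <- split(seq_len(H), ih); ws <- split(seq_len(W), iw)
  for (j in seq_along(ws)) for (i in seq_along(hs)) {
    blk <- dY[hs[[i]], ws[[j]], , , drop = FALSE]
    dg[as.integer(names(hs)[i]), as.integer(names(ws)[j]), , ] <-
      colSums(matrix(blk, nrow = prod(dim(blk)[1:2])))
  }
  dg
}

# ---- conv -------------------------------------------------------------------

conv_fwd_ <- function(layer, x) {
  .conv2d_fwd(x, dim(x), layer$params$w, dim(layer$params$w),
              if (layer$bias) layer$params$b else numeric(0),
              layer$stride, layer$pad, layer$groups)
}

conv_bwd_ <- function(layer, x, dy) {
  gw <- .conv2d_bwd_weight(x, dim(x), dy, dim(dy), dim(layer$params$w),
                           layer$stride, layer$pad, layer$groups, layer$bias)
  dx <- .conv2d_bwd_input(dy, dim(dy), layer$params$w, dim(layer$params$w),
                          dim(x), layer$stride, layer$pad, layer$groups)
  grads <- list(w = gw$dw)
  if (layer$bias) grads$b <- gw$db
  list(dx = dx, grads = grads)
}

# ---- batch norm -------------------------------------------------------------

bn_fwd_ <- function(layer, x, training) {
  d <- dim(x); C <- d[3]
  xm <- matrix(aperm(x, c(1, 2, 4, 3)), ncol = C)   # rows: (h,w,n), cols: c
  if (training) {
    mu <- colMeans(xm)
    v <- pmax(colMeans(xm^2) - mu^2, 0)   # guard tiny negative cancellation
    mom <- layer$momentum
    layer$buffers$mean <- (1 - mom) * layer$buffers$mean + mom * mu
    layer$buffers$var <- (1 - mom) * layer$buffers$var + mom * v
  } else {
    mu <- layer$buffers$mean
    v <- layer$buffers$var
  }
  invstd <- 1 / sqrt(v + layer$eps)
  xhat <- sweep(xm, 2, mu, "-")
  xhat <- sweep(xhat, 2, invstd, "*")
  ym <- sweep(xhat, 2, layer$params$gamma, "*")
  ym <- sweep(ym, 2, layer$params$beta, "+")
  y <- aperm(array(ym, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(y = y, cache = list(xhat = xhat, invstd = invstd, dims = d,
                           training = training),
       layer = layer)
}

bn_bwd_ <- function(layer, cache, dy) {
  d <- cache$dims; C <- d[3]
  dym <- matrix(aperm(dy, c(1, 2, 4, 3)), ncol = C)
  xhat <- cache$xhat
  dbeta <- colSums(dym)
  dgamma <- colSums(dym * xhat)
  dxhat <- sweep(dym, 2, layer$params$gamma, "*")
  if (cache$training) {
    m <- nrow(dym)
    t1 <- sweep(dxhat, 2, colMeans(dxhat), "-")
    t2 <- sweep(xhat, 2, colMeans(dxhat * xhat), "*")
    dxm <- sweep(t1 - t2, 2, cache$invstd, "*")
  } else {
    dxm <- sweep(dxhat, 2, cache$invstd, "*")
  }
  dx <- aperm(array(dxm, dim = d[c(1, 2, 4, 3)]), c(1, 2, 4, 3))
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# ---- ECA --------------------------------------------------------------------

eca_conv1d <- function(gap, w) {
  # zero-padded correlation across the channel axis; gap is C x N
  C <- nrow(gap); k <- length(w); p <- (k - 1L) %/% 2L
  z <- matrix(0, C, ncol(gap))
  for (j in seq_len(k)) {
    o <- j - p - 1L                               # offset in [-p, p]
    src <- seq_len(C) + o
    ok <- src >= 1 & src <= C
    z[ok, ] <- z[ok, ] + w[j] * gap[src[ok], , drop = FALSE]
  }
  z
}

eca_fwd_ <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  gap <- matrix(colMeans(matrix(x, nrow = HW)), C, N)
  z <- eca_conv1d(gap, layer$params$w)
  omega <- sigmoid(z)
  y <- x * array(rep(omega, each = HW), dim = d)
  list(y = y, cache = list(x = x, gap = gap, omega = omega), layer = layer)
}

eca_bwd_ <- function(layer, cache, dy) {
  x <- cache$x; d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  omega <- cache$omega
  domega <- matrix(colSums(matrix(dy * x, nrow = HW)), C, N)
  dz <- domega * omega * (1 - omega)
  w <- layer$params$w; k <- length(w); p <- (k - 1L) %/% 2L
  dgap <- matrix(0, C, N)
  dw <- numeric(k)
  for (j in seq_len(k)) {
    o <- j - p - 1L
    src <- seq_len(C) + o
    ok <- src >= 1 & src <= C
    dgap[src[ok], ] <- dgap[src[ok], ] + w[j] * dz[ok, , drop = FALSE]
    dw[j] <- sum(dz[ok, , drop = FALSE] * cache$gap[src[ok], , drop = FALSE])
  }
  dx <- dy * array(rep(omega, each = HW), dim = d) +
    array(rep(dgap / HW, each = HW), dim = d)
  list(dx = dx, grads = list(w = dw))
}

# ---- DMS --------------------------------------------------------------------

dms_fwd_ <- function(layer, x) {
  d <- dim(x)
  p <- adaptive_avg_pool_fwd(x, layer$pooled_size)
  cw1 <- layer$sub$conv1; cw2 <- layer$sub$conv2
  a <- conv_fwd_(cw1, p)
  m <- mish(a)
  u <- conv_fwd_(cw2, m)
  g <- sigmoid(u)
  G <- upsample_nearest_fwd(g, d[1], d[2])
  y <- x + x * G
  list(y = y, cache = list(x = x, p = p, a = a, m = m, g = g, G = G, dims = d),
       layer = layer)
}

dms_bwd_ <- function(layer, cache, dy) {
  d <- cache$dims
  dx <- dy * (1 + cache$G)
  dG <- dy * cache$x
  dg <- upsample_nearest_bwd(dG, layer$pooled_size)
  du <- dg * cache$g * (1 - cache$g)
  b2 <- conv_bwd_(layer$sub$conv2, cache$m, du)
  da <- b2$dx * mish_grad(cache$a)
  b1 <- conv_bwd_(layer$sub$conv1, cache$p, da)
  dx <- dx + adaptive_avg_pool_bwd(b1$dx, d)
  list(dx = dx, grads = list(sub = list(conv1 = b1$grads, conv2 = b2$grads)))
}

# ---- classifier (global average pool + linear) ------------------------------

classifier_fwd_ <- function(layer, x) {
  d <- dim(x); HW <- d[1] * d[2]; C <- d[3]; N <- d[4]
  pooled <- matrix(colMeans(matrix(x, nrow = HW)), C, N)
  logits <- crossprod(layer$params$w, pooled) + layer$params$b
  list(y = logits, cache = list(pooled = pooled, dims = d), layer = layer)
}

classifier_bwd_ <- function(layer, cache, dlogits) {
  d <- cache$dims; HW <- d[1] * d[2]
  dW <- cache$pooled %*% t(dlogits)
  db <- rowSums(dlogits)
  dpool <- layer$params$w %*% dlogits
  dx <- array(rep(dpool / HW, each = HW), dim = d)
  list(dx = dx, grads = list(w = dW, b = db))
}

# ---- dispatch ---------------------------------------------------------------

layer_forward <- function(layer, x, training = FALSE) {
  switch(layer$kind,
    conv = list(y = conv_fwd_(layer, x), cache = list(x = x), layer = layer),
    bn = bn_fwd_(layer, x, training),
    act = {
      f <- act_fun(layer$fun)
      list(y = f(x), cache = list(x = x), layer = layer)
    },
    eca = eca_fwd_(layer, x),
    dms = dms_fwd_(layer, x),
    classifier = classifier_fwd_(layer, x),
    bottleneck = bottleneck_fwd_(layer, x, training),
    stopf("unknown layer kind '%s'", layer$kind))
}

layer_backward <- function(layer, cache, dy) {
  switch(layer$kind,
    conv = conv_bwd_(layer, cache$x, dy),
    bn = bn_bwd_(layer, cache, dy),
    act = {
      g <- switch(layer$fun,
        mish = mish_grad(cache$x),
        relu6 = relu6_grad(cache$x),
        sigmoid = { y <- sigmoid(cache$x); y * (1 - y) },
        linear = 1)
      list(dx = dy * g, grads = list())
    },
    eca = eca_bwd_(layer, cache, dy),
    dms = dms_bwd_(layer, cache, dy),
    classifier = classifier_bwd_(layer, cache, dy),
    bottleneck = bottleneck_bwd_(layer, cache, dy),
    stopf("unknown layer kind '%s'", layer$kind))
}

bottleneck_fwd_ <- function(layer, x, training) {
  caches <- vector("list", length(layer$sub))
  h <- x
  for (i in seq_along(layer$sub)) {
    r <- layer_forward(layer$sub[[i]], h, training)
    layer$sub[[i]] <- r$layer
    caches[[i]] <- r$cache
    h <- r$y
  }
  if (layer$use_shortcut) h <- h + x
  list(y = h, cache = list(sub = caches), layer = layer)
}

bottleneck_bwd_ <- function(layer, cache, dy) {
  grads <- vector("list", length(layer$sub))
  names(grads) <- names(layer$sub)
  d <- dy
  for (i in rev(seq_along(layer$sub))) {
    r <- layer_backward(layer$sub[[i]], cache$sub[[i]], d)
    grads[[i]] <- r$grads
    d <- r$dx
  }
  if (layer$use_shortcut) d <- d + dy
  list(dx = d, grads = list(sub = grads))
}

# ---- whole-model passes -----------------------------------------------------

model_forward <- function(model, x, training = FALSE, tap = NULL) {
  caches <- vector("list", length(model$layers))
  tap_out <- NULL
  h <- x
  for (i in seq_along(model$layers)) {
    r <- layer_forward(model$layers[[i]], h, training)
    model$layers[[i]] <- r$layer
    caches[[i]] <- r$cache
    h <- r$y
    if (!is.null(tap) && i == tap) tap_out <- h
  }
  list(out = h, caches = caches, model = model, tap_out = tap_out)
}

model_backward <- function(model, caches, dout, stop_at = 0L) {
  grads <- vector("list", length(model$layers))
  d <- dout
  for (i in rev(seq_along(model$layers))) {
    if (i < stop_at) break
    r <- layer_backward(model$layers[[i]], caches[[i]], d)
    grads[[i]] <- r$grads
    d <- r$dx
  }
  list(grads = grads, dx = d)
}

# Recursive SGD-with-momentum update over the layer tree.
sgd_update_layer <- function(layer, grad, vel, lr, momentum, weight_decay) {
  if (!is.null(layer$params) && length(layer$params) > 0 &&
      !is.null(grad) && length(grad) > 0) {
    for (nm in names(layer$params)) {
      if (is.null(grad[[nm]])) next
      g <- grad[[nm]]
      if (weight_decay > 0) g <- g + weight_decay * layer$params[[nm]]
      v <- momentum * (vel$params[[nm]] %||% 0) + g
      vel$params[[nm]] <- v
      layer$params[[nm]] <- layer$params[[nm]] - lr * v
    }
  }
  if (!is.null(layer$sub) && !is.null(grad$sub)) {
    if (is.null(vel$sub)) vel$sub <- vector("list", length(layer$sub))
    for (i in seq_along(layer$sub)) {
      r <- sgd_update_layer(layer$sub[[i]], grad$sub[[i]],
                            vel$sub[[i]] %||% list(params = list()),
                            lr, momentum, weight_decay)
      layer$sub[[i]] <- r$layer
      vel$sub[[i]] <- r$vel
    }
  }
  list(layer = layer, vel = vel)
}

sgd_update_model <- function(model, grads, state, lr, momentum, weight_decay) {
  if (is.null(state)) state <- vector("list", length(model$layers))
  for (i in seq_along(model$layers)) {
    if (is.null(grads[[i]])) next
    r <- sgd_update_layer(model$layers[[i]], grads[[i]],
                          state[[i]] %||% list(params = list()),
                          lr, momentum, weight_decay)
    model$layers[[i]] <- r$layer
    state[[i]] <- r$vel
  }
  list(model = model, state = state)
}

# Enumerate every learnable scalar in a layer tree (the parameter oracle).
count_layer_params <- function(layer) {
  n <- 0
  if (!is.null(layer$params)) n <- n + sum(vapply(layer$params, length, 0L))
  if (!is.null(layer$sub)) n <- n + sum(vapply(layer$sub, count_layer_params, 0))
  n
}
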