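# Layer primitives over (N, H, W, C) channel-last tensors, each with an
# explicit backward pass.  Forward functions return the output plus the
# cache its backward needs; parameter gradients mirror the parameter list
# structure so the Adam update can walk both trees in lockstep.

conv_out_geom <- function(h, w, kh, kw, stride, padding) {
  if (padding == "same") {
    oh <- ceiling(h / stride); ow <- ceiling(w / stride)
    ph <- max((oh - 1) * stride + kh - h, 0)
    pw <- max((ow - 1) * stride + kw - w, 0)
    list(oh = oh, ow = ow, pt = ph %/% 2, pl = pw %/% 2)
  } else {
    list(oh = (h - kh) %/% stride + 1L, ow = (w - kw) %/% stride + 1L,
         pt = 0L, pl = 0L)
  }
}

conv2d_fwd <- function(x, W, b, stride = 1L, padding = "same", groups = 1L) {
  d <- dim(x); wd <- dim(W)
  g <- conv_out_geom(d[2], d[3], wd[1], wd[2], stride, padding)
  y <- cpp_conv2d(x, W, b, as.integer(stride), g$pt, g$pl,
                  as.integer(g$oh), as.integer(g$ow), as.integer(groups))
  list(y = y, cache = list(x = x, W = W, stride = as.integer(stride),
                           pt = g$pt, pl = g$pl, groups = as.integer(groups)))
}

conv2d_bwd <- function(cache, dy) {
  wd <- dim(cache$W)
  dx <- cpp_conv2d_bwd_x(dy, cache$W, dim(cache$x), cache$stride,
                         cache$pt, cache$pl, cache$groups)
  gw <- cpp_conv2d_bwd_w(cache$x, dy, wd[1], wd[2], cache$stride,
                         cache$pt, cache$pl, cache$groups)
  list(dx = dx, grads = list(W = gw$dw, b = as.numeric(gw$db)))
}

conv_init <- function(kh, kw, cin, cout, groups = 1L) {
  cpg <- cin %/% groups
  list(W = glorot(c(kh, kw, cpg, cout), kh * kw * cpg, cout),
       b = numeric(cout))
}

# 1x1 convolutions are token-wise matrix products; cheaper than im2col.
conv1x1_fwd <- function(x, W, b) {
  d <- dim(x)
  t <- as_tokens(x)
  y <- t %*% W
  y <- sweep(y, 2L, b, `+`)
  list(y = from_tokens(y, c(d[1:3], ncol(W))), cache = list(t = t, W = W, d = d))
}

conv1x1_bwd <- function(cache, dy) {
  dyt <- as_tokens(dy)
  list(dx = from_tokens(dyt %*% t(cache$W), cache$d),
       grads = list(W = crossprod(cache$t, dyt), b = colSums(dyt)))
}

dense_fwd <- function(x, W, b) {
  y <- sweep(x %*% W, 2L, b, `+`)
  list(y = y, cache = list(x = x, W = W))
}

dense_bwd <- function(cache, dy) {
  list(dx = dy %*% t(cache$W),
       grads = list(W = crossprod(cache$x, dy), b = colSums(dy)))
}

dense_init <- function(din, dout) {
  list(W = glorot(c(din, dout), din, dout), b = numeric(dout))
}

relu_fwd <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bwd <- function(cache, dy) dy * cache

sigmoid_fwd <- function(x) { y <- sigmoid(x); list(y = y, cache = y) }
sigmoid_bwd <- function(cache, dy) dy * cache * (1 - cache)

swish_fwd <- function(x) { s <- sigmoid(x); list(y = x * s, cache = list(x = x, s = s)) }
swish_bwd <- function(cache, dy) dy * (cache$s + cache$x * cache$s * (1 - cache$s))

# Batch normalization over the channel axis.  `x` may be rank-2 (N, C) or
# rank-4 (N, H, W, C); rank-4 input is normalized per channel over all of
# (N, H, W).  Inference uses the running moments kept in `state`.
bn_init <- function(c) list(gamma = rep(1, c), beta = numeric(c))
bn_state_init <- function(c) list(mean = numeric(c), var = rep(1, c))

bn_fwd <- function(x, p, state, training = FALSE, eps = 1e-6,
                   momentum = getOption("pneumonet.bn_momentum", 0.9)) {
  d <- dim(x)
  m <- if (length(d) == 4L) as_tokens(x) else x
  if (training) {
    mu <- colMeans(m)
    xc <- sweep(m, 2L, mu, `-`)
    va <- colMeans(xc^2)
    state$mean <- momentum * state$mean + (1 - momentum) * mu
    state$var <- momentum * state$var + (1 - momentum) * va
  } else {
    mu <- state$mean; va <- state$var
    xc <- sweep(m, 2L, mu, `-`)
  }
  inv <- 1 / sqrt(va + eps)
  xhat <- sweep(xc, 2L, inv, `*`)
  y <- sweep(sweep(xhat, 2L, p$gamma, `*`), 2L, p$beta, `+`)
  if (length(d) == 4L) dim(y) <- d
  list(y = y, state = state,
       cache = list(xhat = xhat, inv = inv, gamma = p$gamma,
                    d = d, training = training))
}

bn_bwd <- function(cache, dy) {
  d <- cache$d
  dym <- if (length(d) == 4L) as_tokens(dy) else dy
  dgamma <- colSums(dym * cache$xhat)
  dbeta <- colSums(dym)
  n <- nrow(dym)
  dxhat <- sweep(dym, 2L, cache$gamma, `*`)
  dx <- if (cache$training) {
    # standard batch-norm backward through the batch statistics
    sweep(dxhat - matrix(colMeans(dxhat), n, ncol(dym), byrow = TRUE) -
            cache$xhat * matrix(colMeans(dxhat * cache$xhat), n, ncol(dym),
                                byrow = TRUE),
          2L, cache$inv, `*`)
  } else {
    sweep(dxhat, 2L, cache$inv, `*`)
  }
  if (length(d) == 4L) dim(dx) <- d
  list(dx = dx, grads = list(gamma = dgamma, beta = dbeta))
}

# Inverted dropout; active only in training mode.  Uses the current RNG
# stream (the training loop runs under a fixed seed).
dropout_fwd <- function(x, rate, training = FALSE) {
  if (!training || rate <= 0) {
    return(list(y = x, cache = NULL))
  }
  mask <- array((runif(length(x)) >= rate) / (1 - rate), dim = dim(x) %||% length(x))
  list(y = x * mask, cache = mask)
}

dropout_bwd <- function(cache, dy) if (is.null(cache)) dy else dy * cache

# Global average pooling: (N, H, W, C) -> (N, C).
gap_fwd <- function(x) {
  d <- dim(x)
  y <- colSums(aperm(x, c(2, 3, 1, 4)), dims = 2L) / (d[2] * d[3])
  list(y = y, cache = d)
}

gap_bwd <- function(cache, dy) {
  d <- cache
  aperm(array(dy / (d[2] * d[3]), dim = c(d[1], d[4], d[2], d[3])),
        c(1, 3, 4, 2))
}

maxpool_fwd <- function(x, ksize, stride, padding = "same") {
  d <- dim(x)
  g <- conv_out_geom(d[2], d[3], ksize, ksize, stride, padding)
  cpp_pool2d(x, as.integer(ksize), as.integer(stride), g$pt, g$pl,
             as.integer(g$oh), as.integer(g$ow), "max")
}

avgpool_fwd <- function(x, ksize, stride, padding = "valid") {
  d <- dim(x)
  g <- conv_out_geom(d[2], d[3], ksize, ksize, stride, padding)
  cpp_pool2d(x, as.integer(ksize), as.integer(stride), g$pt, g$pl,
             as.integer(g$oh), as.integer(g$ow), "avg")
}
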