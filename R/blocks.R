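#' Fusion block configuration
#'
#' The fused channel vector from the two backbone branches is projected to
#' `projection_units` units and reshaped to `reshape_target`; config
#' validation enforces `projection_units == prod(reshape_target)` (784 for
#' the default 7 x 7 x 16 target).
#'
#' @param projection_units width of the per-branch dense projections.
#' @param reshape_target `(h, w, c)` shape the fused vector is reshaped to.
#' @param dropout dropout rate used inside the fusion block during
#'   training.
#' @param residual_filters filter count of the residual block that follows
#'   fusion.
#' @return an object of class `fusion_config`.
#' @export
fusion_config <- function(projection_units = 784L, reshape_target = c(7L, 7L, 16L),
                          dropout = 0.2377, residual_filters = 256L) {
  if (projection_units != prod(reshape_target)) {
    stopf("projection_units (%d) must equal prod(reshape_target) (%d)",
          projection_units, prod(reshape_target))
  }
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(projection_units = as.integer(projection_units),
                 reshape_target = as.integer(reshape_target),
                 dropout = dropout,
                 residual_filters = as.integer(residual_filters)),
            class = "fusion_config")
}

# ---- channel attention ------------------------------------------------------

#' @rdname channel_attention
#' @param channels input channel count.
#' @export
init_channel_attention <- function(channels) {
  list(W = glorot(c(channels, channels), channels, channels),
       b = numeric(channels))
}

ca_fwd <- function(x, p) {
  cv <- conv1x1_fwd(x, p$W, p$b)
  sg <- sigmoid_fwd(cv$y)
  list(y = sg$y, cache = list(conv = cv$cache, sg = sg$cache))
}

ca_bwd <- function(cache, dy) {
  ds <- sigmoid_bwd(cache$sg, dy)
  conv1x1_bwd(cache$conv, ds)
}

#' Channel attention map of a feature map
#'
#' A 1x1 convolution with as many output channels as input channels and a
#' sigmoid activation; every entry of the returned map lies in `[0, 1]` and
#' the shape equals the input shape.
#'
#' @param F rank-4 feature map `(batch, h, w, channels)`.
#' @param weights list with `W` (`channels x channels`) and `b`; fresh
#'   Glorot weights are drawn when `NULL`.
#' @return attention map, same shape as `F`, entries in `[0, 1]`.
#' @export
channel_attention <- function(F, weights = NULL) {
  if (length(dim(F)) != 4L) stopf("F must be rank-4")
  if (is.null(weights)) weights <- init_channel_attention(dim(F)[4])
  ca_fwd(F, weights)$y
}

# ---- feature fusion ---------------------------------------------------------

#' @rdname feature_fusion
#' @param channels_eff,channels_dense channel counts of the two branches.
#' @param cfg a [fusion_config()].
#' @export
init_feature_fusion <- function(channels_eff, channels_dense,
                                cfg = fusion_config()) {
  list(att_eff = init_channel_attention(channels_eff),
       att_dense = init_channel_attention(channels_dense),
       proj_eff = dense_init(channels_eff, cfg$projection_units),
       proj_dense = dense_init(channels_dense, cfg$projection_units))
}

# 784-vector -> (N, h, w, c) with the last axis fastest (row-major), the
# documented reshape convention.
reshape_fused_fwd <- function(fused, tgt) {
  n <- nrow(fused)
  tmp <- array(t(fused), c(tgt[3], tgt[2], tgt[1], n))
  aperm(tmp, c(4, 3, 2, 1))
}

reshape_fused_bwd <- function(dy) {
  d <- dim(dy)
  t(matrix(aperm(dy, c(4, 3, 2, 1)), d[2] * d[3] * d[4], d[1]))
}

fusion_fwd <- function(x_e, x_d, p, cfg, training = FALSE) {
  branch <- function(x, att, proj) {
    a <- ca_fwd(x, att)
    m <- x * a$y
    g <- gap_fwd(m)
    dn <- dense_fwd(g$y, proj$W, proj$b)
    r <- relu_fwd(dn$y)
    dr <- dropout_fwd(r$y, cfg$dropout, training)
    list(y = dr$y, a = a, x = x, g = g, dn = dn, r = r, dr = dr,
         multiplied = m)
  }
  be <- branch(x_e, p$att_eff, p$proj_eff)
  bd <- branch(x_d, p$att_dense, p$proj_dense)
  fused <- be$y + bd$y
  y <- reshape_fused_fwd(fused, cfg$reshape_target)
  list(y = y, cache = list(be = be, bd = bd, cfg = cfg))
}

fusion_bwd <- function(p, cache, dy) {
  dfused <- reshape_fused_bwd(dy)
  branch_bwd <- function(br, att, proj, dv) {
    dv <- dropout_bwd(br$dr$cache, dv)
    dv <- relu_bwd(br$r$cache, dv)
    dn <- dense_bwd(br$dn$cache, dv)
    dm <- gap_bwd(br$g$cache, dn$dx)
    dx <- dm * br$a$y
    da <- dm * br$x
    ab <- ca_bwd(br$a$cache, da)
    list(dx = dx + ab$dx, att = ab$grads, proj = dn$grads, d_mult = dm)
  }
  ge <- branch_bwd(cache$be, p$att_eff, p$proj_eff, dfused)
  gd <- branch_bwd(cache$bd, p$att_dense, p$proj_dense, dfused)
  list(dx_e = ge$dx, dx_d = gd$dx,
       d_mult_eff = ge$d_mult, d_mult_dense = gd$d_mult,
       grads = list(att_eff = ge$att, att_dense = gd$att,
                    proj_eff = ge$proj, proj_dense = gd$proj))
}

#' Channel-attention feature fusion of two backbone branches
#'
#' Implements the fusion procedure exactly: each branch is multiplied
#' elementwise by its own channel-attention map, globally average pooled
#' to a channel vector, projected through a ReLU dense layer of
#' `projection_units` units with dropout, the two projections are added,
#' and the sum is reshaped (last axis fastest) to `reshape_target` --
#' `(batch, 7, 7, 16)` under the default configuration.
#'
#' @param F_eff,F_dense rank-4 feature maps from the two branches (channel
#'   counts may differ).
#' @param weights parameters from [init_feature_fusion()]; drawn fresh when
#'   `NULL`.
#' @param cfg a [fusion_config()].
#' @param training apply dropout (training mode) or not (default).
#' @return fused rank-4 feature map of shape `(batch, reshape_target)`.
#' @export
feature_fusion <- function(F_eff, F_dense, weights = NULL,
                           cfg = fusion_config(), training = FALSE) {
  if (length(dim(F_eff)) != 4L || length(dim(F_dense)) != 4L) {
    stopf("both inputs must be rank-4 feature maps")
  }
  if (is.null(weights)) {
    weights <- init_feature_fusion(dim(F_eff)[4], dim(F_dense)[4], cfg)
  }
  fusion_fwd(F_eff, F_dense, weights, cfg, training)$y
}

# Simple fusion bypass used by the ablation: global average pooling of each
# branch ("dimensionality reduction"), concatenation, and a linear-ReLU fit
# to the reshape target so downstream layers are unchanged.
init_simple_fusion <- function(channels_eff, channels_dense, cfg) {
  list(proj = dense_init(channels_eff + channels_dense, cfg$projection_units))
}

simple_fusion_fwd <- function(x_e, x_d, p, cfg) {
  ge <- gap_fwd(x_e); gd <- gap_fwd(x_d)
  cat <- cbind(ge$y, gd$y)
  dn <- dense_fwd(cat, p$proj$W, p$proj$b)
  r <- relu_fwd(dn$y)
  y <- reshape_fused_fwd(r$y, cfg$reshape_target)
  list(y = y, cache = list(ge = ge, gd = gd, dn = dn, r = r,
                           ce = ncol(ge$y), cfg = cfg))
}

simple_fusion_bwd <- function(p, cache, dy) {
  dv <- reshape_fused_bwd(dy)
  dv <- relu_bwd(cache$r$cache, dv)
  dn <- dense_bwd(cache$dn$cache, dv)
  dge <- dn$dx[, seq_len(cache$ce), drop = FALSE]
  dgd <- dn$dx[, -seq_len(cache$ce), drop = FALSE]
  list(dx_e = gap_bwd(cache$ge$cache, dge),
       dx_d = gap_bwd(cache$gd$cache, dgd),
       grads = list(proj = dn$grads))
}

# ---- residual block ---------------------------------------------------------

#' @rdname residual_block
#' @param channels_in input channel count.
#' @param filters convolutional filter count (default 256).
#' @export
init_residual_block <- function(channels_in, filters = 256L) {
  p <- list(conv1 = conv_init(3L, 3L, channels_in, filters),
            bn1 = bn_init(filters),
            conv2 = conv_init(3L, 3L, filters, filters),
            bn2 = bn_init(filters))
  if (channels_in != filters) {
    p$proj <- conv_init(1L, 1L, channels_in, filters)
  }
  p
}

res_state_init <- function(filters) {
  list(bn1 = bn_state_init(filters), bn2 = bn_state_init(filters))
}

res_fwd <- function(x, p, state, training = FALSE) {
  c1 <- conv2d_fwd(x, p$conv1$W, p$conv1$b)
  b1 <- bn_fwd(c1$y, p$bn1, state$bn1, training)
  r1 <- relu_fwd(b1$y)
  c2 <- conv2d_fwd(r1$y, p$conv2$W, p$conv2$b)
  b2 <- bn_fwd(c2$y, p$bn2, state$bn2, training)
  if (is.null(p$proj)) {
    sc <- x; pc <- NULL
  } else {
    pcv <- conv1x1_fwd(x, p$proj$W[1, 1, , ], p$proj$b)
    sc <- pcv$y; pc <- pcv$cache
  }
  rf <- relu_fwd(b2$y + sc)
  state$bn1 <- b1$state; state$bn2 <- b2$state
  list(y = rf$y, state = state, conv1_out = c1$y,
       cache = list(c1 = c1$cache, b1 = b1$cache, r1 = r1$cache,
                    c2 = c2$cache, b2 = b2$cache, proj = pc, rf = rf$cache))
}

res_bwd <- function(p, cache, dy) {
  dsum <- relu_bwd(cache$rf, dy)
  b2 <- bn_bwd(cache$b2, dsum)
  c2 <- conv2d_bwd(cache$c2, b2$dx)
  dr1 <- relu_bwd(cache$r1, c2$dx)
  b1 <- bn_bwd(cache$b1, dr1)
  c1 <- conv2d_bwd(cache$c1, b1$dx)
  g <- list(conv1 = c1$grads, bn1 = b1$grads, conv2 = c2$grads, bn2 = b2$grads)
  if (is.null(cache$proj)) {
    dx <- c1$dx + dsum
  } else {
    pj <- conv1x1_bwd(cache$proj, dsum)
    wd <- dim(pj$grads$W)
    g$proj <- list(W = array(pj$grads$W, c(1L, 1L, wd[1], wd[2])),
                   b = pj$grads$b)
    dx <- c1$dx + pj$dx
  }
  list(dx = dx, grads = g, d_conv1 = b1$dx)
}

#' Residual enhancement block
#'
#' Two 3x3 convolution / batch-norm / ReLU stages with stride 1 and same
#' padding, plus a shortcut connection (identity when the channel counts
#' match, otherwise a 1x1 convolution projection); the output is
#' `ReLU(main path + shortcut)`, so spatial dimensions are preserved and
#' the output is elementwise non-negative.
#'
#' @param F rank-4 feature map.
#' @param weights parameters from [init_residual_block()]; drawn fresh when
#'   `NULL`.
#' @param filters filter count used when initializing fresh weights.
#' @return rank-4 feature map `(batch, h, w, filters)`.
#' @export
residual_block <- function(F, weights = NULL, filters = 256L) {
  if (length(dim(F)) != 4L) stopf("F must be rank-4")
  if (is.null(weights)) weights <- init_residual_block(dim(F)[4], filters)
  nf <- length(weights$bn1$gamma)
  res_fwd(F, weights, res_state_init(nf))$y
}

# ---- attention augmentation -------------------------------------------------

#' @rdname attention_augmentation
#' @param channels channel count of the gated feature map.
#' @export
init_attention_augmentation <- function(channels) {
  list(d1 = dense_init(channels, channels), bn1 = bn_init(channels),
       d2 = dense_init(channels, channels), bn2 = bn_init(channels))
}

aug_state_init <- function(channels) {
  list(bn1 = bn_state_init(channels), bn2 = bn_state_init(channels))
}

aug_fwd <- function(x, p, state, training = FALSE, dropout = 0.2377) {
  d <- dim(x)
  t0 <- as_tokens(x)
  d1 <- dense_fwd(t0, p$d1$W, p$d1$b)
  r1 <- relu_fwd(d1$y)
  b1 <- bn_fwd(r1$y, p$bn1, state$bn1, training)
  dr1 <- dropout_fwd(b1$y, dropout, training)
  d2 <- dense_fwd(dr1$y, p$d2$W, p$d2$b)
  s2 <- sigmoid_fwd(d2$y)
  b2 <- bn_fwd(s2$y, p$bn2, state$bn2, training)
  dr2 <- dropout_fwd(b2$y, dropout, training)
  A <- from_tokens(dr2$y, d)
  state$bn1 <- b1$state; state$bn2 <- b2$state
  list(y = x * A, A = A, state = state,
       cache = list(x = x, A = A, t0 = t0, d1 = d1$cache, r1 = r1$cache,
                    b1 = b1$cache, dr1 = dr1$cache, d2 = d2$cache,
                    s2 = s2$cache, b2 = b2$cache, dr2 = dr2$cache, d = d))
}

aug_bwd <- function(p, cache, dy) {
  dx <- dy * cache$A
  dA <- as_tokens(dy * cache$x)
  dA <- dropout_bwd(cache$dr2, dA)
  b2 <- bn_bwd(cache$b2, dA)
  ds <- sigmoid_bwd(cache$s2, b2$dx)
  d2 <- dense_bwd(cache$d2, ds)
  dh <- dropout_bwd(cache$dr1, d2$dx)
  b1 <- bn_bwd(cache$b1, dh)
  dr <- relu_bwd(cache$r1, b1$dx)
  d1 <- dense_bwd(cache$d1, dr)
  list(dx = dx + from_tokens(d1$dx, cache$d),
       grads = list(d1 = d1$grads, bn1 = b1$grads,
                    d2 = d2$grads, bn2 = b2$grads))
}

#' Attention augmentation (channel-wise gating)
#'
#' Builds a gate from the feature map itself -- dense(channels, ReLU),
#' batch norm, dropout, dense(channels, sigmoid), batch norm, dropout --
#' applied independently at every spatial position along the channel axis,
#' and returns the Hadamard product of the input with the gate.  With the
#' post-gate batch norm at identity the gate lies in `[0, 1]`, so
#' `|output| <= |input|` elementwise.
#'
#' @param F rank-4 feature map.
#' @param weights parameters from [init_attention_augmentation()]; drawn
#'   fresh when `NULL`.
#' @param training training mode (batch statistics + dropout) or inference
#'   (default).
#' @param dropout dropout rate for training mode.
#' @return gated feature map, same shape as `F`.
#' @export
attention_augmentation <- function(F, weights = NULL, training = FALSE,
                                   dropout = 0.2377) {
  if (length(dim(F)) != 4L) stopf("F must be rank-4")
  if (is.null(weights)) weights <- init_attention_augmentation(dim(F)[4])
  aug_fwd(F, weights, aug_state_init(length(weights$bn1$gamma)),
          training, dropout)$y
}

# ---- dynamic attention pooling ---------------------------------------------

#' @rdname dynamic_attention_pooling
#' @param channels input channel count.
#' @export
init_dynamic_pooling <- function(channels) {
  list(W = glorot(c(channels, 1L), channels, 1L), b = 0)
}

pool_fwd <- function(x, p) {
  d <- dim(x)
  t0 <- as_tokens(x)
  z <- t0 %*% p$W + p$b
  sg <- sigmoid_fwd(z)
  Atok <- as.numeric(sg$y)       # one gate value per (n, i, j)
  weighted <- x * Atok           # broadcast across the channel axis
  g <- gap_fwd(weighted)
  list(y = g$y, A = array(Atok, c(d[1:3], 1L)),
       cache = list(x = x, t0 = t0, Atok = Atok, sg = sg$cache, g = g$cache,
                    d = d))
}

pool_bwd <- function(p, cache, dy) {
  dweighted <- gap_bwd(cache$g, dy)
  dx <- dweighted * cache$Atok
  dA <- rowSums(as_tokens(dweighted * cache$x))
  dz <- sigmoid_bwd(cache$sg, matrix(dA, ncol = 1L))
  dx <- dx + from_tokens(dz %*% t(p$W), cache$d)
  list(dx = dx,
       grads = list(W = crossprod(cache$t0, dz), b = sum(dz)))
}

#' Dynamic attention pooling
#'
#' A spatial attention map is produced by a 1x1 convolution to a single
#' channel with sigmoid activation, broadcast across channels, multiplied
#' into the feature map, and the weighted map is globally average pooled.
#' When the gate saturates at 1 this reduces to plain global average
#' pooling.
#'
#' @param F rank-4 feature map.
#' @param weights parameters from [init_dynamic_pooling()]; drawn fresh
#'   when `NULL`.
#' @return matrix `(batch, channels)` of pooled descriptors, with the
#'   spatial gate attached as attribute `"gate"`.
#' @export
dynamic_attention_pooling <- function(F, weights = NULL) {
  if (length(dim(F)) != 4L) stopf("F must be rank-4")
  if (is.null(weights)) weights <- init_dynamic_pooling(dim(F)[4])
  out <- pool_fwd(F, weights)
  y <- out$y
  attr(y, "gate") <- out$A
  y
}

# ---- classifier head --------------------------------------------------------

#' Classifier head configuration
#'
#' Defaults follow the tuned values (dropout 0.2377, L2 coefficient
#' 6.72e-3); the coarser 0.23 / 0.006 sometimes quoted for the same head
#' are the two-significant-figure roundings of these.
#'
#' @param hidden_units width of the hidden dense layer.
#' @param l2_coeff L2 penalty coefficient on the hidden layer's weights.
#' @param dropout dropout rate between batch norm and the output layer.
#' @param n_classes number of output classes.
#' @return an object of class `head_config`.
#' @export
head_config <- function(hidden_units = 128L, l2_coeff = 6.72e-3,
                        dropout = 0.2377, n_classes = 2L) {
  if (hidden_units <= 0) stopf("hidden_units must be positive")
  if (l2_coeff < 0) stopf("l2_coeff must be >= 0")
  if (dropout < 0 || dropout >= 1) stopf("dropout must lie in [0, 1)")
  structure(list(hidden_units = as.integer(hidden_units),
                 l2_coeff = l2_coeff, dropout = dropout,
                 n_classes = as.integer(n_classes)),
            class = "head_config")
}

#' Build the classifier head
#'
#' Dense(`hidden_units`, ReLU, L2-penalized), batch normalization, dropout,
#' Dense(`n_classes`, softmax).
#'
#' @param input_dim dimension of the pooled feature vector fed to the head.
#' @param cfg a [head_config()].
#' @return an object of class `pn_head` (parameters + config).
#' @export
build_head <- function(input_dim, cfg = head_config()) {
  structure(list(
    params = list(d1 = dense_init(input_dim, cfg$hidden_units),
                  bn = bn_init(cfg$hidden_units),
                  d2 = dense_init(cfg$hidden_units, cfg$n_classes)),
    state = list(bn = bn_state_init(cfg$hidden_units)),
    cfg = cfg), class = "pn_head")
}

head_fwd <- function(x, p, state, cfg, training = FALSE) {
  d1 <- dense_fwd(x, p$d1$W, p$d1$b)
  r1 <- relu_fwd(d1$y)
  b1 <- bn_fwd(r1$y, p$bn, state$bn, training)
  dr <- dropout_fwd(b1$y, cfg$dropout, training)
  d2 <- dense_fwd(dr$y, p$d2$W, p$d2$b)
  probs <- softmax_rows(d2$y)
  state$bn <- b1$state
  list(probs = probs, logits = d2$y, state = state,
       cache = list(d1 = d1$cache, r1 = r1$cache, b1 = b1$cache,
                    dr = dr$cache, d2 = d2$cache))
}

head_bwd <- function(p, cache, dlogits, cfg) {
  d2 <- dense_bwd(cache$d2, dlogits)
  dh <- dropout_bwd(cache$dr, d2$dx)
  b1 <- bn_bwd(cache$b1, dh)
  dr <- relu_bwd(cache$r1, b1$dx)
  d1 <- dense_bwd(cache$d1, dr)
  # L2 penalty gradient on the hidden layer weights
  d1$grads$W <- d1$grads$W + 2 * cfg$l2_coeff * p$d1$W
  list(dx = d1$dx, grads = list(d1 = d1$grads, bn = b1$grads, d2 = d2$grads))
}

#' Apply the classifier head to pooled feature vectors
#'
#' @param head a `pn_head` from [build_head()].
#' @param x matrix `(batch, input_dim)` of pooled descriptors.
#' @return matrix `(batch, n_classes)` of class probabilities (rows sum to
#'   one).
#' @export
head_apply <- function(head, x) {
  stopifnot(inherits(head, "pn_head"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  head_fwd(x, head$params, head$state, head$cfg, training = FALSE)$probs
}

#' L2 penalty of a weight matrix
#'
#' @param W numeric weights.
#' @param coeff penalty coefficient.
#' @return `coeff * sum(W^2)`.
#' @export
l2_penalty <- function(W, coeff) coeff * sum(W^2)
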