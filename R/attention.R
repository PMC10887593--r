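#' Attention configuration for the backbone branches
#'
#' @param num_heads number of attention heads (default 4).
#' @param key_dim dimension of the per-head query/key/value projections
#'   (default 128).
#' @return an object of class `attention_config`.
#' @export
attention_config <- function(num_heads = 4L, key_dim = 128L) {
  if (!is_count(num_heads) || num_heads < 1) stopf("num_heads must be >= 1")
  if (!is_count(key_dim) || key_dim < 1) stopf("key_dim must be >= 1")
  structure(list(num_heads = as.integer(num_heads),
                 key_dim = as.integer(key_dim)),
            class = "attention_config")
}

#' Scaled dot-product attention
#'
#' Computes `softmax(Q K' / sqrt(d_k)) V`.  Each row of the softmax weight
#' matrix sums to one.
#'
#' @param Q,K,V numeric matrices; `Q` and `K` must have `d_k` columns and
#'   `K`, `V` the same number of rows.
#' @param d_k key dimension used for the `1/sqrt(d_k)` scaling; defaults to
#'   `ncol(K)`.
#' @return the attended value matrix (`nrow(Q)` x `ncol(V)`), with the
#'   attention weight matrix attached as attribute `"weights"`.
#' @export
scaled_dot_attention <- function(Q, K, V, d_k = ncol(K)) {
  Q <- as.matrix(Q); K <- as.matrix(K); V <- as.matrix(V)
  if (ncol(Q) != ncol(K)) stopf("Q and K must have the same number of columns")
  if (nrow(K) != nrow(V)) stopf("K and V must have the same number of rows")
  P <- softmax_rows(Q %*% t(K) / sqrt(d_k))
  out <- P %*% V
  attr(out, "weights") <- P
  out
}

#' Initialize multi-head self-attention weights for a channel dimension
#'
#' Learned per-head query/key/value projections to `key_dim` plus an output
#' projection back to the channel count, as in the standard transformer
#' multi-head layer.
#'
#' @param channels token feature dimension (the feature-map channel count).
#' @param cfg an [attention_config()].
#' @return parameter list with arrays `Wq`, `Wk`, `Wv`
#'   (`channels x key_dim x num_heads`), biases, and the output projection
#'   `Wo` (`num_heads*key_dim x channels`), `bo`.
#' @export
init_mha_weights <- function(channels, cfg = attention_config()) {
  h <- cfg$num_heads; dk <- cfg$key_dim
  list(
    Wq = glorot(c(channels, dk, h), channels, dk),
    Wk = glorot(c(channels, dk, h), channels, dk),
    Wv = glorot(c(channels, dk, h), channels, dk),
    bq = zeros(c(dk, h)), bk = zeros(c(dk, h)), bv = zeros(c(dk, h)),
    Wo = glorot(c(dk * h, channels), dk * h, channels),
    bo = numeric(channels)
  )
}

mha_fwd <- function(x, p) {
  d <- dim(x)
  n <- d[1]; S <- d[2] * d[3]; C <- d[4]
  h <- dim(p$Wq)[3]; dk <- dim(p$Wq)[2]
  y <- array(0, d)
  caches <- vector("list", n)
  for (b in seq_len(n)) {
    X <- matrix(x[b, , , ], S, C)
    heads <- vector("list", h)
    conc <- matrix(0, S, dk * h)
    for (k in seq_len(h)) {
      Q <- sweep(X %*% p$Wq[, , k], 2L, p$bq[, k], `+`)
      Km <- sweep(X %*% p$Wk[, , k], 2L, p$bk[, k], `+`)
      V <- sweep(X %*% p$Wv[, , k], 2L, p$bv[, k], `+`)
      P <- softmax_rows(Q %*% t(Km) / sqrt(dk))
      H <- P %*% V
      conc[, (k - 1) * dk + seq_len(dk)] <- H
      heads[[k]] <- list(Q = Q, K = Km, V = V, P = P)
    }
    O <- sweep(conc %*% p$Wo, 2L, p$bo, `+`)
    y[b, , , ] <- array(O, d[2:4])
    caches[[b]] <- list(X = X, heads = heads, conc = conc)
  }
  list(y = y, cache = list(d = d, per = caches, dk = dk, h = h))
}

mha_bwd <- function(p, cache, dy) {
  d <- cache$d
  n <- d[1]; S <- d[2] * d[3]; C <- d[4]
  h <- cache$h; dk <- cache$dk
  g <- tree_map(function(a) 0 * a, p)
  dx <- array(0, d)
  for (b in seq_len(n)) {
    cb <- cache$per[[b]]
    dO <- matrix(dy[b, , , ], S, C)
    g$Wo <- g$Wo + crossprod(cb$conc, dO)
    g$bo <- g$bo + colSums(dO)
    dconc <- dO %*% t(p$Wo)
    dX <- matrix(0, S, C)
    for (k in seq_len(h)) {
      hd <- cb$heads[[k]]
      dH <- dconc[, (k - 1) * dk + seq_len(dk), drop = FALSE]
      dP <- dH %*% t(hd$V)
      dV <- crossprod(hd$P, dH)
      # softmax backward, row-wise
      dSc <- hd$P * (dP - rowSums(dP * hd$P))
      dSc <- dSc / sqrt(dk)
      dQ <- dSc %*% hd$K
      dK <- crossprod(dSc, hd$Q)
      g$Wq[, , k] <- g$Wq[, , k] + crossprod(cb$X, dQ)
      g$Wk[, , k] <- g$Wk[, , k] + crossprod(cb$X, dK)
      g$Wv[, , k] <- g$Wv[, , k] + crossprod(cb$X, dV)
      g$bq[, k] <- g$bq[, k] + colSums(dQ)
      g$bk[, k] <- g$bk[, k] + colSums(dK)
      g$bv[, k] <- g$bv[, k] + colSums(dV)
      dX <- dX + dQ %*% t(p$Wq[, , k]) + dK %*% t(p$Wk[, , k]) +
        dV %*% t(p$Wv[, , k])
    }
    dx[b, , , ] <- array(dX, d[2:4])
  }
  list(dx = dx, grads = g)
}

#' Multi-head self-attention over a convolutional feature map
#'
#' The `h x w` spatial positions are flattened into a token sequence whose
#' embeddings are the channel vectors; multi-head self-attention (learned
#' Q/K/V projections per head, concatenation, output projection back to
#' the channel count) is applied and the result reshaped back, so the
#' operation is shape-preserving.  No positional encoding is added, which
#' makes the block permutation-equivariant over spatial tokens.
#'
#' @param F rank-4 feature map `(batch, h, w, channels)`.
#' @param weights parameters from [init_mha_weights()]; when `NULL`, fresh
#'   ones are drawn from the current RNG stream.
#' @param cfg an [attention_config()], used when `weights` is `NULL`.
#' @return feature map with the same shape as `F`.
#' @export
apply_mha_to_map <- function(F, weights = NULL, cfg = attention_config()) {
  if (length(dim(F)) != 4L) stopf("F must be a rank-4 (batch, h, w, channels) array")
  if (is.null(weights)) weights <- init_mha_weights(dim(F)[4], cfg)
  mha_fwd(F, weights)$y
}
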