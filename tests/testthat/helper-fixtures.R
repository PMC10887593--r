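# Shared helpers for the test suite.

# A small synthetic dataset on disk, generated once per test run.
small_dataset <- local({
  cache <- new.env()
  function(image_size = 32, n_train = 10, n_val = 4, n_test = 4, seed = 42,
           blob_sigma = 2) {
    key <- paste(image_size, n_train, n_val, n_test, seed, blob_sigma, sep = "-")
    if (is.null(cache[[key]])) {
      dir <- file.path(tempdir(), paste0("pn-fixture-", key))
      cfg <- synthetic_config(n_train = n_train, n_val = n_val, n_test = n_test,
                              image_size = image_size, blob_sigma = blob_sigma,
                              opacity_count_range = c(2, 4), seed = seed)
      man <- generate_synthetic_dataset(cfg, dir)
      cache[[key]] <- list(dir = dir, manifest = man, cfg = cfg)
    }
    cache[[key]]
  }
})

subset_manifest <- function(man, split) {
  m <- man[man$split == split, , drop = FALSE]
  class(m) <- c("pn_manifest", "data.frame")
  m
}

# Identity-configured batch-norm parameters (unit scale, zero shift) --
# with zero running mean and unit running variance the inference-mode
# block is numerically the identity.
bn_ident_params <- function(c) list(gamma = rep(1, c), beta = numeric(c))

# Pure scalar-loop reference implementations used as independent oracles.
ref_channel_attention <- function(F, W, b) {
  d <- dim(F); A <- array(0, d)
  for (n in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) for (co in 1:d[4]) {
    z <- b[co]
    for (ci in 1:d[4]) z <- z + F[n, i, j, ci] * W[ci, co]
    A[n, i, j, co] <- 1 / (1 + exp(-z))
  }
  A
}

ref_gap <- function(F) {
  d <- dim(F); out <- matrix(0, d[1], d[4])
  for (n in 1:d[1]) for (c in 1:d[4]) out[n, c] <- mean(F[n, , , c])
  out
}

ref_dynamic_pool <- function(F, w, b) {
  d <- dim(F); weighted <- array(0, d)
  for (n in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) {
    z <- b
    for (c in 1:d[4]) z <- z + F[n, i, j, c] * w[c]
    a <- 1 / (1 + exp(-z))
    for (c in 1:d[4]) weighted[n, i, j, c] <- F[n, i, j, c] * a
  }
  ref_gap(weighted)
}

ref_attention_augmentation <- function(F, W1, b1, W2, b2) {
  d <- dim(F); out <- array(0, d)
  for (n in 1:d[1]) for (i in 1:d[2]) for (j in 1:d[3]) {
    v <- F[n, i, j, ]
    h <- pmax(as.numeric(v %*% W1) + b1, 0)
    a <- 1 / (1 + exp(-(as.numeric(h %*% W2) + b2)))
    out[n, i, j, ] <- v * a
  }
  out
}

ref_fusion <- function(Fe, Fd, w, tgt = c(7, 7, 16)) {
  ae <- ref_channel_attention(Fe, w$att_eff$W, w$att_eff$b)
  ad <- ref_channel_attention(Fd, w$att_dense$W, w$att_dense$b)
  ge <- ref_gap(Fe * ae); gd <- ref_gap(Fd * ad)
  he <- pmax(sweep(ge %*% w$proj_eff$W, 2, w$proj_eff$b, `+`), 0)
  hd <- pmax(sweep(gd %*% w$proj_dense$W, 2, w$proj_dense$b, `+`), 0)
  fused <- he + hd
  n <- nrow(fused)
  out <- array(0, c(n, tgt))
  for (b in 1:n) for (i in 1:tgt[1]) for (j in 1:tgt[2]) for (c in 1:tgt[3]) {
    out[b, i, j, c] <- fused[b, c + tgt[3] * (j - 1) + tgt[3] * tgt[2] * (i - 1)]
  }
  out
}

# O(n*m) pairwise AUC oracle.
ref_auc <- function(pos, neg) {
  s <- 0
  for (p in pos) for (q in neg) s <- s + (p > q) + 0.5 * (p == q)
  s / (length(pos) * length(neg))
}
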