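#' Backbone specification for the feature-extraction branches
#'
#' Three backbones are available:
#' \describe{
#'   \item{`efficientnet_b0`}{the published EfficientNet-B0 layer table
#'     (stem, 16 MBConv blocks with squeeze-excitation, 1x1 head conv);
#'     with 224x224x3 input the final convolutional feature map is
#'     7x7x1280 (asserted when the backbone is built).}
#'   \item{`densenet121`}{the published DenseNet-121 layer table (7x7 stem,
#'     dense blocks of 6/12/24/16 layers with growth rate 32, halving
#'     transitions); 224x224x3 input yields a 7x7x1024 map (asserted).}
#'   \item{`tiny_test`}{a compact stack of `stages` stride-2 3x3
#'     convolutions with ReLU (widths 4, 8, 16, then capped at 16), small
#'     enough that the whole classifier trains in seconds on a CPU.  With
#'     `stages = 3` a 32x32 input maps to a 4x4x16 feature map; with
#'     `stages = 5` a 224x224 input maps to 7x7x16.}
#' }
#'
#' Pretrained weights cannot be shipped or downloaded, so
#' `pretrained = TRUE` is rejected; the large backbones build with random
#' (Glorot) weights and run as fixed feature extractors
#' (`trainable = FALSE`), while `tiny_test` supports full gradient
#' training.
#'
#' @param name one of `"efficientnet_b0"`, `"densenet121"`, `"tiny_test"`.
#' @param pretrained must be `FALSE` (no download path exists).
#' @param trainable whether gradients flow into the backbone; defaults to
#'   `TRUE` for `tiny_test` and `FALSE` otherwise.  Only `tiny_test`
#'   implements the backward pass.
#' @param stages number of stride-2 stages for `tiny_test`.
#' @return an object of class `backbone_spec`.
#' @export
backbone_spec <- function(name = c("tiny_test", "efficientnet_b0", "densenet121"),
                          pretrained = FALSE, trainable = NULL, stages = 3L) {
  name <- match.arg(name)
  if (isTRUE(pretrained)) {
    stopf("pretrained weights are not available offline; use pretrained = FALSE")
  }
  trainable <- trainable %||% (name == "tiny_test")
  if (trainable && name != "tiny_test") {
    stopf("backbone '%s' runs as a fixed feature extractor; trainable = TRUE is only supported for tiny_test", name)
  }
  if (!is_count(stages) || stages < 1) stopf("stages must be >= 1")
  structure(list(name = name, pretrained = FALSE, trainable = trainable,
                 stages = as.integer(stages)),
            class = "backbone_spec")
}

tiny_widths <- function(stages) pmin(4L * 2L^(seq_len(stages) - 1L), 16L)

tiny_init <- function(spec, cin = 3L) {
  widths <- tiny_widths(spec$stages)
  params <- vector("list", spec$stages)
  for (i in seq_along(widths)) {
    params[[i]] <- conv_init(3L, 3L, cin, widths[i])
    cin <- widths[i]
  }
  params
}

tiny_fwd <- function(params, x, want_cache = FALSE) {
  caches <- if (want_cache) vector("list", length(params))
  for (i in seq_along(params)) {
    cv <- conv2d_fwd(x, params[[i]]$W, params[[i]]$b, stride = 2L)
    rl <- relu_fwd(cv$y)
    x <- rl$y
    if (want_cache) caches[[i]] <- list(conv = cv$cache, relu = rl$cache)
  }
  list(y = x, cache = caches)
}

tiny_bwd <- function(params, cache, dy) {
  grads <- vector("list", length(params))
  for (i in rev(seq_along(params))) {
    dy <- relu_bwd(cache[[i]]$relu, dy)
    cb <- conv2d_bwd(cache[[i]]$conv, dy)
    grads[[i]] <- cb$grads
    dy <- cb$dx
  }
  list(dx = dy, grads = grads)
}

# ---- EfficientNet-B0 (forward only) ----------------------------------------

effnet_b0_table <- function() {
  # expand ratio, output channels, kernel, stride, repeats
  list(c(1, 16, 3, 1, 1), c(6, 24, 3, 2, 2), c(6, 40, 5, 2, 2),
       c(6, 80, 3, 2, 3), c(6, 112, 5, 1, 3), c(6, 192, 5, 2, 4),
       c(6, 320, 3, 1, 1))
}

mbconv_init <- function(cin, cout, e, k) {
  exp_ch <- cin * e
  se_dim <- max(1L, round(cin / 4))
  p <- list()
  if (e > 1) {
    p$expand <- conv_init(1L, 1L, cin, exp_ch)
    p$bn_e <- bn_init(exp_ch)
  }
  p$dw <- list(W = glorot(c(k, k, 1L, exp_ch), k * k, 1),
               b = numeric(exp_ch))
  p$bn_d <- bn_init(exp_ch)
  p$se_reduce <- dense_init(exp_ch, se_dim)
  p$se_expand <- dense_init(se_dim, exp_ch)
  p$project <- conv_init(1L, 1L, exp_ch, cout)
  p$bn_p <- bn_init(cout)
  p
}

bn_identity <- function(x, p) {
  # random-initialized backbones run with identity moments (mean 0, var 1)
  d <- dim(x); m <- as_tokens(x)
  y <- sweep(sweep(m, 2L, p$gamma / sqrt(1 + 1e-3), `*`), 2L, p$beta, `+`)
  dim(y) <- d
  y
}

mbconv_fwd <- function(p, x, k, s, skip) {
  z <- x
  if (!is.null(p$expand)) {
    z <- bn_identity(conv1x1_fwd(z, p$expand$W[1, 1, , ], p$expand$b)$y, p$bn_e)
    z <- swish_fwd(z)$y
  }
  exp_ch <- dim(z)[4]
  z <- conv2d_fwd(z, p$dw$W, p$dw$b, stride = s, groups = exp_ch)$y
  z <- swish_fwd(bn_identity(z, p$bn_d))$y
  # squeeze-excitation
  sq <- gap_fwd(z)$y
  sq <- swish_fwd(dense_fwd(sq, p$se_reduce$W, p$se_reduce$b)$y)$y
  sq <- sigmoid(dense_fwd(sq, p$se_expand$W, p$se_expand$b)$y)
  d <- dim(z)
  z <- z * aperm(array(sq, c(d[1], d[4], d[2], d[3])), c(1, 3, 4, 2))
  z <- bn_identity(conv1x1_fwd(z, p$project$W[1, 1, , ], p$project$b)$y, p$bn_p)
  if (skip) z <- z + x
  z
}

effnet_init <- function() {
  p <- list(stem = conv_init(3L, 3L, 3L, 32L), bn_s = bn_init(32L),
            blocks = list())
  cin <- 32L
  for (row in effnet_b0_table()) {
    e <- row[1]; cout <- row[2]; k <- row[3]; s <- row[4]; reps <- row[5]
    for (r in seq_len(reps)) {
      p$blocks[[length(p$blocks) + 1L]] <-
        list(p = mbconv_init(cin, cout, e, k), k = k,
             s = if (r == 1L) s else 1L,
             skip = (if (r == 1L) s else 1L) == 1L && cin == cout)
      cin <- cout
    }
  }
  p$head <- conv_init(1L, 1L, cin, 1280L)
  p$bn_h <- bn_init(1280L)
  p
}

effnet_fwd <- function(p, x) {
  z <- conv2d_fwd(x, p$stem$W, p$stem$b, stride = 2L)$y
  z <- swish_fwd(bn_identity(z, p$bn_s))$y
  for (blk in p$blocks) z <- mbconv_fwd(blk$p, z, blk$k, blk$s, blk$skip)
  z <- conv1x1_fwd(z, p$head$W[1, 1, , ], p$head$b)$y
  swish_fwd(bn_identity(z, p$bn_h))$y
}

# ---- DenseNet-121 (forward only) -------------------------------------------

densenet_init <- function(growth = 32L, layers = c(6L, 12L, 24L, 16L)) {
  p <- list(stem = conv_init(7L, 7L, 3L, 64L), bn_s = bn_init(64L),
            blocks = list(), transitions = list())
  ch <- 64L
  for (bi in seq_along(layers)) {
    blk <- list()
    for (li in seq_len(layers[bi])) {
      blk[[li]] <- list(bn1 = bn_init(ch), conv1 = conv_init(1L, 1L, ch, 4L * growth),
                        bn2 = bn_init(4L * growth),
                        conv2 = conv_init(3L, 3L, 4L * growth, growth))
      ch <- ch + growth
    }
    p$blocks[[bi]] <- blk
    if (bi < length(layers)) {
      out <- ch %/% 2L
      p$transitions[[bi]] <- list(bn = bn_init(ch), conv = conv_init(1L, 1L, ch, out))
      ch <- out
    }
  }
  p$bn_f <- bn_init(ch)
  p
}

densenet_fwd <- function(p, x) {
  z <- conv2d_fwd(x, p$stem$W, p$stem$b, stride = 2L)$y
  z <- relu_fwd(bn_identity(z, p$bn_s))$y
  z <- maxpool_fwd(z, 3L, 2L, "same")
  for (bi in seq_along(p$blocks)) {
    for (ly in p$blocks[[bi]]) {
      h <- relu_fwd(bn_identity(z, ly$bn1))$y
      h <- conv1x1_fwd(h, ly$conv1$W[1, 1, , ], ly$conv1$b)$y
      h <- relu_fwd(bn_identity(h, ly$bn2))$y
      h <- conv2d_fwd(h, ly$conv2$W, ly$conv2$b, stride = 1L)$y
      dz <- dim(z)
      z2 <- array(0, c(dz[1:3], dz[4] + dim(h)[4]))
      z2[, , , seq_len(dz[4])] <- z
      z2[, , , dz[4] + seq_len(dim(h)[4])] <- h
      z <- z2
    }
    if (bi <= length(p$transitions)) {
      tr <- p$transitions[[bi]]
      z <- relu_fwd(bn_identity(z, tr$bn))$y
      z <- conv1x1_fwd(z, tr$conv$W[1, 1, , ], tr$conv$b)$y
      z <- avgpool_fwd(z, 2L, 2L, "valid")
    }
  }
  relu_fwd(bn_identity(z, p$bn_f))$y
}

# ---- Shared interface -------------------------------------------------------

backbone_out_channels <- function(spec) {
  switch(spec$name,
         tiny_test = tiny_widths(spec$stages)[spec$stages],
         efficientnet_b0 = 1280L,
         densenet121 = 1024L)
}

#' Build a backbone (initialize weights and assert its output geometry)
#'
#' For `efficientnet_b0` and `densenet121` a forward pass on a dummy
#' 224x224x3 input is run at build time to assert the documented 7x7x1280 /
#' 7x7x1024 output shapes rather than assuming them.
#'
#' @param spec a [backbone_spec()].
#' @param seed integer seed for the weight initialization.
#' @param check run the build-time shape assertion (default `TRUE` for the
#'   large backbones; `tiny_test` geometry is pure arithmetic).
#' @return an object of class `pn_backbone` holding the spec and weights.
#' @export
build_backbone <- function(spec, seed = 0L, check = TRUE) {
  stopifnot(inherits(spec, "backbone_spec"))
  params <- withr::with_seed(seed, switch(spec$name,
    tiny_test = tiny_init(spec),
    efficientnet_b0 = effnet_init(),
    densenet121 = densenet_init()))
  bb <- structure(list(spec = spec, params = params), class = "pn_backbone")
  if (check && spec$name != "tiny_test") {
    out <- extract_features(array(0, c(1L, 224L, 224L, 3L)), bb)
    expect <- c(1L, 7L, 7L, backbone_out_channels(spec))
    if (!identical(dim(out), expect)) {
      stopf("backbone '%s' shape contract violated: got (%s), expected (%s)",
            spec$name, paste(dim(out), collapse = ", "),
            paste(expect, collapse = ", "))
    }
  }
  bb
}

#' Extract the final convolutional feature map of a backbone
#'
#' No global pooling or classifier head is applied; the output is the
#' rank-4 `(batch, h, w, channels)` activation tensor of the last
#' convolutional stage.
#'
#' @param images batch array `(batch, h, w, 3)`; a single `(h, w, 3)` image
#'   is promoted to a batch of one.
#' @param backbone a `pn_backbone` from [build_backbone()], or a
#'   [backbone_spec()] (weights are then drawn with `seed`).
#' @param seed seed used when `backbone` is a bare spec.
#' @return rank-4 feature map.
#' @export
extract_features <- function(images, backbone, seed = 0L) {
  if (inherits(backbone, "backbone_spec")) {
    backbone <- build_backbone(backbone, seed = seed, check = FALSE)
  }
  stopifnot(inherits(backbone, "pn_backbone"))
  if (length(dim(images)) == 3L) {
    images <- array(images, c(1L, dim(images)))
  }
  if (length(dim(images)) != 4L) stopf("images must be a rank-4 batch array")
  switch(backbone$spec$name,
         tiny_test = tiny_fwd(backbone$params, images)$y,
         efficientnet_b0 = effnet_fwd(backbone$params, images),
         densenet121 = densenet_fwd(backbone$params, images))
}
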