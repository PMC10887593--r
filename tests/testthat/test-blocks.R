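test_that("channel attention matches hand-set weights and stays in [0, 1]", {
  # zero weights and biases: sigmoid(0) = 0.5 everywhere
  F <- array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4))
  A <- channel_attention(F, list(W = matrix(0, 4, 4), b = numeric(4)))
  expect_equal(A, array(0.5, dim(F)))
  # a large positive bias saturates the gate towards one
  A <- channel_attention(F, list(W = matrix(0, 4, 4), b = rep(50, 4)))
  expect_true(all(A > 1 - 1e-9))
  # identity-diagonal 1x1 kernel on [3, -3]
  F2 <- array(c(3, -3), c(1, 1, 1, 2))
  A <- channel_attention(F2, list(W = diag(2), b = numeric(2)))
  expect_equal(as.numeric(A), c(1 / (1 + exp(-3)), 1 / (1 + exp(3))),
               tolerance = 1e-6)
  expect_equal(round(as.numeric(A), 4), c(0.9526, 0.0474))
  # sigmoid range invariant under arbitrary random weights
  set.seed(8)
  for (k in 1:5) {
    w <- list(W = matrix(rnorm(16, sd = 3), 4, 4), b = rnorm(4, sd = 3))
    A <- channel_attention(F, w)
    expect_true(all(A >= 0 & A <= 1))
    expect_identical(dim(A), dim(F))
  }
})

test_that("channel attention agrees with a scalar reference implementation", {
  set.seed(9)
  F <- array(rnorm(2 * 3 * 2 * 3), c(2, 3, 2, 3))
  w <- list(W = matrix(rnorm(9), 3, 3), b = rnorm(3))
  expect_equal(channel_attention(F, w), ref_channel_attention(F, w$W, w$b),
               tolerance = 1e-6)
})

test_that("feature fusion follows the five-step procedure exactly", {
  cfg <- fusion_config()
  # hand-traced example: 1x1x1 branches with values 2 and 4, attention 0.5,
  # all-ones projections -> every fused unit is 1.0 + 2.0 = 3.0
  w <- list(att_eff = list(W = matrix(0, 1, 1), b = 0),
            att_dense = list(W = matrix(0, 1, 1), b = 0),
            proj_eff = list(W = matrix(1, 1, 784), b = numeric(784)),
            proj_dense = list(W = matrix(1, 1, 784), b = numeric(784)))
  y <- feature_fusion(array(2, c(1, 1, 1, 1)), array(4, c(1, 1, 1, 1)), w, cfg)
  expect_identical(dim(y), c(1L, 7L, 7L, 16L))
  expect_equal(as.numeric(y), rep(3, 784), tolerance = 1e-9)
  # zeros propagate through every linear stage
  w0 <- withr::with_seed(1, init_feature_fusion(3, 5, cfg))
  w0$att_eff$b[] <- 0; w0$att_dense$b[] <- 0
  w0$proj_eff$b[] <- 0; w0$proj_dense$b[] <- 0
  y0 <- feature_fusion(array(0, c(2, 4, 4, 3)), array(0, c(2, 6, 6, 5)), w0, cfg)
  expect_equal(y0, array(0, c(2, 7, 7, 16)))
  # output shape holds for differing branch channel counts and spatial sizes
  yr <- feature_fusion(array(rnorm(96), c(2, 4, 4, 3)),
                       array(rnorm(360), c(2, 6, 6, 5)), w0, cfg)
  expect_identical(dim(yr), c(2L, 7L, 7L, 16L))
})

test_that("fusion config validation enforces the projection/reshape identity", {
  expect_error(fusion_config(projection_units = 700), "must equal")
  expect_equal(fusion_config()$projection_units, 784L)
})

test_that("feature fusion agrees with a scalar reference implementation", {
  set.seed(10)
  cfg <- fusion_config()
  w <- init_feature_fusion(3, 4, cfg)
  Fe <- array(rnorm(2 * 3 * 3 * 3), c(2, 3, 3, 3))
  Fd <- array(rnorm(2 * 2 * 5 * 4), c(2, 2, 5, 4))
  expect_equal(feature_fusion(Fe, Fd, w, cfg), ref_fusion(Fe, Fd, w),
               tolerance = 1e-6)
})

test_that("residual block is identity under zero convolutions and preserves geometry", {
  # zero conv weights, identity batch norm, matching channels
  w <- init_residual_block(16L, filters = 16L)
  w$conv1$W[] <- 0; w$conv1$b[] <- 0
  w$conv2$W[] <- 0; w$conv2$b[] <- 0
  x <- array(runif(1 * 5 * 5 * 16), c(1, 5, 5, 16))  # non-negative input
  expect_equal(residual_block(x, w), x, tolerance = 1e-5)
  # the published configuration: (1, 7, 7, 16) -> (1, 7, 7, 256)
  set.seed(11)
  w256 <- init_residual_block(16L, filters = 256L)
  y <- residual_block(array(rnorm(784), c(1, 7, 7, 16)), w256)
  expect_identical(dim(y), c(1L, 7L, 7L, 256L))
  # final ReLU: output is non-negative always
  expect_true(all(y >= 0))
  for (k in 1:3) {
    wr <- init_residual_block(4L, filters = 8L)
    yr <- residual_block(array(rnorm(2 * 3 * 3 * 4), c(2, 3, 3, 4)), wr)
    expect_true(all(yr >= 0))
  }
})

test_that("attention augmentation gates channels per spatial position", {
  # identity dense weights, identity batch norm: ReLU then sigmoid by hand
  w <- list(d1 = list(W = diag(2), b = numeric(2)), bn1 = bn_ident_params(2),
            d2 = list(W = diag(2), b = numeric(2)), bn2 = bn_ident_params(2))
  y <- attention_augmentation(array(c(1, -1), c(1, 1, 1, 2)), w)
  sig <- function(z) 1 / (1 + exp(-z))
  expect_equal(as.numeric(y), c(1 * sig(1), -1 * sig(0)), tolerance = 1e-6)
  expect_equal(round(as.numeric(y), 4), c(0.7311, -0.5))
  # |output| <= |input| elementwise when the post-gate batch norm is identity
  set.seed(12)
  for (k in 1:5) {
    C <- 3
    wr <- init_attention_augmentation(C)
    x <- array(rnorm(2 * 4 * 4 * C), c(2, 4, 4, C))
    yr <- attention_augmentation(x, wr)
    expect_true(all(abs(yr) <= abs(x) + 1e-12))
  }
  # zero input maps to zero output
  w0 <- init_attention_augmentation(3)
  expect_equal(attention_augmentation(array(0, c(1, 2, 2, 3)), w0),
               array(0, c(1, 2, 2, 3)))
})

test_that("attention augmentation agrees with a scalar reference implementation", {
  set.seed(13)
  C <- 3
  w <- init_attention_augmentation(C)
  x <- array(rnorm(2 * 3 * 2 * C), c(2, 3, 2, C))
  expect_equal(attention_augmentation(x, w),
               ref_attention_augmentation(x, w$d1$W, w$d1$b, w$d2$W, w$d2$b),
               tolerance = 1e-6)
})

test_that("dynamic attention pooling gates space then averages", {
  # zero conv: gate 0.5 everywhere; [[1,2],[3,4]] pools to 1.25
  F <- array(0, c(1, 2, 2, 1))
  F[1, 1, 1, 1] <- 1; F[1, 1, 2, 1] <- 2; F[1, 2, 1, 1] <- 3; F[1, 2, 2, 1] <- 4
  y <- dynamic_attention_pooling(F, list(W = matrix(0, 1, 1), b = 0))
  expect_equal(as.numeric(y), 1.25, tolerance = 1e-9)
  # saturated gate reduces to plain global average pooling
  set.seed(14)
  x <- array(rnorm(2 * 4 * 4 * 3), c(2, 4, 4, 3))
  ysat <- dynamic_attention_pooling(x, list(W = matrix(0, 3, 1), b = 100))
  expect_equal(unclass(ysat), ref_gap(x), ignore_attr = TRUE, tolerance = 1e-9)
  # zero input gives the zero vector
  y0 <- dynamic_attention_pooling(array(0, c(1, 3, 3, 2)),
                                  list(W = matrix(1, 2, 1), b = 0))
  expect_equal(as.numeric(y0), c(0, 0))
  # gate entries always lie in [0, 1]
  w <- init_dynamic_pooling(3)
  g <- attr(dynamic_attention_pooling(x, w), "gate")
  expect_true(all(g >= 0 & g <= 1))
})

test_that("dynamic pooling agrees with a scalar reference implementation", {
  set.seed(15)
  x <- array(rnorm(2 * 3 * 4 * 3), c(2, 3, 4, 3))
  w <- init_dynamic_pooling(3)
  expect_equal(unclass(dynamic_attention_pooling(x, w)),
               ref_dynamic_pool(x, as.numeric(w$W), w$b),
               ignore_attr = TRUE, tolerance = 1e-6)
})

test_that("the classifier head emits normalized probabilities", {
  set.seed(16)
  hd <- build_head(10L)
  x <- matrix(rnorm(30), 3, 10)
  p <- head_apply(hd, x)
  expect_identical(dim(p), c(3L, 2L))
  expect_true(all(p >= 0))
  expect_equal(rowSums(p), rep(1, 3), tolerance = 1e-6)
  # zero weights give the symmetric prediction
  hd0 <- build_head(10L)
  hd0$params$d1$W[] <- 0; hd0$params$d1$b[] <- 0
  hd0$params$d2$W[] <- 0; hd0$params$d2$b[] <- 0
  expect_equal(head_apply(hd0, x), matrix(0.5, 3, 2))
})

test_that("the L2 penalty is coeff times the squared weight sum", {
  expect_equal(l2_penalty(2.0, 0.006), 0.024)
  W <- matrix(c(1, -2, 3), 1)
  expect_equal(l2_penalty(W, 0.1), 1.4)
})

test_that("head config defaults carry the tuned values with valid bounds", {
  cfg <- head_config()
  expect_equal(cfg$hidden_units, 128L)
  expect_equal(cfg$l2_coeff, 6.72e-3)
  expect_equal(cfg$dropout, 0.2377)
  expect_error(head_config(dropout = 1), "dropout")
  expect_error(head_config(l2_coeff = -1), "l2_coeff")
})
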