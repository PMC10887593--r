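tiny2 <- c("tiny_test", "tiny_test")

test_that("the assembled model maps an image batch to a probability pair", {
  m <- assemble_model(backbones = tiny2, input_size = 32L, seed = 1)
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  p <- model_predict(m, x)
  expect_identical(dim(p), c(2L, 2L))
  expect_identical(colnames(p), c("normal", "pneumonia"))
  expect_equal(rowSums(p), rep(1, 2), tolerance = 1e-6)
  expect_true(all(p >= 0))
})

test_that("removing all components reduces to GAP-concat of backbone features plus head", {
  specs <- list(backbone_spec("tiny_test", stages = 3L),
                backbone_spec("tiny_test", stages = 3L))
  m0 <- assemble_model(backbones = specs, input_size = 32L, seed = 1,
                       components = list(feature_fusion = FALSE,
                                         attention_augmentation = FALSE,
                                         dynamic_pooling = FALSE,
                                         multi_head_attention = FALSE))
  expect_true(m0$all_off)
  # head takes the concatenated 16+16 backbone channel means directly
  expect_identical(dim(m0$params$head$d1$W), c(32L, 128L))
  expect_null(m0$params$res)
  expect_null(m0$params$fusion)
  x <- array(runif(32 * 32 * 3), c(1, 32, 32, 3))
  p <- model_predict(m0, x)
  expect_equal(sum(p), 1, tolerance = 1e-6)
})

test_that("turning any single component off strictly reduces the parameter count", {
  full <- n_params(assemble_model(backbones = tiny2, input_size = 32L, seed = 1))
  for (flag in c("feature_fusion", "attention_augmentation",
                 "dynamic_pooling", "multi_head_attention")) {
    comp <- setNames(list(FALSE), flag)
    m <- assemble_model(backbones = tiny2, input_size = 32L, seed = 1,
                        components = comp)
    expect_lt(n_params(m), full)
  }
})

test_that("checkpoint save/load round-trips to bit-identical forward outputs", {
  m <- assemble_model(backbones = tiny2, input_size = 32L, seed = 2)
  x <- array(runif(2 * 32 * 32 * 3), c(2, 32, 32, 3))
  p1 <- model_predict(m, x)
  ck <- file.path(tempdir(), "ck.rds")
  save_checkpoint(m, ck)
  m2 <- load_checkpoint(ck)
  p2 <- model_predict(m2, x)
  expect_identical(p1, p2)
})

test_that("backpropagated gradients match finite differences across every block", {
  set.seed(20)
  m <- assemble_model(backbones = tiny2, input_size = 16L, seed = 5,
                      head = head_config(dropout = 0),
                      fusion = fusion_config(dropout = 0))
  x <- array(runif(2 * 16 * 16 * 3), c(2, 16, 16, 3))
  y <- matrix(c(1, 0, 0, 1), 2, 2)
  w <- c(1.5, 0.5)
  loss_of <- function(model) {
    f <- model_forward(model, x, training = FALSE)
    pneumonet:::weighted_ce(f$probs, y, w)$loss
  }
  f0 <- model_forward(m, x, training = FALSE)
  lo <- pneumonet:::weighted_ce(f0$probs, y, w)
  bw <- model_backward(m, f0, lo$dlogits)
  eps <- 1e-5
  paths <- list(c("head", "d2", "W"), c("pool", "W"), c("aug", "d1", "W"),
                c("res", "conv2", "W"), c("fusion", "proj_dense", "W"),
                c("fusion", "att_eff", "W"), c("mha_eff", "Wk"),
                c("mha_dense", "Wv"))
  for (pth in paths) {
    g <- bw$grads; p <- m$params
    for (k in pth) { g <- g[[k]]; p <- p[[k]] }
    i <- sample(length(p), 1)
    bump <- function(v) {
      m2 <- m
      node <- paste0("m2$params", paste0("[['", pth, "']]", collapse = ""))
      eval(parse(text = paste0(node, "[", i, "] <- ", v)))
      m2
    }
    num <- (loss_of(bump(p[i] + eps)) - loss_of(bump(p[i] - eps))) / (2 * eps)
    # head_bwd folds the L2 penalty gradient into d1 only; none of the
    # sampled paths carry a penalty term
    expect_lt(abs(num - g[i]), 1e-6)
  }
})

test_that("forward/backward exposes the named activation registry", {
  m <- assemble_model(backbones = tiny2, input_size = 32L, seed = 1)
  x <- array(runif(32 * 32 * 3), c(1, 32, 32, 3))
  f <- model_forward(m, x, training = FALSE)
  expect_true(all(c("backbone_eff", "mha_dense", "fusion_multiply_eff",
                    "fusion_reshape", "post_reshape_conv", "residual_out",
                    "augment_out") %in% names(f$acts)))
  expect_identical(dim(f$acts$fusion_reshape), c(1L, 7L, 7L, 16L))
  expect_identical(dim(f$acts$post_reshape_conv), c(1L, 7L, 7L, 256L))
})

test_that("run configuration reading merges YAML over the tuned defaults", {
  y <- file.path(tempdir(), "run.yaml")
  writeLines(c("model:",
               "  backbones: [tiny_test, tiny_test]",
               "training:",
               "  epochs: 2"), y)
  cfg <- read_run_config(y)
  expect_equal(cfg$model$backbones, c("tiny_test", "tiny_test"))
  expect_equal(cfg$training$epochs, 2L)
  expect_equal(cfg$training$peak_lr, 7.47e-5)   # untouched default
  expect_equal(cfg$model$dropout, 0.2377)
  writeLines("nonsense: 1", y)
  expect_error(read_run_config(y), "unknown config section")
})
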