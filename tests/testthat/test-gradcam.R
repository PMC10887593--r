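gradcam_model <- function(seed = 1) {
  assemble_model(backbones = c("tiny_test", "tiny_test"), input_size = 32L,
                 seed = seed)
}

test_that("heatmaps are normalized to [0, 1] at input resolution", {
  m <- gradcam_model()
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  for (layer in c("post_reshape_conv", "fusion_reshape", "residual_out")) {
    h <- gradcam(m, img, layer)
    expect_s3_class(h, "pn_gradcam")
    expect_identical(dim(h$heatmap), c(32L, 32L))
    expect_true(all(h$heatmap >= 0 & h$heatmap <= 1))
    expect_true(all(h$raw_map >= 0))
  }
})

test_that("a class score with zero gradients yields the all-zero heatmap", {
  m <- gradcam_model()
  # constant logits: zero out the output layer
  m$params$head$d2$W[] <- 0
  m$params$head$d2$b[] <- 0
  h <- gradcam(m, array(runif(32 * 32 * 3), c(32, 32, 3)), "post_reshape_conv")
  expect_equal(max(abs(h$heatmap)), 0)
  expect_equal(max(abs(h$raw_map)), 0)
})

test_that("channel weights are the spatial means of the layer gradient", {
  # alpha_k * (h*w) must equal d(score)/d(bias_k) of the first post-reshape
  # convolution, because that bias shifts every spatial position of channel k
  m <- gradcam_model(seed = 3)
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  x <- array(img, c(1, 32, 32, 3))
  fwd <- model_forward(m, x, training = FALSE)
  dl <- matrix(c(0, 1), 1)  # pneumonia logit
  bw <- model_backward(m, fwd, dl, act_grads = "post_reshape_conv")
  dA <- bw$act_grads$post_reshape_conv
  alpha <- apply(array(dA[1, , , ], dim(dA)[2:4]), 3, mean)
  eps <- 1e-5
  for (k in sample(256, 3)) {
    mp <- m; mp$params$res$conv1$b[k] <- mp$params$res$conv1$b[k] + eps
    mm <- m; mm$params$res$conv1$b[k] <- mm$params$res$conv1$b[k] - eps
    sp <- model_forward(mp, x, training = FALSE)$logits[1, 2]
    sm <- model_forward(mm, x, training = FALSE)$logits[1, 2]
    expect_equal(alpha[k] * 49, (sp - sm) / (2 * eps), tolerance = 1e-4)
  }
})

test_that("pre-fusion multiply layers and the post-reshape layer are addressable", {
  m <- gradcam_model()
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  h1 <- gradcam(m, img, "fusion_multiply_eff")
  h2 <- gradcam(m, img, "fusion_multiply_dense")
  h3 <- gradcam(m, img, "post_reshape_conv")
  expect_identical(h1$layer_name, "fusion_multiply_eff")
  expect_identical(dim(h2$heatmap), c(32L, 32L))
  expect_identical(h3$layer_name, "post_reshape_conv")
})

test_that("unknown layers and non-spatial targets are contract errors", {
  m <- gradcam_model()
  img <- array(runif(32 * 32 * 3), c(32, 32, 3))
  expect_error(gradcam(m, img, "no_such_layer"), "unknown layer")
  expect_error(gradcam(m, img, "post_reshape_conv", target_class = "flu"),
               "unknown class")
})

test_that("heatmap mass concentrates on the planted opacities of true positives", {
  # Train a small model and compare mean heatmap values inside the planted
  # blob disks against outside, over >= 20 correctly-classified pneumonia
  # images.  The check runs on the pre-fusion multiplication layer, which
  # retains spatial correspondence with the input (the post-reshape layers
  # mix positions through GAP + dense + reshape), and without histogram
  # equalization so the opacities keep their direct brightness cue.
  dir <- file.path(tempdir(), "pn-gradcam-data")
  cfg <- synthetic_config(n_train = 40, n_val = 2, n_test = 2,
                          image_size = 64, blob_sigma = 3,
                          opacity_count_range = c(2, 4), seed = 31)
  man <- generate_synthetic_dataset(cfg, dir)
  tr <- subset_manifest(man, "train")
  pre <- preprocess_config(target_size = c(64, 64), equalize = FALSE)
  m <- assemble_model(backbones = c("tiny_test", "tiny_test"),
                      input_size = 64L, seed = 1)
  res <- train_model(m, tr,
                     training_config(epochs = 4, seed = 1, peak_lr = 3e-3,
                                     augment = FALSE),
                     pre_cfg = pre)
  blobs <- read.csv(file.path(dir, "blob_truth.csv"))
  pneu <- tr[tr$label == "pneumonia", ]
  inside_wins <- 0L; n_used <- 0L
  xs <- matrix(rep(seq_len(64), each = 64), 64)
  ys <- matrix(rep(seq_len(64), times = 64), 64)
  for (p in pneu$path) {
    if (n_used >= 24) break
    arr <- preprocess_image(p, pre)
    pr <- model_predict(res$model, array(arr, c(1, 64, 64, 3)))
    if (pr[1, "pneumonia"] <= 0.5) next  # true positives only
    h <- gradcam(res$model, arr, "fusion_multiply_eff")$heatmap
    b <- blobs[blobs$path == p, ]
    mask <- matrix(FALSE, 64, 64)
    for (r in seq_len(nrow(b))) {
      mask <- mask | ((xs - b$x[r])^2 + (ys - b$y[r])^2 <= (2 * b$sigma[r])^2)
    }
    if (!any(mask) || all(mask)) next
    n_used <- n_used + 1L
    inside_wins <- inside_wins + (mean(h[mask]) > mean(h[!mask]))
  }
  expect_gte(n_used, 20L)
  expect_gt(inside_wins / n_used, 0.5)
})
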