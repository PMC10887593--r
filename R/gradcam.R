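#' Grad-CAM heatmap for a named internal layer
#'
#' Computes the gradient of the target class score (pre-softmax logit)
#' with respect to the chosen rank-4 activation, averages it spatially to
#' per-channel weights, forms the ReLU of the weighted channel sum,
#' min--max normalizes to `[0, 1]` (a constant map is defined as all zeros)
#' and bilinearly upsamples to the input resolution.
#'
#' Addressable layers are the named activations the model registers:
#' `backbone_eff`, `backbone_dense`, `mha_eff`, `mha_dense`,
#' `fusion_multiply_eff`, `fusion_multiply_dense`, `fusion_reshape`,
#' `post_reshape_conv` (the first convolutional layer following the
#' fusion reshape), `residual_out`, `augment_out` -- so both the
#' pre-fusion multiplication layers and the post-reshape convolution can
#' be compared.
#'
#' @param model a `pn_model` or fitted [pneumonet()] object.
#' @param image a preprocessed `(h, w, 3)` array in `[0, 1]`, a grayscale
#'   matrix in `[0, 255]`, or a file path.
#' @param layer_name one of the registered layer names above.
#' @param target_class class whose score is explained (default
#'   `"pneumonia"`).
#' @return an object of class `pn_gradcam`: list with `heatmap`
#'   (input-resolution matrix in `[0, 1]`), `raw_map` (pre-upsampling
#'   weighted map), `layer_name`, `target_class` and the normalization
#'   `bounds`.
#' @export
gradcam <- function(model, image, layer_name, target_class = "pneumonia") {
  if (inherits(model, "pneumonet")) model <- model$model
  stopifnot(inherits(model, "pn_model"))
  if (is.character(image) || is.matrix(image)) {
    image <- preprocess_image(image, preprocess_config(
      target_size = c(model$input_size, model$input_size)))
  }
  if (length(dim(image)) == 3L) image <- array(image, c(1L, dim(image)))
  cls <- match(target_class, model$classes)
  if (is.na(cls)) stopf("unknown class '%s'", target_class)

  fwd <- model_forward(model, image, training = FALSE)
  if (!layer_name %in% names(fwd$acts)) {
    stopf("unknown layer '%s'; available: %s", layer_name,
          paste(names(fwd$acts), collapse = ", "))
  }
  A <- fwd$acts[[layer_name]]
  if (length(dim(A)) != 4L) {
    stopf("layer '%s' is not a rank-4 activation", layer_name)
  }
  dlogits <- matrix(0, 1L, length(model$classes))
  dlogits[1L, cls] <- 1
  bwd <- model_backward(model, fwd, dlogits, act_grads = layer_name)
  dA <- bwd$act_grads[[layer_name]]
  if (is.null(dA)) {
    stopf("no gradient reaches layer '%s' in this configuration", layer_name)
  }

  A1 <- array(A[1L, , , ], dim(A)[2:4])
  dA1 <- array(dA[1L, , , ], dim(A)[2:4])
  alpha <- apply(dA1, 3L, mean)                      # spatial-mean weights
  raw <- array(0, dim(A)[2:3])
  for (k in seq_along(alpha)) raw <- raw + alpha[k] * A1[, , k]
  raw <- pmax(raw, 0)
  lo <- min(raw); hi <- max(raw)
  norm <- if (hi > lo) (raw - lo) / (hi - lo) else array(0, dim(raw))
  heat <- resize_bilinear(norm, dim(image)[2], dim(image)[3])
  structure(list(heatmap = heat, raw_map = raw, layer_name = layer_name,
                 target_class = target_class, bounds = c(lo, hi)),
            class = "pn_gradcam")
}

#' @export
plot.pn_gradcam <- function(x, ...) {
  graphics::image(t(x$heatmap)[, nrow(x$heatmap):1], axes = FALSE,
                  col = grDevices::hcl.colors(64, "inferno"),
                  main = sprintf("Grad-CAM: %s (%s)", x$layer_name,
                                 x$target_class), ...)
  invisible(x)
}
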