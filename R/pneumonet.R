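#' Fit the attention-ensemble pneumonia classifier
#'
#' The main entry point: assembles the dual-backbone model described by
#' `config`, trains it with class-weighted categorical cross-entropy under
#' the warmup Adam schedule, and returns a fitted object with `print`,
#' `summary`, `predict` and `plot` methods.
#'
#' @param train training data: a `pn_manifest` or a split directory with
#'   `normal/` and `pneumonia/` subdirectories.
#' @param val optional validation data (manifest or directory); per-epoch
#'   validation accuracy is recorded when given.
#' @param config a [pn_config()].
#' @param seed integer seed controlling weight initialization, shuffling,
#'   dropout and augmentation.
#' @param verbose print per-epoch progress.
#' @return an object of class `pneumonet`.
#' @export
#' @examples
#' \donttest{
#' ds <- file.path(tempdir(), "pn-demo")
#' man <- generate_synthetic_dataset(
#'   synthetic_config(n_train = 12, n_val = 4, n_test = 4,
#'                    image_size = 32, blob_sigma = 2, seed = 1), ds)
#' cfg <- pn_config(model = list(backbones = c("tiny_test", "tiny_test")),
#'                  preprocess = list(target_size = c(32L, 32L)),
#'                  training = list(epochs = 1L))
#' fit <- pneumonet(file.path(ds, "train"), config = cfg, seed = 1)
#' predict(fit, file.path(ds, "test"))
#' }
pneumonet <- function(train, val = NULL, config = pn_config(), seed = 1L,
                      verbose = FALSE) {
  if (is.character(train)) train <- load_image_directory(train)
  if (is.character(val)) val <- load_image_directory(val)
  obj <- config_objects(config)
  input_size <- obj$pre$target_size[1]
  model <- assemble_model(backbones = config$model$backbones,
                          attention = obj$attention, fusion = obj$fusion,
                          head = obj$head,
                          components = config$model$components,
                          input_size = input_size, seed = seed)
  tc <- obj$train
  tc$seed <- as.integer(seed)
  res <- train_model(model, train, cfg = tc, val_manifest = val,
                     pre_cfg = obj$pre, aug_cfg = obj$aug, verbose = verbose)
  structure(list(model = res$model, history = res$history, config = config,
                 classes = res$model$classes, seed = as.integer(seed),
                 n_train = nrow(train), call = match.call()),
            class = "pneumonet")
}

#' @export
print.pneumonet <- function(x, ...) {
  cat("Fitted pneumonet classifier\n")
  print(x$model)
  h <- x$history
  cat(sprintf("  trained %d epochs on %d images; final loss %.4f, accuracy %.3f\n",
              nrow(h), x$n_train, h$loss[nrow(h)], h$accuracy[nrow(h)]))
  if (!is.null(h$val_accuracy)) {
    cat(sprintf("  final validation accuracy %.3f\n", h$val_accuracy[nrow(h)]))
  }
  invisible(x)
}

#' @export
summary.pneumonet <- function(object, ...) {
  print(object)
  cat("\nTraining history:\n")
  print(object$history, row.names = FALSE)
  invisible(object)
}

#' Predict class probabilities or labels
#'
#' @param object a fitted [pneumonet()] object.
#' @param newdata a `pn_manifest`, a split directory, a preprocessed
#'   `(batch, h, w, 3)` array, or a single image path.
#' @param type `"prob"` for class probabilities (default) or `"class"`
#'   for hard labels.
#' @param ... unused.
#' @return probability matrix with one column per class, or a character
#'   vector of labels.
#' @export
predict.pneumonet <- function(object, newdata, type = c("prob", "class"), ...) {
  type <- match.arg(type)
  pre <- config_objects(object$config)$pre
  x <- if (is.character(newdata) && length(newdata) == 1L && dir.exists(newdata)) {
    manifest_to_array(load_image_directory(newdata), pre)
  } else if (is.character(newdata)) {
    array(preprocess_image(newdata, pre), c(1L, pre$target_size, 3L))
  } else if (inherits(newdata, "pn_manifest")) {
    manifest_to_array(newdata, pre)
  } else {
    newdata
  }
  probs <- model_predict(object$model, x)
  if (type == "prob") probs else colnames(probs)[max.col(probs)]
}

#' Plot the training history of a fit
#'
#' Draws per-epoch loss and accuracy (plus validation accuracy when
#' recorded).
#'
#' @param x a fitted [pneumonet()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.pneumonet <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::plot(h$epoch, h$loss, type = "b", xlab = "epoch", ylab = "loss",
                 main = "training loss", ...)
  cols <- c("black", "firebrick")
  acc <- cbind(h$accuracy, h$val_accuracy)
  graphics::matplot(h$epoch, acc, type = "b", pch = 1, lty = 1, col = cols,
                    xlab = "epoch", ylab = "accuracy", main = "accuracy",
                    ylim = c(0, 1), ...)
  if (ncol(acc) > 1) {
    graphics::legend("bottomright", c("train", "val"), col = cols, lty = 1)
  }
  invisible(x)
}
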