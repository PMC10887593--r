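#' Training configuration
#'
#' Defaults are the tuned hyperparameters: Adam with a peak learning rate
#' of 7.47e-5 reached by a linear warmup, batch size 8, categorical
#' cross-entropy over 5 epochs, with per-sample class weights computed
#' from the training class counts.
#'
#' @param epochs number of passes over the training set.
#' @param batch_size minibatch size.
#' @param peak_lr peak learning rate of the warmup schedule.
#' @param warmup_steps steps of the linear ramp; `NULL` means one epoch of
#'   steps (computed when training starts); 0 disables the ramp.
#' @param class_weights named per-class loss weights, or `NULL` to use the
#'   balanced scheme from [compute_class_weights()] on the training counts.
#' @param augment apply the configured affine/brightness augmentation to
#'   each training image (fresh draw per epoch).
#' @param seed seed driving shuffling, dropout and augmentation.
#' @return an object of class `training_config`.
#' @export
training_config <- function(epochs = 5L, batch_size = 8L, peak_lr = 7.47e-5,
                            warmup_steps = NULL, class_weights = NULL,
                            augment = TRUE, seed = 1L) {
  if (!is_count(epochs) || epochs < 1) stopf("epochs must be >= 1")
  if (!is_count(batch_size) || batch_size < 1) stopf("batch_size must be >= 1")
  if (peak_lr <= 0) stopf("peak_lr must be > 0")
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 peak_lr = peak_lr, warmup_steps = warmup_steps,
                 class_weights = class_weights, augment = isTRUE(augment),
                 seed = as.integer(seed)),
            class = "training_config")
}

#' Warmup learning-rate schedule
#'
#' Linear ramp to the peak: `lr(step) = peak_lr * min(1, (step + 1) /
#' warmup_steps)`, constant at `peak_lr` afterwards.  `warmup_steps = 0`
#' gives a constant schedule.
#'
#' @param step 0-based optimizer step index (vectorized).
#' @param cfg a [training_config()] (its `warmup_steps` must be set).
#' @return learning rate(s).
#' @export
warmup_schedule <- function(step, cfg) {
  if (any(step < 0)) stopf("step must be >= 0")
  ws <- cfg$warmup_steps %||% stopf("warmup_steps not set")
  if (ws == 0) return(rep(cfg$peak_lr, length(step)))
  cfg$peak_lr * pmin(1, (step + 1) / ws)
}

adam_init <- function(params) {
  # 0 * a keeps each leaf's exact shape (including dimensionless scalars)
  list(m = tree_map(function(a) 0 * a, params),
       v = tree_map(function(a) 0 * a, params),
       t = 0L)
}

adam_update <- function(params, grads, opt, lr,
                        beta1 = 0.9, beta2 = 0.999, eps = 1e-7) {
  opt$t <- opt$t + 1L
  opt$m <- tree_map(function(m, g) beta1 * m + (1 - beta1) * g, opt$m, grads)
  opt$v <- tree_map(function(v, g) beta2 * v + (1 - beta2) * g^2, opt$v, grads)
  corr <- lr * sqrt(1 - beta2^opt$t) / (1 - beta1^opt$t)
  params <- tree_map(function(p, m, v) p - corr * m / (sqrt(v) + eps),
                     params, opt$m, opt$v)
  list(params = params, opt = opt)
}

# Weighted categorical cross-entropy; normalization by the total sample
# weight, so zero-weight classes contribute nothing and the loss equals
# the loss over the weighted samples alone.
weighted_ce <- function(probs, y_onehot, w) {
  eps <- 1e-12
  ce <- -rowSums(y_onehot * log(pmax(probs, eps)))
  sw <- sum(w)
  list(loss = sum(w * ce) / sw,
       dlogits = (probs - y_onehot) * (w / sw))
}

one_hot <- function(labels, classes) {
  y <- matrix(0, length(labels), length(classes))
  y[cbind(seq_along(labels), match(labels, classes))] <- 1
  y
}

# Recompute the batch-norm running moments as population statistics over
# the training set ("precise BN").  With minibatches of 8 the
# exponentially averaged moments are biased by batch composition, so
# inference-mode forward passes drift from training behaviour; replacing
# them with weighted full-data moments removes that mismatch.
recalibrate_bn <- function(model, x, batch = 64L) {
  paths <- bn_state_paths(model$state)
  if (length(paths) == 0) return(model)
  n <- dim(x)[1]
  idx <- sample.int(n)  # interleave classes across chunks
  stats <- list(); w <- numeric(0)
  withr::with_options(list(pneumonet.bn_momentum = 0), {
    for (s in seq(1L, n, by = batch)) {
      ii <- idx[s:min(s + batch - 1L, n)]
      f <- model_forward(model, x[ii, , , , drop = FALSE], training = TRUE)
      stats[[length(stats) + 1L]] <- f$state
      w <- c(w, length(ii))
    }
  })
  w <- w / sum(w)
  st <- model$state
  for (p in paths) {
    mus <- vapply(stats, function(s) s[[p]]$mean, stats[[1]][[p]]$mean)
    vas <- vapply(stats, function(s) s[[p]]$var, stats[[1]][[p]]$var)
    mus <- matrix(mus, ncol = length(stats))
    vas <- matrix(vas, ncol = length(stats))
    gm <- as.numeric(mus %*% w)
    gv <- as.numeric((vas + mus^2) %*% w) - gm^2
    st[[p]]$mean <- gm
    st[[p]]$var <- pmax(gv, 0)
  }
  model$state <- st
  model
}

# Flatten the nested state tree into [[c("res","bn1")]]-style paths whose
# leaves hold mean/var running moments.
bn_state_paths <- function(state, prefix = NULL) {
  out <- list()
  for (nm in names(state)) {
    node <- state[[nm]]
    if (is.list(node) && all(c("mean", "var") %in% names(node))) {
      out[[length(out) + 1L]] <- c(prefix, nm)
    } else if (is.list(node)) {
      out <- c(out, bn_state_paths(node, c(prefix, nm)))
    }
  }
  out
}

# Load and preprocess every image of a manifest into an (N, h, w, 3) array.
manifest_to_array <- function(manifest, pre_cfg) {
  n <- nrow(manifest)
  th <- pre_cfg$target_size[1]; tw <- pre_cfg$target_size[2]
  x <- array(0, c(n, th, tw, 3L))
  for (i in seq_len(n)) {
    x[i, , , ] <- preprocess_image(manifest$path[i], pre_cfg)
  }
  x
}

#' Train a model on a dataset manifest
#'
#' Runs Adam with the warmup schedule and per-sample class weights on
#' class-weighted categorical cross-entropy (plus the head's L2 penalty).
#' All randomness -- shuffling, dropout masks, augmentation draws -- is
#' keyed off `cfg$seed`, so a repeated run reproduces the history exactly.
#'
#' @param model a `pn_model` from [assemble_model()].
#' @param train_manifest training `pn_manifest` (non-empty).
#' @param cfg a [training_config()].
#' @param val_manifest optional validation manifest; accuracy on it is
#'   recorded per epoch.
#' @param pre_cfg a [preprocess_config()] (sized to the model input).
#' @param aug_cfg an [augmentation_config()] used when `cfg$augment`.
#' @param checkpoint optional path; the final model is saved there.
#' @param verbose print one line per epoch.
#' @return list with the trained `model` and `history` (data frame with
#'   one row per epoch: loss, accuracy, optional val_accuracy, seconds).
#' @export
train_model <- function(model, train_manifest, cfg = training_config(),
                        val_manifest = NULL, pre_cfg = NULL, aug_cfg = NULL,
                        checkpoint = NULL, verbose = FALSE) {
  stopifnot(inherits(model, "pn_model"), inherits(cfg, "training_config"))
  if (nrow(train_manifest) == 0) stopf("training manifest is empty")
  pre_cfg <- pre_cfg %||%
    preprocess_config(target_size = c(model$input_size, model$input_size))
  aug_cfg <- aug_cfg %||% augmentation_config()

  classes <- model$classes
  labels <- train_manifest$label
  if (!all(labels %in% classes)) stopf("labels must be in {%s}", paste(classes, collapse = ", "))
  counts <- class_counts(train_manifest)
  cw <- cfg$class_weights %||% compute_class_weights(counts)
  w_all <- as.numeric(cw[labels])
  y_all <- one_hot(labels, classes)
  x_all <- manifest_to_array(train_manifest, pre_cfg)
  n <- nrow(train_manifest)
  steps_per_epoch <- ceiling(n / cfg$batch_size)
  cfg$warmup_steps <- cfg$warmup_steps %||% steps_per_epoch

  xv <- NULL
  if (!is.null(val_manifest) && nrow(val_manifest) > 0) {
    xv <- manifest_to_array(val_manifest, pre_cfg)
    yv <- val_manifest$label
  }

  trainable <- model$params
  bb_e_tr <- model$backbone_eff$spec$trainable
  bb_d_tr <- model$backbone_dense$spec$trainable
  full <- list(main = trainable)
  if (bb_e_tr) full$bb_eff <- model$backbone_eff$params
  if (bb_d_tr) full$bb_dense <- model$backbone_dense$params
  opt <- adam_init(full)

  hist <- data.frame()
  step <- 0L
  withr::with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      t0 <- proc.time()[["elapsed"]]
      ord <- sample.int(n)
      ep_loss <- 0; ep_correct <- 0; ep_weight <- 0
      for (bs in seq(1L, n, by = cfg$batch_size)) {
        idx <- ord[bs:min(bs + cfg$batch_size - 1L, n)]
        xb <- x_all[idx, , , , drop = FALSE]
        if (cfg$augment) {
          for (k in seq_along(idx)) {
            xb[k, , , ] <- augment_image(xb[k, , , ], aug_cfg)
          }
        }
        yb <- y_all[idx, , drop = FALSE]
        wb <- w_all[idx]
        fwd <- model_forward(model, xb, training = TRUE)
        model$state <- fwd$state
        lo <- weighted_ce(fwd$probs, yb, wb)
        if (!is.finite(lo$loss)) {
          stopf("training aborted: non-finite loss at epoch %d step %d", ep, step)
        }
        bwd <- model_backward(model, fwd, lo$dlogits)
        g <- list(main = bwd$grads)
        if (bb_e_tr) g$bb_eff <- bwd$backbone_grads$eff
        if (bb_d_tr) g$bb_dense <- bwd$backbone_grads$dense
        lr <- warmup_schedule(step, cfg)
        upd <- adam_update(full, g, opt, lr)
        full <- upd$params; opt <- upd$opt
        model$params <- full$main
        if (bb_e_tr) model$backbone_eff$params <- full$bb_eff
        if (bb_d_tr) model$backbone_dense$params <- full$bb_dense
        step <- step + 1L
        pen <- l2_penalty(model$params$head$d1$W, model$head$l2_coeff)
        ep_loss <- ep_loss + (lo$loss + pen) * length(idx)
        pred <- max.col(fwd$probs)
        ep_correct <- ep_correct + sum(pred == max.col(yb))
        ep_weight <- ep_weight + length(idx)
      }
      row <- data.frame(epoch = ep, loss = ep_loss / ep_weight,
                        accuracy = ep_correct / ep_weight,
                        seconds = proc.time()[["elapsed"]] - t0)
      if (!is.null(xv)) {
        pv <- model_predict(model, xv)
        row$val_accuracy <- mean(colnames(pv)[max.col(pv)] == yv)
      }
      if (verbose) {
        cat(sprintf("epoch %d/%d  loss %.4f  acc %.3f%s  (%.1fs)\n",
                    ep, cfg$epochs, row$loss, row$accuracy,
                    if (!is.null(xv)) sprintf("  val_acc %.3f", row$val_accuracy) else "",
                    row$seconds))
      }
      hist <- rbind(hist, row)
    }
    model <- recalibrate_bn(model, x_all)
    if (!is.null(xv)) {
      pv <- model_predict(model, xv)
      hist$val_accuracy[nrow(hist)] <- mean(colnames(pv)[max.col(pv)] == yv)
    }
  })
  if (!is.null(checkpoint)) save_checkpoint(model, checkpoint)
  list(model = model, history = hist)
}
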