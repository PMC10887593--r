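#' Assemble the full attention-ensemble classifier
#'
#' Wiring: image -> two backbone branches -> per-branch multi-head
#' self-attention -> channel-attention feature fusion -> residual block ->
#' attention augmentation -> dynamic attention pooling -> softmax head.
#' Each of the four bespoke components can be ablated via `components`:
#' feature fusion falls back to a simple strategy (global average pooling
#' of each branch, concatenation, linear fit to the reshape target),
#' attention augmentation to the identity, dynamic pooling to plain global
#' average pooling, and multi-head attention to the identity.  With all
#' four off the model reduces to GAP-concatenation of the backbone feature
#' maps feeding the head directly.
#'
#' @param backbones character vector of two backbone names, or a list of
#'   two [backbone_spec()] objects, for the two branches.
#' @param attention an [attention_config()].
#' @param fusion a [fusion_config()].
#' @param head a [head_config()].
#' @param components named list of logical flags: `feature_fusion`,
#'   `attention_augmentation`, `dynamic_pooling`, `multi_head_attention`.
#' @param input_size input image side length (images are
#'   `input_size x input_size x 3`).
#' @param seed seed for all weight initialization.
#' @return an object of class `pn_model`.
#' @export
assemble_model <- function(backbones = c("tiny_test", "tiny_test"),
                           attention = attention_config(),
                           fusion = fusion_config(),
                           head = head_config(),
                           components = list(),
                           input_size = 224L, seed = 0L) {
  comp <- modifyList(list(feature_fusion = TRUE, attention_augmentation = TRUE,
                          dynamic_pooling = TRUE, multi_head_attention = TRUE),
                     components)
  specs <- lapply(seq_len(2), function(i) {
    b <- if (is.list(backbones) && !inherits(backbones, "backbone_spec")) {
      backbones[[i]]
    } else {
      backbones[i]
    }
    if (inherits(b, "backbone_spec")) return(b)
    if (b == "tiny_test") {
      backbone_spec("tiny_test",
                    stages = max(1L, round(log2(input_size / 7))))
    } else {
      backbone_spec(b)
    }
  })
  bb_e <- build_backbone(specs[[1]], seed = seed)
  bb_d <- build_backbone(specs[[2]], seed = seed + 1L)
  ce <- backbone_out_channels(specs[[1]])
  cd <- backbone_out_channels(specs[[2]])
  all_off <- !comp$feature_fusion && !comp$attention_augmentation &&
    !comp$dynamic_pooling && !comp$multi_head_attention
  params <- withr::with_seed(seed + 2L, {
    p <- list()
    if (comp$multi_head_attention) {
      p$mha_eff <- init_mha_weights(ce, attention)
      p$mha_dense <- init_mha_weights(cd, attention)
    }
    if (!all_off) {
      p$fusion <- if (comp$feature_fusion) {
        init_feature_fusion(ce, cd, fusion)
      } else {
        init_simple_fusion(ce, cd, fusion)
      }
      cf <- fusion$reshape_target[3]
      p$res <- init_residual_block(cf, fusion$residual_filters)
      if (comp$attention_augmentation) {
        p$aug <- init_attention_augmentation(fusion$residual_filters)
      }
      if (comp$dynamic_pooling) {
        p$pool <- init_dynamic_pooling(fusion$residual_filters)
      }
      head_dim <- fusion$residual_filters
    } else {
      head_dim <- ce + cd
    }
    hd <- build_head(head_dim, head)
    p$head <- hd$params
    p
  })
  state <- list(head = list(bn = bn_state_init(head$hidden_units)))
  if (!all_off) {
    state$res <- res_state_init(fusion$residual_filters)
    if (comp$attention_augmentation) {
      state$aug <- aug_state_init(fusion$residual_filters)
    }
  }
  structure(list(
    backbone_eff = bb_e, backbone_dense = bb_d,
    attention = attention, fusion = fusion, head = head,
    components = comp, all_off = all_off,
    input_size = as.integer(input_size), seed = as.integer(seed),
    params = params, state = state,
    classes = pn_classes
  ), class = "pn_model")
}

#' Total trainable-parameter count of a model (backbones included)
#' @param model a `pn_model`.
#' @return integer scalar.
#' @export
n_params <- function(model) {
  stopifnot(inherits(model, "pn_model"))
  tree_size(model$params) + tree_size(model$backbone_eff$params) +
    tree_size(model$backbone_dense$params)
}

# Forward pass.  Returns probs, logits, the named internal activations
# (the Grad-CAM layer registry), per-stage caches for backward, and the
# updated batch-norm state.
model_forward <- function(model, x, training = FALSE) {
  if (length(dim(x)) == 3L) x <- array(x, c(1L, dim(x)))
  p <- model$params; st <- model$state; comp <- model$components
  acts <- list(); caches <- list()

  eff_trainable <- model$backbone_eff$spec$trainable
  dense_trainable <- model$backbone_dense$spec$trainable
  run_bb <- function(bb, trainable) {
    if (bb$spec$name == "tiny_test") {
      tiny_fwd(bb$params, x, want_cache = trainable && training)
    } else {
      list(y = extract_features(x, bb), cache = NULL)
    }
  }
  fe <- run_bb(model$backbone_eff, eff_trainable)
  fd <- run_bb(model$backbone_dense, dense_trainable)
  acts$backbone_eff <- fe$y; acts$backbone_dense <- fd$y
  caches$bb_eff <- fe$cache; caches$bb_dense <- fd$cache

  if (comp$multi_head_attention) {
    me <- mha_fwd(fe$y, p$mha_eff)
    md <- mha_fwd(fd$y, p$mha_dense)
    caches$mha_eff <- me$cache; caches$mha_dense <- md$cache
    me_y <- me$y; md_y <- md$y
  } else {
    me_y <- fe$y; md_y <- fd$y
  }
  acts$mha_eff <- me_y; acts$mha_dense <- md_y

  if (model$all_off) {
    ge <- gap_fwd(me_y); gd <- gap_fwd(md_y)
    pooled <- cbind(ge$y, gd$y)
    caches$gap_eff <- ge$cache; caches$gap_dense <- gd$cache
    caches$ce <- ncol(ge$y)
  } else {
    if (comp$feature_fusion) {
      fz <- fusion_fwd(me_y, md_y, p$fusion, model$fusion, training)
      acts$fusion_attn_eff <- fz$cache$be$a$y
      acts$fusion_attn_dense <- fz$cache$bd$a$y
      acts$fusion_multiply_eff <- fz$cache$be$multiplied
      acts$fusion_multiply_dense <- fz$cache$bd$multiplied
    } else {
      fz <- simple_fusion_fwd(me_y, md_y, p$fusion, model$fusion)
    }
    acts$fusion_reshape <- fz$y
    caches$fusion <- fz$cache

    rs <- res_fwd(fz$y, p$res, st$res, training)
    st$res <- rs$state
    acts$post_reshape_conv <- rs$conv1_out
    acts$residual_out <- rs$y
    caches$res <- rs$cache

    if (comp$attention_augmentation) {
      ag <- aug_fwd(rs$y, p$aug, st$aug, training, model$fusion$dropout)
      st$aug <- ag$state
      acts$augment_out <- ag$y
      acts$augment_gate <- ag$A
      caches$aug <- ag$cache
      au_y <- ag$y
    } else {
      au_y <- rs$y
    }

    if (comp$dynamic_pooling) {
      pl <- pool_fwd(au_y, p$pool)
      acts$pool_gate <- pl$A
      caches$pool <- pl$cache
      pooled <- pl$y
    } else {
      gp <- gap_fwd(au_y)
      caches$gap <- gp$cache
      pooled <- gp$y
    }
  }

  hd <- head_fwd(pooled, p$head, st$head, model$head, training)
  st$head <- hd$state
  caches$head <- hd$cache
  list(probs = hd$probs, logits = hd$logits, acts = acts,
       caches = caches, state = st)
}

model_backward <- function(model, fwd, dlogits, act_grads = character()) {
  p <- model$params; comp <- model$components; caches <- fwd$caches
  g <- list(); ag <- list()

  hb <- head_bwd(p$head, caches$head, dlogits, model$head)
  g$head <- hb$grads
  dpooled <- hb$dx

  if (model$all_off) {
    ce <- caches$ce
    dme <- gap_bwd(caches$gap_eff, dpooled[, seq_len(ce), drop = FALSE])
    dmd <- gap_bwd(caches$gap_dense, dpooled[, -seq_len(ce), drop = FALSE])
  } else {
    if (comp$dynamic_pooling) {
      pb <- pool_bwd(p$pool, caches$pool, dpooled)
      g$pool <- pb$grads
      dau <- pb$dx
    } else {
      dau <- gap_bwd(caches$gap, dpooled)
    }
    if (comp$attention_augmentation) {
      ab <- aug_bwd(p$aug, caches$aug, dau)
      g$aug <- ab$grads
      if ("augment_out" %in% act_grads) ag$augment_out <- dau
      dres <- ab$dx
    } else {
      dres <- dau
    }
    if ("residual_out" %in% act_grads) ag$residual_out <- dres
    rb <- res_bwd(p$res, caches$res, dres)
    g$res <- rb$grads
    if ("post_reshape_conv" %in% act_grads) ag$post_reshape_conv <- rb$d_conv1
    dfz <- rb$dx
    if ("fusion_reshape" %in% act_grads) ag$fusion_reshape <- dfz
    if (comp$feature_fusion) {
      fb <- fusion_bwd(p$fusion, caches$fusion, dfz)
      if ("fusion_multiply_eff" %in% act_grads) ag$fusion_multiply_eff <- fb$d_mult_eff
      if ("fusion_multiply_dense" %in% act_grads) ag$fusion_multiply_dense <- fb$d_mult_dense
    } else {
      fb <- simple_fusion_bwd(p$fusion, caches$fusion, dfz)
    }
    g$fusion <- fb$grads
    dme <- fb$dx_e; dmd <- fb$dx_d
  }
  if (any(c("mha_eff", "mha_dense") %in% act_grads)) {
    ag$mha_eff <- dme; ag$mha_dense <- dmd
  }

  if (comp$multi_head_attention) {
    mbe <- mha_bwd(p$mha_eff, caches$mha_eff, dme)
    mbd <- mha_bwd(p$mha_dense, caches$mha_dense, dmd)
    g$mha_eff <- mbe$grads; g$mha_dense <- mbd$grads
    dbe <- mbe$dx; dbd <- mbd$dx
  } else {
    dbe <- dme; dbd <- dmd
  }
  if (any(c("backbone_eff", "backbone_dense") %in% act_grads)) {
    ag$backbone_eff <- dbe; ag$backbone_dense <- dbd
  }

  gb <- list()
  if (!is.null(caches$bb_eff)) {
    gb$eff <- tiny_bwd(model$backbone_eff$params, caches$bb_eff, dbe)$grads
  }
  if (!is.null(caches$bb_dense)) {
    gb$dense <- tiny_bwd(model$backbone_dense$params, caches$bb_dense, dbd)$grads
  }
  list(grads = g, backbone_grads = gb, act_grads = ag)
}

#' Class probabilities for a batch of preprocessed images
#'
#' @param model a `pn_model`.
#' @param x array `(batch, h, w, 3)` (or a single `(h, w, 3)` image) of
#'   preprocessed intensities in `[0, 1]`.
#' @return matrix `(batch, 2)` of probabilities, columns named by class.
#' @export
model_predict <- function(model, x) {
  out <- model_forward(model, x, training = FALSE)
  colnames(out$probs) <- model$classes
  out$probs
}

#' Save / load a model checkpoint
#'
#' The checkpoint holds every weight, batch-norm running moment and
#' configuration; `load_checkpoint()` restores an object whose forward
#' pass is bit-identical to the saved model's.
#'
#' @param model a `pn_model`.
#' @param path checkpoint file path (RDS format).
#' @return `path` (save) / the restored `pn_model` (load).
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "pn_model"))
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  m <- readRDS(path)
  if (!inherits(m, "pn_model")) stopf("%s is not a pn_model checkpoint", path)
  m
}

#' @export
print.pn_model <- function(x, ...) {
  comp <- x$components
  on <- names(comp)[vapply(comp, isTRUE, logical(1))]
  cat("Attention-ensemble dual-backbone classifier\n")
  cat(sprintf("  backbones: %s + %s (input %dx%dx3)\n",
              x$backbone_eff$spec$name, x$backbone_dense$spec$name,
              x$input_size, x$input_size))
  cat(sprintf("  components: %s\n",
              if (length(on)) paste(on, collapse = ", ") else "none (ablated)"))
  cat(sprintf("  parameters: %s\n", format(n_params(x), big.mark = ",")))
  invisible(x)
}
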