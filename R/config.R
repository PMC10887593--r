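#' Default run configuration
#'
#' One validated record collecting every tunable of the pipeline, mirroring
#' the YAML layout accepted by [read_run_config()]: `augmentation:`
#' (rotation/shift/shear/zoom/brightness/fill mode), `preprocess:`,
#' `model:` (backbones, attention, fusion, components, head) and
#' `training:`.  Defaults are the tuned values (batch 8, dropout 0.2377,
#' L2 6.72e-3, peak learning rate 7.47e-5, 5 epochs, 4 attention heads of
#' key dimension 128, 784 -> 7x7x16 fusion, 256 residual filters).
#'
#' @param ... named overrides merged recursively into the defaults, e.g.
#'   `pn_config(model = list(backbones = c("tiny_test", "tiny_test")))`.
#' @return nested list of class `pn_config`.
#' @export
pn_config <- function(...) {
  base <- list(
    augmentation = list(rotation_deg = 15, shift_frac = 0.1, shear = 0.2,
                        zoom_frac = 0.2, brightness_range = c(0.8, 1.2),
                        fill_mode = "nearest", enabled = TRUE),
    preprocess = list(target_size = c(224L, 224L), channels = 3L,
                      equalize = TRUE),
    model = list(
      backbones = c("efficientnet_b0", "densenet121"),
      attention = list(num_heads = 4L, key_dim = 128L),
      fusion = list(projection_units = 784L, reshape_target = c(7L, 7L, 16L),
                    residual_filters = 256L),
      components = list(feature_fusion = TRUE, attention_augmentation = TRUE,
                        dynamic_pooling = TRUE, multi_head_attention = TRUE),
      head = list(hidden_units = 128L, n_classes = 2L),
      dropout = 0.2377,
      l2_coeff = 6.72e-3
    ),
    training = list(epochs = 5L, batch_size = 8L, peak_lr = 7.47e-5,
                    warmup_steps = NULL, augment = TRUE, seed = 1L)
  )
  over <- list(...)
  cfg <- modifyList(base, over)
  structure(cfg, class = "pn_config")
}

#' Read a YAML run configuration
#'
#' Unknown keys are rejected at the top level; missing keys fall back to
#' the [pn_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `pn_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  known <- c("augmentation", "preprocess", "model", "training")
  bad <- setdiff(names(y), known)
  if (length(bad)) stopf("unknown config section(s): %s", paste(bad, collapse = ", "))
  do.call(pn_config, y)
}

# Materialize the typed sub-configurations from a pn_config.
config_objects <- function(cfg) {
  stopifnot(inherits(cfg, "pn_config"))
  list(
    aug = augmentation_config(
      rotation_deg = cfg$augmentation$rotation_deg,
      shift_frac = cfg$augmentation$shift_frac,
      shear = cfg$augmentation$shear,
      zoom_frac = cfg$augmentation$zoom_frac,
      brightness_range = cfg$augmentation$brightness_range,
      fill_mode = cfg$augmentation$fill_mode),
    pre = preprocess_config(target_size = cfg$preprocess$target_size,
                            equalize = cfg$preprocess$equalize),
    attention = attention_config(num_heads = cfg$model$attention$num_heads,
                                 key_dim = cfg$model$attention$key_dim),
    fusion = fusion_config(projection_units = cfg$model$fusion$projection_units,
                           reshape_target = cfg$model$fusion$reshape_target,
                           dropout = cfg$model$dropout,
                           residual_filters = cfg$model$fusion$residual_filters),
    head = head_config(hidden_units = cfg$model$head$hidden_units,
                       l2_coeff = cfg$model$l2_coeff,
                       dropout = cfg$model$dropout,
                       n_classes = cfg$model$head$n_classes),
    train = training_config(epochs = cfg$training$epochs,
                            batch_size = cfg$training$batch_size,
                            peak_lr = cfg$training$peak_lr,
                            warmup_steps = cfg$training$warmup_steps,
                            augment = cfg$training$augment,
                            seed = cfg$training$seed)
  )
}
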