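#' Configuration for the synthetic chest-X-ray fixture generator
#'
#' The generator emulates the directory layout of the public pediatric
#' chest-X-ray collection used to train the classifier: a root directory
#' with `train/`, `val/` and `test/` splits, each holding `normal/` and
#' `pneumonia/` class subdirectories.  "Normal" images are dark backgrounds
#' with two brighter elliptical lung fields plus Gaussian pixel noise;
#' "pneumonia" images additionally contain a random number of blurred
#' bright blobs ("opacities") planted inside the lung fields, so the two
#' classes are separable by construction (pneumonia images have strictly
#' higher expected mean intensity).
#'
#' @param n_train,n_val,n_test images per class for each split.  A single
#'   number gives balanced classes; a named vector
#'   (e.g. `c(normal = 100, pneumonia = 290)`) gives imbalanced classes so
#'   the class-weighting machinery can be exercised.
#' @param image_size side length in pixels of the square images (>= 8).
#' @param opacity_count_range integer range `c(lo, hi)` of opacity blobs per
#'   pneumonia image.
#' @param blob_sigma Gaussian width of an opacity blob, in pixels.
#' @param noise_sd standard deviation of the additive pixel noise, in 8-bit
#'   intensity units.
#' @param seed integer seed; the same configuration and seed produce
#'   byte-identical image files.
#' @return an object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_train = 200, n_val = 25, n_test = 25,
                             image_size = 224,
                             opacity_count_range = c(3, 7),
                             blob_sigma = 6, noise_sd = 8, seed = 1L) {
  for (n in list(n_train, n_val, n_test)) {
    if (any(n < 0) || any(n != floor(n))) stopf("split sizes must be counts >= 0")
  }
  if (!is_count(image_size) || image_size < 8) {
    stopf("image_size must be an integer >= 8")
  }
  if (length(opacity_count_range) != 2L ||
      opacity_count_range[1] > opacity_count_range[2] ||
      opacity_count_range[1] < 1) {
    stopf("opacity_count_range must be c(lo, hi) with 1 <= lo <= hi")
  }
  if (blob_sigma <= 0 || noise_sd < 0) stopf("blob_sigma > 0 and noise_sd >= 0 required")
  structure(list(
    n_train = n_train, n_val = n_val, n_test = n_test,
    image_size = as.integer(image_size),
    opacity_count_range = as.integer(opacity_count_range),
    blob_sigma = blob_sigma, noise_sd = noise_sd, seed = as.integer(seed)
  ), class = "synthetic_config")
}

pn_classes <- c("normal", "pneumonia")

split_counts <- function(n) {
  if (length(n) == 1L) setNames(rep(as.integer(n), 2L), pn_classes)
  else {
    if (!all(sort(names(n)) == pn_classes)) {
      stopf("per-class counts must be named 'normal' and 'pneumonia'")
    }
    setNames(as.integer(n[pn_classes]), pn_classes)
  }
}

# Lung-field geometry shared by the generator and synthetic_lung_mask().
lung_params <- function(s) {
  list(cx = c(0.32, 0.68) * s, cy = c(0.52, 0.52) * s,
       ax = 0.16 * s, ay = 0.30 * s)
}

lung_field_image <- function(s) {
  lp <- lung_params(s)
  x <- matrix(rep(seq_len(s), each = s), s, s)   # column index
  y <- matrix(rep(seq_len(s), times = s), s, s)  # row index
  base <- matrix(25, s, s)
  for (k in 1:2) {
    inside <- ((x - lp$cx[k]) / lp$ax)^2 + ((y - lp$cy[k]) / lp$ay)^2 <= 1
    base[inside] <- 85
  }
  base
}

# Draw one synthetic image; uses the current RNG stream.  Returns the pixel
# matrix plus the blob table (empty for the normal class).
draw_synthetic_image <- function(class, cfg, template) {
  s <- cfg$image_size
  img <- template
  blobs <- data.frame(x = numeric(0), y = numeric(0),
                      sigma = numeric(0), amplitude = numeric(0))
  if (class == "pneumonia") {
    lp <- lung_params(s)
    k <- sample(seq(cfg$opacity_count_range[1], cfg$opacity_count_range[2]), 1L)
    xs <- matrix(rep(seq_len(s), each = s), s, s)
    ys <- matrix(rep(seq_len(s), times = s), s, s)
    for (b in seq_len(k)) {
      side <- sample(1:2, 1L)
      r <- sqrt(runif(1)) * 0.85
      th <- runif(1, 0, 2 * pi)
      bx <- lp$cx[side] + r * lp$ax * cos(th)
      by <- lp$cy[side] + r * lp$ay * sin(th)
      sg <- cfg$blob_sigma * runif(1, 0.75, 1.25)
      amp <- runif(1, 100, 140)
      img <- img + amp * exp(-((xs - bx)^2 + (ys - by)^2) / (2 * sg^2))
      blobs <- rbind(blobs, data.frame(x = bx, y = by, sigma = sg, amplitude = amp))
    }
  }
  img <- img + rnorm(s * s, 0, cfg$noise_sd)
  list(img = clamp(round(img), 0, 255), blobs = blobs)
}

new_manifest <- function(path, label, split) {
  m <- data.frame(path = as.character(path), label = as.character(label),
                  split = as.character(split), stringsAsFactors = FALSE)
  class(m) <- c("pn_manifest", "data.frame")
  m
}

#' Per-class record counts of a dataset manifest
#' @param manifest a manifest as returned by [generate_synthetic_dataset()]
#'   or [load_image_directory()].
#' @return named integer vector of counts per class label.
#' @export
class_counts <- function(manifest) {
  tab <- table(manifest$label)
  setNames(as.integer(tab), names(tab))
}

#' Generate a synthetic two-class X-ray-like dataset on disk
#'
#' Writes `train/`, `val/` and `test/` split directories under `out_dir`,
#' each with `normal/` and `pneumonia/` subdirectories of 8-bit grayscale
#' PNG images (lossless, so regeneration with the same configuration and
#' seed is byte-identical).  The planted opacity positions are recorded in
#' `blob_truth.csv` at the root, which the Grad-CAM localization checks use
#' as ground truth.
#'
#' @param cfg a [synthetic_config()].
#' @param out_dir writable output directory (created if missing).
#' @return a manifest (class `pn_manifest`): data frame with columns
#'   `path`, `label`, `split`, one row per image written.
#' @export
generate_synthetic_dataset <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "synthetic_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stopf("cannot create output directory: %s", out_dir)
  ok <- file.access(out_dir, mode = 2) == 0
  if (!ok) stopf("output directory not writable: %s", out_dir)

  splits <- list(train = cfg$n_train, val = cfg$n_val, test = cfg$n_test)
  template <- lung_field_image(cfg$image_size)
  rows <- list()
  blob_rows <- list()
  withr::with_seed(cfg$seed, {
    for (sp in names(splits)) {
      counts <- split_counts(splits[[sp]])
      for (cl in pn_classes) {
        d <- file.path(out_dir, sp, cl)
        dir.create(d, recursive = TRUE, showWarnings = FALSE)
        n <- counts[[cl]]
        for (i in seq_len(n)) {
          res <- draw_synthetic_image(cl, cfg, template)
          p <- file.path(d, sprintf("%s_%04d.png", cl, i))
          write_gray_png(res$img, p)
          rows[[length(rows) + 1L]] <- new_manifest(p, cl, sp)
          if (nrow(res$blobs) > 0) {
            res$blobs$path <- p
            blob_rows[[length(blob_rows) + 1L]] <- res$blobs
          }
        }
      }
    }
  })
  blobs <- if (length(blob_rows)) do.call(rbind, blob_rows) else
    data.frame(x = numeric(0), y = numeric(0), sigma = numeric(0),
               amplitude = numeric(0), path = character(0))
  write.csv(blobs, file.path(out_dir, "blob_truth.csv"), row.names = FALSE)
  m <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(m)) m <- new_manifest(character(0), character(0), character(0))
  class(m) <- c("pn_manifest", "data.frame")
  m
}

#' Load a split directory with two class subdirectories into a manifest
#'
#' The directory must contain exactly two subdirectories; their names are
#' taken as the class labels.  Records are returned in sorted-path order so
#' repeated loads are deterministic.  Files that cannot be decoded as
#' images are excluded from the manifest and reported in the `skipped`
#' attribute rather than silently dropped.
#'
#' @param root a split directory (e.g. `<dataset>/train`).
#' @return a `pn_manifest` with attribute `skipped` (character vector of
#'   undecodable files, possibly empty).
#' @export
load_image_directory <- function(root) {
  if (!dir.exists(root)) stopf("directory does not exist: %s", root)
  sub <- sort(list.dirs(root, recursive = FALSE))
  if (length(sub) != 2L) {
    stopf("expected exactly 2 class subdirectories under %s, found %d",
          root, length(sub))
  }
  split <- basename(root)
  if (!split %in% c("train", "val", "test")) split <- NA_character_
  rows <- list(); skipped <- character(0)
  for (d in sub) {
    files <- sort(list.files(d, full.names = TRUE))
    files <- files[!dir.exists(files)]
    for (f in files) {
      ok <- tryCatch({ read_image(f); TRUE }, error = function(e) FALSE)
      if (ok) rows[[length(rows) + 1L]] <- new_manifest(f, basename(d), split)
      else skipped <- c(skipped, f)
    }
  }
  m <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
  else new_manifest(character(0), character(0), character(0))
  class(m) <- c("pn_manifest", "data.frame")
  attr(m, "skipped") <- skipped
  m
}

#' Export / import a manifest as CSV
#' @param manifest a `pn_manifest`.
#' @param path CSV file path.
#' @return `path` (write) or the manifest (read).
#' @export
write_manifest_csv <- function(manifest, path) {
  write.csv(as.data.frame(manifest)[, c("path", "label", "split")], path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest_csv
#' @export
read_manifest_csv <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE)
  new_manifest(d$path, d$label, d$split)
}

#' Scaled-down imbalanced split counts mirroring the study dataset
#'
#' The source dataset is imbalanced (3875 pneumonia vs 1341 normal training
#' images; 390/234 test; 8/8 validation).  This helper scales those counts
#' by `scale` (rounding up, minimum 1 per class) so small fixtures keep the
#' same class imbalance and the class-weighting code path is exercised.
#'
#' @param scale multiplicative factor applied to the real split sizes.
#' @return list with named per-class count vectors `n_train`, `n_val`,
#'   `n_test`, usable directly in [synthetic_config()].
#' @export
study_split_counts <- function(scale = 0.05) {
  sc <- function(n) pmax(1L, as.integer(ceiling(n * scale)))
  list(
    n_train = c(normal = sc(1341), pneumonia = sc(3875)),
    n_val   = c(normal = sc(8),    pneumonia = sc(8)),
    n_test  = c(normal = sc(234),  pneumonia = sc(390))
  )
}
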