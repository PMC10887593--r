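#' Augmentation configuration (training-time affine + brightness jitter)
#'
#' Parameters mirror the augmentation table used for training: rotation
#' +/-15 degrees, shift fraction 0.1, shear 0.2, zoom 0.2, brightness range
#' 0.8--1.2 and 'nearest' boundary fill.
#'
#' @param rotation_deg rotation is sampled uniformly in +/- this many degrees.
#' @param shift_frac horizontal/vertical shift, as a fraction of the side,
#'   sampled uniformly in +/- this value.
#' @param shear shear intensity (radians of the x-shear), sampled uniformly
#'   in +/- this value.
#' @param zoom_frac zoom half-width: the scale factor is sampled uniformly
#'   in `[1 - zoom_frac, 1 + zoom_frac]`.
#' @param brightness_range multiplicative brightness factor range `c(lo, hi)`.
#' @param fill_mode boundary policy; only `"nearest"` (clamp to edge pixels)
#'   is implemented, matching the training setup.
#' @param seed optional default seed for [augment_image()].
#' @return an object of class `augmentation_config`.
#' @export
augmentation_config <- function(rotation_deg = 15, shift_frac = 0.1,
                                shear = 0.2, zoom_frac = 0.2,
                                brightness_range = c(0.8, 1.2),
                                fill_mode = "nearest", seed = NULL) {
  if (rotation_deg < 0 || shift_frac < 0 || shear < 0 || zoom_frac < 0) {
    stopf("augmentation ranges must be non-negative")
  }
  if (length(brightness_range) != 2L || brightness_range[1] > brightness_range[2]) {
    stopf("brightness_range must be c(lo, hi) with lo <= hi")
  }
  if (!identical(fill_mode, "nearest")) stopf("only fill_mode = 'nearest' is supported")
  structure(list(rotation_deg = rotation_deg, shift_frac = shift_frac,
                 shear = shear, zoom_frac = zoom_frac,
                 brightness_range = brightness_range,
                 fill_mode = fill_mode, seed = seed),
            class = "augmentation_config")
}

#' Preprocessing configuration
#'
#' @param target_size output spatial size, default `c(224, 224)`.
#' @param channels number of output channels; the network input is
#'   grayscale replicated to 3 channels.
#' @param equalize apply histogram equalization before channel replication
#'   (default `TRUE`); applied to every split.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(target_size = c(224, 224), channels = 3L,
                              equalize = TRUE) {
  if (any(target_size <= 0)) stopf("target_size must be positive")
  if (channels != 3L) stopf("channels must be 3")
  structure(list(target_size = as.integer(target_size),
                 channels = 3L, equalize = isTRUE(equalize)),
            class = "preprocess_config")
}

#' Classical histogram equalization of an 8-bit grayscale image
#'
#' Applies the cumulative-distribution remapping
#' `out(v) = round((cdf(v) - cdf_min) / (N - cdf_min) * 255)` where
#' `cdf_min` is the smallest non-zero CDF value and `N` the pixel count.
#' An image whose histogram is already uniform is a fixed point.  A
#' constant image (for which `cdf_min = N` makes the denominator zero) is
#' defined to map to all zeros.
#'
#' @param img single-channel matrix of whole numbers in `[0, 255]`.
#' @return matrix of the same shape, whole numbers in `[0, 255]`.
#' @export
histogram_equalize <- function(img) {
  if (!is.matrix(img)) {
    stopf("histogram_equalize expects a single-channel matrix (equalize before channel replication)")
  }
  v <- as.integer(round(img))
  if (any(v < 0 | v > 255)) stopf("pixel values must lie in [0, 255]")
  n <- length(v)
  h <- tabulate(v + 1L, nbins = 256L)
  cdf <- cumsum(h)
  cdf_min <- min(cdf[cdf > 0])
  if (cdf_min == n) return(array(0, dim(img)))  # constant image
  lut <- round((cdf - cdf_min) / (n - cdf_min) * 255)
  out <- lut[v + 1L]
  dim(out) <- dim(img)
  out
}

# Bilinear sampling of `img` (matrix) at fractional (row, col) coordinates,
# with coordinates clamped to the image so out-of-range samples take the
# nearest edge value ('nearest' fill).
bilinear_sample <- function(img, rows, cols) {
  h <- nrow(img); w <- ncol(img)
  rows <- clamp(rows, 1, h); cols <- clamp(cols, 1, w)
  r0 <- floor(rows); c0 <- floor(cols)
  r1 <- pmin(r0 + 1, h); c1 <- pmin(c0 + 1, w)
  fr <- rows - r0; fc <- cols - c0
  i00 <- img[cbind(r0, c0)]; i01 <- img[cbind(r0, c1)]
  i10 <- img[cbind(r1, c0)]; i11 <- img[cbind(r1, c1)]
  (1 - fr) * ((1 - fc) * i00 + fc * i01) + fr * ((1 - fc) * i10 + fc * i11)
}

#' Bilinear resize of a single-channel image
#'
#' Uses half-pixel-centre coordinate mapping, so resizing to the input size
#' is an exact identity.
#'
#' @param img numeric matrix.
#' @param out_h,out_w output size in pixels.
#' @return `out_h` x `out_w` matrix.
#' @export
resize_bilinear <- function(img, out_h, out_w) {
  h <- nrow(img); w <- ncol(img)
  if (h == 0 || w == 0) stopf("cannot resize a zero-sized image")
  sr <- h / out_h; sc <- w / out_w
  rows <- (seq_len(out_h) - 0.5) * sr + 0.5
  cols <- (seq_len(out_w) - 0.5) * sc + 0.5
  rc <- rep(rows, times = out_w)
  cc <- rep(cols, each = out_h)
  matrix(bilinear_sample(img, rc, cc), out_h, out_w)
}

#' Random affine + brightness augmentation of one image
#'
#' Samples a rotation, shift, shear and zoom uniformly from the configured
#' ranges, composes them into a single affine warp about the image centre,
#' resamples bilinearly with nearest-edge boundary fill, then applies a
#' multiplicative brightness factor and clips back into the intensity
#' range.  With all ranges zero and brightness range `c(1, 1)` the output
#' equals the input exactly.
#'
#' @param img matrix (h x w) or array (h x w x c) of intensities in `[0, 1]`.
#' @param cfg an [augmentation_config()].
#' @param seed optional integer seed making the draw reproducible; when
#'   `NULL` the current RNG stream is used (the training loop seeds it).
#' @return augmented image, same shape and range as the input.
#' @export
augment_image <- function(img, cfg, seed = NULL) {
  stopifnot(inherits(cfg, "augmentation_config"))
  seed <- seed %||% cfg$seed
  draw <- function() {
    list(theta = runif(1, -cfg$rotation_deg, cfg$rotation_deg) * pi / 180,
         tx = runif(1, -cfg$shift_frac, cfg$shift_frac),
         ty = runif(1, -cfg$shift_frac, cfg$shift_frac),
         sh = runif(1, -cfg$shear, cfg$shear),
         z = runif(1, 1 - cfg$zoom_frac, 1 + cfg$zoom_frac),
         br = runif(1, cfg$brightness_range[1], cfg$brightness_range[2]))
  }
  p <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  warp_one <- function(m) {
    h <- nrow(m); w <- ncol(m)
    # forward map: dst = R(theta) %*% Shear %*% Zoom %*% (src - c) + c + t
    R <- matrix(c(cos(p$theta), sin(p$theta), -sin(p$theta), cos(p$theta)), 2)
    S <- matrix(c(1, 0, -p$sh, 1), 2)     # x-shear
    Z <- diag(c(p$z, p$z))
    M <- R %*% S %*% Z
    Minv <- solve(M)
    cy <- (h + 1) / 2; cx <- (w + 1) / 2
    ty <- p$ty * h; tx <- p$tx * w
    rows <- rep(seq_len(h), times = w) - cy - ty
    cols <- rep(seq_len(w), each = h) - cx - tx
    src_r <- Minv[1, 1] * rows + Minv[1, 2] * cols + cy
    src_c <- Minv[2, 1] * rows + Minv[2, 2] * cols + cx
    matrix(bilinear_sample(m, src_r, src_c), h, w)
  }
  out <- if (is.matrix(img)) warp_one(img) else {
    a <- img
    for (k in seq_len(dim(img)[3])) a[, , k] <- warp_one(img[, , k])
    a
  }
  clamp(out * p$br, 0, 1)
}

#' Preprocess a raw image into a network-ready array
#'
#' Pipeline: bilinear resize to the target size, optional histogram
#' equalization (on the single grayscale channel, before replication),
#' replication to 3 identical channels, and scaling to `[0, 1]`.
#'
#' @param img a path, or a grayscale matrix with values in `[0, 255]`.
#' @param cfg a [preprocess_config()].
#' @return array `target_h x target_w x 3` of doubles in `[0, 1]`.
#' @export
preprocess_image <- function(img, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  if (is.character(img)) img <- read_image(img)
  if (!is.matrix(img) || nrow(img) == 0 || ncol(img) == 0) {
    stopf("preprocess_image expects a non-empty grayscale matrix or file path")
  }
  th <- cfg$target_size[1]; tw <- cfg$target_size[2]
  if (nrow(img) != th || ncol(img) != tw) {
    img <- resize_bilinear(img, th, tw)
  }
  if (cfg$equalize) {
    img <- histogram_equalize(clamp(round(img), 0, 255))
  }
  g <- img / 255
  array(g, dim = c(th, tw, 3L))  # grayscale replicated channel-wise
}

#' Balanced class weights from class counts
#'
#' Uses the standard balanced scheme `w_c = n_total / (n_classes * n_c)`,
#' which satisfies the conservation identity
#' `sum_c n_c * w_c = n_total` for any counts.
#'
#' @param counts named vector of per-class counts, all positive.
#' @return named numeric vector of weights.
#' @export
compute_class_weights <- function(counts) {
  if (is.null(names(counts)) || any(names(counts) == "")) {
    stopf("counts must be a named vector")
  }
  if (any(counts <= 0)) stopf("all class counts must be positive")
  n_total <- sum(counts)
  w <- n_total / (length(counts) * counts)
  setNames(as.numeric(w), names(counts))
}
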