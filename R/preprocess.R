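# Image conditioning chain: histogram equalization -> bilinear resize ->
# (train-time augmentation) -> z-score normalization with training-set stats.
# Statistics are pooled over all training-fold pixels so validation and test
# images never leak into them.

#' Pooled intensity statistics of a training set
#'
#' Mean and standard deviation pooled over every pixel of every training
#' image (population formula).  The sd is floored at `1e-8` so constant
#' inputs stay usable.
#'
#' @param images list of numeric matrices (or a single matrix).
#' @return An object of class `"norm_stats"`: list with `mean` and `sd`.
#' @export
norm_stats <- function(images) {
  if (is.matrix(images)) images <- list(images)
  if (length(images) == 0L) stop("norm_stats: empty training set")
  px <- unlist(lapply(images, as.vector), use.names = FALSE)
  m <- mean(px)
  s <- sqrt(mean((px - m)^2))
  structure(list(mean = m, sd = max(s, 1e-8)), class = "norm_stats")
}

#' Z-score normalize an image
#'
#' Elementwise `(x - mean) / sd` with training-set statistics.
#'
#' @param image numeric matrix.
#' @param stats a [norm_stats()].
#' @return Matrix of the same shape.
#' @export
normalize_zscore <- function(image, stats) {
  stopifnot(inherits(stats, "norm_stats"), stats$sd > 0)
  (image - stats$mean) / stats$sd
}

#' Global histogram equalization on the 8-bit quantization
#'
#' Intensities are quantized to 256 levels; the output level of value `v` is
#' `round((cdf(v) - cdf_min) / (N - cdf_min) * 255)`, mapped back to `[0,1]`.
#' Constant images are returned unchanged (the textbook formula degenerates).
#'
#' @param image numeric matrix in `[0,1]`.
#' @return Equalized matrix in `[0,1]`.
#' @export
hist_equalize <- function(image) {
  q <- as.integer(pmin(255, pmax(0, round(image * 255))))
  n <- length(q)
  counts <- tabulate(q + 1L, nbins = 256L)
  cdf <- cumsum(counts)
  cdf_min <- min(cdf[cdf > 0])
  if (n == cdf_min) return(image)            # constant image: fixed point
  lut <- round((cdf - cdf_min) / (n - cdf_min) * 255) / 255
  out <- lut[q + 1L]
  matrix(out, nrow(image), ncol(image))
}

#' Bilinear resize to a square target
#'
#' Half-pixel center mapping with edge clamping; resizing to the input size
#' is an exact identity.  Output is clipped to the input's intensity range.
#'
#' @param image numeric matrix.
#' @param target_size side of the square output (>= 8).
#' @return `target_size x target_size` matrix.
#' @export
resize_bilinear <- function(image, target_size) {
  target_size <- as.integer(target_size)
  if (target_size < 8L) stop("resize: target_size must be >= 8")
  H <- nrow(image); W <- ncol(image)
  interp_mat <- function(n_out, n_in) {
    src <- pmin(n_in - 1, pmax(0, (seq_len(n_out) - 0.5) * n_in / n_out - 0.5))
    i0 <- floor(src); f <- src - i0
    i1 <- pmin(i0 + 1, n_in - 1)
    R <- matrix(0, n_out, n_in)
    R[cbind(seq_len(n_out), i0 + 1)] <- R[cbind(seq_len(n_out), i0 + 1)] + (1 - f)
    R[cbind(seq_len(n_out), i1 + 1)] <- R[cbind(seq_len(n_out), i1 + 1)] + f
    R
  }
  out <- interp_mat(target_size, H) %*% image %*% t(interp_mat(target_size, W))
  rng <- range(image)
  clip_to(out, rng[1], rng[2])
}

# Inverse-mapped affine resample (rotation by `angle_deg` about the center,
# then uniform scale).  Bilinear sampling; out-of-range source pixels -> fill.
affine_resample <- function(image, angle_deg = 0, scale = 1, fill = 0) {
  if (angle_deg == 0 && scale == 1) return(image)
  H <- nrow(image); W <- ncol(image)
  cy <- (H + 1) / 2; cx <- (W + 1) / 2
  yt <- rep(seq_len(H), times = W) - cy
  xt <- rep(seq_len(W), each = H) - cx
  th <- -angle_deg * pi / 180     # inverse rotation
  ys <- (cos(th) * yt - sin(th) * xt) / scale + cy
  xs <- (sin(th) * yt + cos(th) * xt) / scale + cx
  y0 <- floor(ys); x0 <- floor(xs)
  fy <- ys - y0; fx <- xs - x0
  sample_at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= H & xx >= 1 & xx <= W
    v <- rep(fill, length(yy))
    v[ok] <- image[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * sample_at(y0, x0) +
       (1 - fy) * fx       * sample_at(y0, x0 + 1) +
       fy       * (1 - fx) * sample_at(y0 + 1, x0) +
       fy       * fx       * sample_at(y0 + 1, x0 + 1)
  matrix(v, H, W)
}

#' Train-time augmentation specification
#'
#' Defaults: rotation up to +/-5 degrees, horizontal flip with probability
#' 0.5, uniform scale in `[0.95, 1.05]` (content rescaled about the center
#' and cropped/padded back to the original size).  The magnitudes are mild
#' on purpose: at 64x64 with fine structure (rib bands), +/-15-degree
#' rotations decorrelate an image from its original almost completely and
#' measurably stall training; see the methods vignette.
#'
#' @param rotation_deg maximum absolute rotation in degrees (>= 0).
#' @param hflip_prob horizontal-flip probability in `[0,1]`.
#' @param scale_range length-2 multiplicative range `(lo, hi)`, `0 < lo <= hi`.
#' @return An object of class `"augment_spec"`.
#' @export
augment_spec <- function(rotation_deg = 5, hflip_prob = 0.5,
                         scale_range = c(0.95, 1.05)) {
  stopifnot(rotation_deg >= 0, hflip_prob >= 0, hflip_prob <= 1,
            length(scale_range) == 2L, scale_range[1] > 0,
            scale_range[1] <= scale_range[2])
  structure(list(rotation_deg = rotation_deg, hflip_prob = hflip_prob,
                 scale_range = scale_range), class = "augment_spec")
}

#' Randomly augment one image
#'
#' Applies, in order: rotation by a uniform angle within the spec's range,
#' horizontal flip with the spec's probability, and uniform scaling about the
#' center (cropped/padded back to the original size).  Draws three variates
#' from the current RNG regardless of the spec, so call sequences stay
#' reproducible.  Shape is always preserved.
#'
#' @param image numeric matrix.
#' @param spec an [augment_spec()].
#' @return Augmented matrix of the same shape.
#' @export
augment_image <- function(image, spec) {
  stopifnot(inherits(spec, "augment_spec"))
  ang <- stats::runif(1, -spec$rotation_deg, spec$rotation_deg)
  do_flip <- stats::runif(1) < spec$hflip_prob
  sc <- stats::runif(1, spec$scale_range[1], spec$scale_range[2])
  out <- affine_resample(image, angle_deg = ang, scale = 1)
  if (do_flip) out <- out[, rev(seq_len(ncol(out))), drop = FALSE]
  affine_resample(out, angle_deg = 0, scale = sc)
}

#' 3x3 median filter
#'
#' Optional light denoising step for noisy inputs (replicate padding at the
#' borders).
#'
#' @param image numeric matrix.
#' @return Filtered matrix of the same shape.
#' @export
median_filter3 <- function(image) {
  H <- nrow(image); W <- ncol(image)
  yp <- c(1, seq_len(H), H); xp <- c(1, seq_len(W), W)
  pad <- image[yp, xp, drop = FALSE]
  stack <- matrix(0, H * W, 9L)
  j <- 0L
  for (dx in 0:2) for (dy in 0:2) {
    j <- j + 1L
    stack[, j] <- as.vector(pad[dy + seq_len(H), dx + seq_len(W)])
  }
  matrix(apply(stack, 1L, stats::median), H, W)
}

#' Apply the deterministic preprocessing chain to a list of images
#'
#' Order: equalize (optional) -> resize.  Normalization is applied separately
#' once training statistics exist, and augmentation only inside the training
#' loop.
#'
#' @param images list of matrices.
#' @param size target square size.
#' @param equalize logical; apply [hist_equalize()] first.
#' @return List of `size x size` matrices.
#' @export
preprocess_images <- function(images, size, equalize = TRUE) {
  lapply(images, function(im) {
    if (equalize) im <- hist_equalize(im)
    resize_bilinear(im, size)
  })
}
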