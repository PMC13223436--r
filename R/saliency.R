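# Grad-CAM saliency over the last spatial layer (the pointwise convolution
# of the separable residual block, post-activation, just before global
# average pooling).  The gradient target is the pre-softmax class score, so
# saliency is invariant to adding a constant to all logits.

#' Grad-CAM saliency map for one image
#'
#' Channel weights are the spatial means of the target-class logit gradient
#' at the designated layer; the map is the rectified weighted sum of that
#' layer's activations, bilinearly upsampled to the input size and min-max
#' normalized.  For this head (global average pooling + linear), the logit
#' gradient at the layer is spatially uniform and equals
#' `w_fc[class, c] / n_spatial` per channel, which is what is computed here.
#' An all-zero pre-normalization map is returned as all zeros with attribute
#' `flat = TRUE`.
#'
#' @param model a fitted `"pneumonet"`.
#' @param image raw grayscale image matrix (preprocessed internally with the
#'   model's stored pipeline).
#' @param target_class class label or 1-based index.
#' @return Matrix of the input size in `[0,1]`, with attributes
#'   `target_class`, `layer`, and `flat`.
#' @export
grad_cam <- function(model, image, target_class) {
  stopifnot(inherits(model, "pneumonet"))
  if (is.character(target_class) || is.factor(target_class)) {
    k <- match(as.character(target_class), model$classes)
    if (is.na(k)) stop("invalid target class: ", target_class)
  } else {
    k <- as.integer(target_class)
    if (k < 1L || k > length(model$classes)) {
      stop("invalid target class index: ", k)
    }
  }
  pre <- preprocess_images(list(image), model$config$input_size,
                           model$control$equalize)
  xin <- normalize_zscore(pre[[1]], model$stats)
  st <- stack_images(list(xin))
  fw <- net_forward(st$X, st$geom, model$params, model$config,
                    training = FALSE, rate = 0)
  A <- fw$A_spatial                       # S' x C, the designated layer
  n_sp <- nrow(A)
  # d(logit_k)/dA[s, c] through GAP + FC (residual add passes gradient 1)
  gradA <- matrix(rep(model$params$fc_W[k, ] / n_sp, each = n_sp), n_sp)
  alpha <- colMeans(gradA)                # spatially pooled channel weights
  raw <- pmax(0, as.vector(A %*% alpha))  # rectified weighted sum
  g <- fw$geom_sep
  cam <- matrix(raw, g$H, g$W)
  up <- resize_bilinear(cam, model$config$input_size)
  mx <- max(up)
  flat <- mx <= 0
  out <- if (flat) up * 0 else (up - min(up)) / (mx - min(up))
  structure(out, target_class = model$classes[k],
            layer = "separable_pointwise", flat = flat)
}

#' Write a saliency overlay as a PNG
#'
#' Blends the (preprocessed) input image with a red-tinted saliency layer.
#'
#' @param model a fitted `"pneumonet"`.
#' @param image raw grayscale image matrix.
#' @param target_class class label or index.
#' @param path output PNG path.
#' @param alpha blend weight of the saliency layer.
#' @return The saliency map, invisibly.
#' @export
grad_cam_overlay <- function(model, image, target_class, path, alpha = 0.45) {
  sal <- grad_cam(model, image, target_class)
  base <- resize_bilinear(image, model$config$input_size)
  rgb <- array(0, c(nrow(base), ncol(base), 3L))
  rgb[, , 1] <- clip01((1 - alpha) * base + alpha * sal)
  rgb[, , 2] <- clip01((1 - alpha) * base)
  rgb[, , 3] <- clip01((1 - alpha) * base)
  png::writePNG(rgb, target = path)
  invisible(sal)
}
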