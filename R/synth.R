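# Synthetic four-class chest image generator.
#
# Emulates the statistical structure of grayscale chest X-ray / CT pneumonia
# datasets at desk scale: two elliptical lung fields on a body background,
# class-specific opacity signatures, modality-dependent contrast, additive
# Gaussian noise, and ground-truth lesion masks.  This is a statistical
# stand-in, not a radiological simulation; see the methods vignette.

PNEUMO_CLASSES <- c("Normal", "Bacterial Pneumonia",
                    "Viral Pneumonia", "Fungal Pneumonia")

# Fixed lung-field geometry (normalized [0,1] coordinates): two ellipses.
LUNG_GEOM <- list(
  centers = list(c(x = 0.33, y = 0.48), c(x = 0.67, y = 0.48)),
  axes    = c(a = 0.16, b = 0.27)
)

#' Specification for a synthetic chest-image dataset
#'
#' @param n_per_class images generated per class (>= 1).
#' @param classes class vocabulary; defaults to the four pneumonia screening
#'   classes (Normal, Bacterial, Viral, Fungal).
#' @param modality `"xray"` (rib-band sinusoids, full-field body) or `"ct"`
#'   (circular body cross-section, 1.5x lesion contrast).
#' @param image_size square image side in pixels (>= 32).
#' @param severity fraction in `[0,1]` scaling lesion contrast; 0 makes every
#'   class pixel-identical to Normal.
#' @param noise_sd standard deviation of additive Gaussian intensity noise.
#' @param seed integer seed; every image derives its own substream from it,
#'   so generation is insertion-order independent.
#' @return An object of class `"synth_spec"`.
#' @export
synth_spec <- function(n_per_class = 50L, classes = PNEUMO_CLASSES,
                       modality = c("xray", "ct"), image_size = 64L,
                       severity = 1, noise_sd = 0.05, seed = 1L) {
  modality <- match.arg(modality)
  n_per_class <- as.integer(n_per_class)
  image_size <- as.integer(image_size)
  stopifnot(n_per_class >= 1L, image_size >= 32L,
            noise_sd >= 0, severity >= 0, severity <= 1,
            length(classes) >= 2L, !anyDuplicated(classes))
  structure(list(n_per_class = n_per_class, classes = classes,
                 modality = modality, image_size = image_size,
                 severity = severity, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synth_spec")
}

#' Logical mask of the two elliptical lung fields
#'
#' The lung geometry is fixed (not randomized), so the same mask applies to
#' every generated image of a given size.
#'
#' @param image_size square image side in pixels.
#' @return `image_size x image_size` logical matrix.
#' @export
synth_lung_mask <- function(image_size) {
  n <- as.integer(image_size)
  xv <- (seq_len(n) - 0.5) / n
  yv <- (seq_len(n) - 0.5) / n
  xs <- matrix(rep(xv, each = n), n)
  ys <- matrix(rep(yv, n), n)
  m <- matrix(FALSE, n, n)
  a <- LUNG_GEOM$axes[["a"]]; b <- LUNG_GEOM$axes[["b"]]
  for (ctr in LUNG_GEOM$centers) {
    m <- m | (((xs - ctr[["x"]]) / a)^2 + ((ys - ctr[["y"]]) / b)^2 <= 1)
  }
  m
}

# Draw a point uniformly inside lung ellipse `side` (1 = left, 2 = right),
# shrunk by `margin` so lesions sit inside the field.  Uses the current RNG.
sample_in_lung <- function(side, margin = 0.75) {
  ctr <- LUNG_GEOM$centers[[side]]
  a <- LUNG_GEOM$axes[["a"]] * margin; b <- LUNG_GEOM$axes[["b"]] * margin
  repeat {
    u <- stats::runif(2, -1, 1)
    if (sum(u^2) <= 1) {
      return(c(x = ctr[["x"]] + u[1] * a, y = ctr[["y"]] + u[2] * b))
    }
  }
}

#' Generate one synthetic chest image and its lesion mask
#'
#' Class signatures: Normal has clear lung fields; Bacterial one focal
#' high-opacity blob (radius 8--15% of image width); Viral a diffuse
#' bilateral low-contrast texture; Fungal 3--6 small nodules (radius 2--4%).
#' CT images get a circular body cross-section and 1.5x lesion contrast;
#' X-ray images get overlapping low-frequency rib bands.  Gaussian noise of
#' sd `spec$noise_sd` is added, then intensities are clipped to `[0,1]`.
#'
#' Geometry and noise come from separate substreams derived from
#' `(spec$seed, index)`, so two classes generated at the same index share
#' their noise field: at `severity = 0` every class is pixel-identical to
#' Normal.
#'
#' @param class_label one of `spec$classes`.
#' @param spec a [synth_spec()].
#' @param index 1-based image index within the class (selects the substream).
#' @return A list with `image` (H x W matrix in `[0,1]`), `mask` (logical
#'   H x W lesion support, empty for Normal), `label`, `modality`.
#' @export
synth_image <- function(class_label, spec, index = 1L) {
  if (!class_label %in% spec$classes) {
    stop("unknown class label: '", class_label, "'")
  }
  n <- spec$image_size
  xv <- (seq_len(n) - 0.5) / n
  xs <- matrix(rep(xv, each = n), n)
  ys <- matrix(rep(xv, n), n)

  cls_i <- match(class_label, spec$classes)
  # base anatomy and noise are class-independent substreams, so severity 0
  # makes every class pixel-identical to Normal at the same index
  base_seed  <- hash_seed(spec$seed, index, "base")
  geom_seed  <- hash_seed(spec$seed, index, cls_i, "geom")
  noise_seed <- hash_seed(spec$seed, index, "noise")
  mult <- if (spec$modality == "ct") 1.5 else 1.0
  lung <- synth_lung_mask(n)

  img <- with_seed(base_seed, {
    # body background
    if (spec$modality == "ct") {
      inside <- (xs - 0.5)^2 + (ys - 0.5)^2 <= 0.48^2
      base <- ifelse(inside, 0.55, 0.02)
    } else {
      base <- matrix(0.55, n, n)
      freq <- stats::runif(1, 6, 8)
      phase <- stats::runif(1, 0, 2 * pi)
      base <- base + 0.05 * sin(2 * pi * freq * ys + phase)
    }
    base[lung] <- 0.22
    base
  })

  mask <- matrix(FALSE, n, n)
  sev <- spec$severity
  canon <- sub(" Pneumonia$", "", class_label)
  if (canon %in% c("Bacterial", "Viral", "Fungal")) {
    lesion <- with_seed(hash_seed(geom_seed, "lesion"), {
      add <- matrix(0, n, n)
      if (canon == "Bacterial") {
        side <- sample.int(2L, 1L)
        ctr <- sample_in_lung(side, margin = 0.65)
        r <- stats::runif(1, 0.08, 0.15)
        d2 <- (xs - ctr[["x"]])^2 + (ys - ctr[["y"]])^2
        prof <- pmax(0, 1 - d2 / r^2)
        add <- 0.5 * sev * mult * prof
        mask <- (d2 <= r^2) & lung
      } else if (canon == "Viral") {
        field <- matrix(0, n, n)
        for (k in 1:4) {
          ang <- stats::runif(1, 0, pi)
          fr <- stats::runif(1, 2, 5)
          ph <- stats::runif(1, 0, 2 * pi)
          field <- field +
            sin(2 * pi * fr * (cos(ang) * xs + sin(ang) * ys) + ph) / k
        }
        rng <- range(field)
        field <- (field - rng[1]) / max(rng[2] - rng[1], 1e-12)
        add <- 0.05 * sev * mult * field
        mask <- lung
      } else { # Fungal
        k <- sample(3:6, 1L)
        nod <- matrix(FALSE, n, n)
        for (j in seq_len(k)) {
          side <- sample.int(2L, 1L)
          ctr <- sample_in_lung(side, margin = 0.8)
          r <- stats::runif(1, 0.02, 0.04)
          d2 <- (xs - ctr[["x"]])^2 + (ys - ctr[["y"]])^2
          add <- add + 0.55 * sev * mult * pmax(0, 1 - d2 / r^2)
          nod <- nod | (d2 <= r^2)
        }
        mask <- nod & lung
      }
      add
    })
    img <- img + lesion * lung
  }

  if (spec$noise_sd > 0) {
    img <- img + with_seed(noise_seed,
                           matrix(stats::rnorm(n * n, 0, spec$noise_sd), n, n))
  }
  list(image = clip01(img), mask = mask, label = class_label,
       modality = spec$modality)
}

#' Generate a labelled synthetic dataset
#'
#' Produces exactly `n_per_class` images per class, in class-major,
#' index-minor order, with lesion masks carried alongside.  Content is a
#' pure function of the spec (including its seed).
#'
#' @param spec a [synth_spec()].
#' @return An object of class `"pneumo_dataset"`: list with `images` (list of
#'   matrices), `labels` (factor over `spec$classes`), `masks` (list of
#'   logical matrices), `modality`, `spec`.
#' @export
synth_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  images <- list(); masks <- list(); labels <- character(0)
  for (cl in spec$classes) {
    for (i in seq_len(spec$n_per_class)) {
      g <- synth_image(cl, spec, index = i)
      images[[length(images) + 1L]] <- g$image
      masks[[length(masks) + 1L]] <- g$mask
      labels <- c(labels, cl)
    }
  }
  structure(list(images = images,
                 labels = factor(labels, levels = spec$classes),
                 masks = masks, modality = spec$modality, spec = spec),
            class = "pneumo_dataset")
}

#' @export
print.pneumo_dataset <- function(x, ...) {
  cat("pneumo_dataset:", length(x$images), "images,",
      nlevels(x$labels), "classes,",
      paste(dim(x$images[[1]]), collapse = "x"), "px,",
      "modality", x$modality, "\n")
  print(table(x$labels))
  invisible(x)
}
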