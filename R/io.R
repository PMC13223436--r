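# Dataset I/O: class-per-subdirectory image trees (the layout most public
# image collections ship in), 8-bit grayscale PNG output, and a CSV manifest
# per written dataset.

read_gray_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- if (ext == "png") {
    png::readPNG(path)
  } else if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE)) {
      stop("JPEG input requires the EBImage package")
    }
    a <- EBImage::imageData(EBImage::readImage(path))
    # EBImage stores x-major; transpose back to row = y
    if (length(dim(a)) == 2L) t(a) else aperm(a, c(2, 1, 3))
  } else {
    stop("unsupported image format: ", path)
  }
  if (length(dim(img)) == 3L) {
    # color input: luminance by channel average (alpha dropped)
    nc <- min(dim(img)[3], 3L)
    img <- apply(img[, , seq_len(nc), drop = FALSE], c(1, 2), mean)
  }
  clip01(img)
}

write_gray_png <- function(image, path) {
  png::writePNG(clip01(image), target = path)
  invisible(path)
}

#' Write a dataset as a class-per-folder PNG tree
#'
#' Images go to `<dir>/<class>/img_<i>.png` (8-bit grayscale); lesion masks,
#' when present, to a parallel `<dir>/masks/<class>/` tree; and a
#' `manifest.csv` (path, label, modality, seed) is written at the root.
#'
#' @param dataset a `"pneumo_dataset"` (see [synth_dataset()]).
#' @param dir output directory (created if missing).
#' @return The manifest data frame, invisibly.
#' @export
write_image_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "pneumo_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  labs <- as.character(dataset$labels)
  rows <- vector("list", length(dataset$images))
  counter <- integer(0)
  for (i in seq_along(dataset$images)) {
    cl <- labs[i]
    counter[cl] <- if (is.na(counter[cl])) 1L else counter[cl] + 1L
    cdir <- file.path(dir, cl)
    dir.create(cdir, showWarnings = FALSE)
    fn <- sprintf("img_%04d.png", counter[cl])
    rel <- file.path(cl, fn)
    write_gray_png(dataset$images[[i]], file.path(dir, rel))
    if (!is.null(dataset$masks) && !is.null(dataset$masks[[i]])) {
      mdir <- file.path(dir, "masks", cl)
      dir.create(mdir, recursive = TRUE, showWarnings = FALSE)
      write_gray_png(dataset$masks[[i]] * 1.0, file.path(mdir, fn))
    }
    rows[[i]] <- data.frame(path = rel, label = cl,
                            modality = dataset$modality,
                            seed = dataset$spec$seed,
                            stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' Load a class-per-folder image tree as a dataset
#'
#' Labels come from subdirectory names (sorted vocabulary); images are
#' decoded to `[0,1]` grayscale (color inputs by luminance average; 8- and
#' 16-bit PNGs both land on `[0,1]`).  Unreadable files are skipped with a
#' warning.  A `masks/` subdirectory, if present, is read into lesion masks.
#'
#' @param root directory containing at least two class subdirectories.
#' @return A `"pneumo_dataset"`.
#' @export
load_image_dataset <- function(root) {
  if (!dir.exists(root)) stop("dataset root does not exist: ", root)
  dirs <- list.dirs(root, recursive = FALSE, full.names = FALSE)
  cls <- sort(setdiff(dirs, "masks"))
  if (length(cls) < 2L) {
    stop("need >= 2 class subdirectories under ", root,
         "; found: ", paste(dirs, collapse = ", "))
  }
  images <- list(); masks <- list(); labels <- character(0)
  any_mask <- dir.exists(file.path(root, "masks"))
  for (cl in cls) {
    files <- sort(list.files(file.path(root, cl),
                             pattern = "\\.(png|jpg|jpeg)$",
                             ignore.case = TRUE))
    if (length(files) == 0L) {
      stop("empty class folder: ", cl,
           " (folders found: ", paste(dirs, collapse = ", "), ")")
    }
    for (f in files) {
      img <- tryCatch(read_gray_image(file.path(root, cl, f)),
                      error = function(e) {
                        warning("skipping unreadable file ",
                                file.path(cl, f), ": ", conditionMessage(e))
                        NULL
                      })
      if (is.null(img)) next
      images[[length(images) + 1L]] <- img
      labels <- c(labels, cl)
      mpath <- file.path(root, "masks", cl, f)
      masks[[length(masks) + 1L]] <-
        if (any_mask && file.exists(mpath)) read_gray_image(mpath) > 0.5
        else NULL
    }
  }
  structure(list(images = images, labels = factor(labels, levels = cls),
                 masks = if (any_mask) masks else NULL,
                 modality = NA_character_, spec = NULL),
            class = "pneumo_dataset")
}
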