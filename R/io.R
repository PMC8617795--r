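#' Write a dataset to disk as PNG pairs with a split manifest
#'
#' Images and masks are written as 8-bit grayscale PNGs named
#' `img_0001.png` / `msk_0001.png`, plus a `manifest.csv` with columns
#' `image`, `mask`, `split`.
#'
#' @param dataset a `"seg_dataset"` from [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return Invisibly, the manifest data frame.
#' @export
write_dataset <- function(dataset, dir) {
  if (!inherits(dataset, "seg_dataset")) stop("'dataset' must be a seg_dataset")
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- length(dataset$pairs)
  img_files <- sprintf("img_%04d.png", seq_len(n))
  msk_files <- sprintf("msk_%04d.png", seq_len(n))
  for (i in seq_len(n)) {
    png::writePNG(dataset$pairs[[i]]$image, file.path(dir, img_files[i]))
    png::writePNG(dataset$pairs[[i]]$mask, file.path(dir, msk_files[i]))
  }
  manifest <- data.frame(image = img_files, mask = msk_files,
                         split = dataset$split, stringsAsFactors = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
              png = png::readPNG(path),
              tif = ,
              tiff = tiff::readTIFF(path),
              stop("unsupported image format: ", ext, call. = FALSE))
  if (length(dim(x)) == 3L) x <- apply(x[, , seq_len(min(3L, dim(x)[3L])), drop = FALSE],
                                       c(1L, 2L), mean)
  x
}

#' Read an image/mask pair from PNG or TIFF files
#'
#' RGB inputs are averaged to grayscale; the mask is binarized at 0.5. The
#' same reader serves synthetic datasets and external ultrasound data laid
#' out as same-shape image/mask files.
#'
#' @param image_path,mask_path file paths (PNG or TIFF).
#' @return An `"image_pair"` list with `image` in \[0, 1\] and `mask` in \{0, 1\}.
#' @export
read_image_pair <- function(image_path, mask_path) {
  img <- read_gray(image_path)
  msk <- (read_gray(mask_path) >= 0.5) * 1
  if (!identical(dim(img), dim(msk)))
    stop("image and mask shapes differ", call. = FALSE)
  structure(list(image = pmin(pmax(img, 0), 1), mask = msk), class = "image_pair")
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir directory containing `manifest.csv` and the PNG/TIFF pairs.
#' @return A `"seg_dataset"` list with `pairs` and `split`.
#' @export
read_dataset <- function(dir) {
  mf <- read.csv(file.path(dir, "manifest.csv"), stringsAsFactors = FALSE)
  pairs <- lapply(seq_len(nrow(mf)), function(i)
    read_image_pair(file.path(dir, mf$image[i]), file.path(dir, mf$mask[i])))
  structure(list(pairs = pairs, split = mf$split), class = "seg_dataset")
}

#' Save / load a fitted segmentation model
#'
#' Checkpoints are single files holding the layer stack with weights, the
#' model configuration, the RFF parameters and the training history.
#'
#' @param object a fitted `"kernseg_fit"`.
#' @param path checkpoint file path.
#' @return `seg_load()` returns the restored `"kernseg_fit"`.
#' @export
seg_save <- function(object, path) {
  if (!inherits(object, "kernseg_fit")) stop("'object' must be a kernseg_fit")
  saveRDS(object, path)
  invisible(path)
}

#' @rdname seg_save
#' @export
seg_load <- function(path) {
  obj <- readRDS(path)
  if (!inherits(obj, "kernseg_fit")) stop("checkpoint does not hold a kernseg_fit")
  obj
}

# Jet-style colormap used for heatmap overlays, matching the usual rendering
# of class-activation maps.
jet_colors <- function(n = 256L) {
  grDevices::colorRampPalette(c("#00007F", "blue", "#007FFF", "cyan", "#7FFF7F",
                                "yellow", "#FF7F00", "red", "#7F0000"))(n)
}

#' Write a saliency heatmap as raw values and a Jet-colormap overlay
#'
#' @param map normalized saliency map in \[0, 1\].
#' @param image grayscale image the map explains.
#' @param path_prefix files `<prefix>_raw.tsv` and `<prefix>_overlay.png` are
#'   written.
#' @param alpha overlay opacity of the heatmap.
#' @return Invisibly, the overlay file path.
#' @export
write_heatmap <- function(map, image, path_prefix, alpha = 0.5) {
  utils::write.table(map, paste0(path_prefix, "_raw.tsv"),
                     row.names = FALSE, col.names = FALSE, sep = "\t")
  pal <- jet_colors()
  idx <- pmin(pmax(round(map * 255) + 1L, 1L), 256L)
  rgb <- grDevices::col2rgb(pal[idx]) / 255
  H <- nrow(map); W <- ncol(map)
  over <- array(0, c(H, W, 3L))
  for (k in 1:3)
    over[, , k] <- (1 - alpha) * image + alpha * matrix(rgb[k, ], H, W)
  out <- paste0(path_prefix, "_overlay.png")
  png::writePNG(pmin(pmax(over, 0), 1), out)
  invisible(out)
}
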