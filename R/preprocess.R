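#' Threshold-segmentation configuration
#'
#' @param threshold grayscale segmentation threshold in (0, 1); 0.4 separates
#'   bright seeds from the near-black cloth background.
#' @param min_region_area smallest connected-region area (pixels) kept as a
#'   seed; rejects speckle.
#' @param crop_padding pixels of margin added around each region's bounding
#'   box before cropping.
#' @param output_size side of the square resized crop.
#' @return list of class `"preprocess_config"`.
#' @export
preprocess_config <- function(threshold = 0.4, min_region_area = 50L,
                              crop_padding = 4L, output_size = 224L) {
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0, 1), got %g", threshold)
  if (min_region_area < 1) stopf("min_region_area must be >= 1")
  structure(list(threshold = threshold,
                 min_region_area = as.integer(min_region_area),
                 crop_padding = as.integer(crop_padding),
                 output_size = as.integer(output_size)),
            class = "preprocess_config")
}

#' Convert an RGB image to grayscale
#'
#' Uses ITU-R BT.601 luma weights on `[0, 1]`-scaled channels:
#' `0.299 R + 0.587 G + 0.114 B`.
#'
#' @param img H x W x 3 numeric array in `[0, 1]`.
#' @return H x W numeric matrix in `[0, 1]`.
#' @export
to_grayscale <- function(img) {
  assert_rgb(img)
  0.299 * img[, , 1] + 0.587 * img[, , 2] + 0.114 * img[, , 3]
}

#' Binarize a grayscale image at a fixed threshold
#'
#' Pixels below the threshold become 0 (background), pixels at or above it
#' become 1 (seed). The boundary case (exactly equal) maps to 1.
#' Idempotent on its own output for any threshold in (0, 1].
#'
#' @param gray H x W numeric matrix in `[0, 1]`.
#' @param threshold fraction in (0, 1).
#' @return H x W integer matrix of 0/1 values (a binary mask).
#' @export
binarize <- function(gray, threshold = 0.4) {
  if (threshold <= 0 || threshold >= 1)
    stopf("threshold must lie strictly inside (0, 1), got %g", threshold)
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray >= threshold] <- 1L
  m
}

#' Apply a binary mask to an RGB image
#'
#' Pixel-wise multiplication: foreground pixels are kept, background pixels
#' are set to black.
#'
#' @param img H x W x 3 numeric array.
#' @param mask H x W binary (0/1) matrix of the same spatial size.
#' @return masked H x W x 3 array.
#' @export
apply_mask <- function(img, mask) {
  assert_rgb(img)
  if (!all(dim(img)[1:2] == dim(mask)))
    stopf("image (%dx%d) and mask (%dx%d) sizes differ",
          dim(img)[1], dim(img)[2], nrow(mask), ncol(mask))
  img * as.numeric(mask)   # recycles across the 3 channels (column-major)
}

#' Extract per-seed crops from a masked image
#'
#' Labels connected foreground regions (8-connectivity), discards regions
#' smaller than `min_region_area`, and returns one crop per remaining region:
#' the region's bounding box grown by `crop_padding` (clamped to the image),
#' resized bilinearly to `output_size` x `output_size`. Each crop carries its
#' source bounding box as attribute `"bbox"`.
#'
#' @param img masked H x W x 3 array (background already black).
#' @param mask H x W binary matrix.
#' @param config a [preprocess_config()].
#' @return list of crops (possibly empty), in label order.
#' @export
extract_seed_crops <- function(img, mask, config = preprocess_config()) {
  assert_rgb(img)
  storage.mode(mask) <- "integer"
  lab <- .label_components(mask)
  n <- max(lab)
  crops <- list()
  if (n == 0) return(crops)
  areas <- tabulate(lab[lab > 0], nbins = n)
  H <- nrow(mask); W <- ncol(mask); p <- config$crop_padding
  for (i in seq_len(n)) {
    if (areas[i] < config$min_region_area) next
    w <- which(lab == i, arr.ind = TRUE)
    h0 <- max(1L, min(w[, 1]) - p); h1 <- min(H, max(w[, 1]) + p)
    w0 <- max(1L, min(w[, 2]) - p); w1 <- min(W, max(w[, 2]) + p)
    crop <- img[h0:h1, w0:w1, , drop = FALSE]
    out <- EBImage::resize(crop, w = config$output_size,
                           h = config$output_size)
    out <- pmin(pmax(array(out, dim = c(config$output_size,
                                        config$output_size, 3L)), 0), 1)
    attr(out, "bbox") <- c(h0 = h0, h1 = h1, w0 = w0, w1 = w1)
    crops[[length(crops) + 1L]] <- out
  }
  crops
}

#' Segment a scene photograph into per-seed crops
#'
#' The full pipeline of one image: grayscale, fixed-threshold
#' binarization, pixel-wise masking, connected-region extraction and
#' per-region cropping.
#'
#' @param img H x W x 3 RGB array in `[0, 1]`.
#' @param config a [preprocess_config()].
#' @return list with `crops`, `mask`, and `gray`.
#' @export
preprocess_scene <- function(img, config = preprocess_config()) {
  gray <- to_grayscale(img)
  mask <- binarize(gray, config$threshold)
  masked <- apply_mask(img, mask)
  list(crops = extract_seed_crops(masked, mask, config), mask = mask,
       gray = gray)
}

#' Segment every image in a directory tree
#'
#' Reads PNG/JPEG scene photographs from `in_dir` (one subdirectory per class
#' label), segments each into per-seed crops, writes crops as PNG under
#' `out_dir/<label>/` and returns a crop manifest.
#'
#' @param in_dir input directory with one subdirectory per class.
#' @param out_dir output directory for crops.
#' @param config a [preprocess_config()].
#' @return manifest data.frame (`path`, `label`, `split`, `origin`).
#' @export
preprocess_dir <- function(in_dir, out_dir, config = preprocess_config()) {
  if (!dir.exists(in_dir)) stopf("input directory '%s' does not exist", in_dir)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  classes <- list.dirs(in_dir, recursive = FALSE)
  rows <- list()
  for (cdir in classes) {
    label <- basename(cdir)
    odir <- file.path(out_dir, label)
    if (!dir.exists(odir)) dir.create(odir)
    files <- list.files(cdir, pattern = "\\.(png|jpe?g)$", ignore.case = TRUE,
                        full.names = TRUE)
    for (f in files) {
      img <- read_image(f)
      res <- preprocess_scene(img, config)
      base <- tools::file_path_sans_ext(basename(f))
      for (k in seq_along(res$crops)) {
        p <- file.path(odir, sprintf("%s_seed%03d.png", base, k))
        png::writePNG(res$crops[[k]], p)
        rows[[length(rows) + 1L]] <-
          data.frame(path = p, label = label, split = NA_character_,
                     origin = "original")
      }
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), label = character(),
               split = character(), origin = character())
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  man
}

#' Read an image file as an H x W x 3 array in [0, 1]
#'
#' PNG via the png package; other formats via EBImage (whose x/y axis order
#' is transposed relative to row/column order and is corrected here). Alpha
#' channels are dropped; grayscale is replicated to 3 channels.
#'
#' @param path image file path.
#' @return H x W x 3 numeric array.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stopf("image file '%s' does not exist", path)
  if (grepl("\\.png$", path, ignore.case = TRUE)) {
    img <- png::readPNG(path)
  } else {
    img <- EBImage::imageData(EBImage::readImage(path))
    img <- if (length(dim(img)) == 2L) t(img) else aperm(img, c(2, 1, 3))
  }
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), dim = c(dim(img), 3L))
  if (dim(img)[3] > 3L) img <- img[, , 1:3, drop = FALSE]
  img
}
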