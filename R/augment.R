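#' Offline augmentation configuration
#'
#' The four enhancement operators applied to every effective image: doubling
#' brightness, additive Gaussian noise (mean 1, sd 1.5 on the 0-255 intensity
#' scale — a tiny perturbation), mirroring, and rotation. Mirror axis and
#' rotation angle default to horizontal / 90 degrees.
#'
#' @param brightness_factor multiplicative brightness gain (> 0).
#' @param noise_mean,noise_sd Gaussian noise parameters in 0-255 gray-level
#'   units (`noise_sd >= 0`).
#' @param mirror_axis `"horizontal"` or `"vertical"`.
#' @param rotation_angle degrees.
#' @param rng_seed base seed for per-image noise draws.
#' @return list of class `"augment_config"`.
#' @export
augment_config <- function(brightness_factor = 2, noise_mean = 1,
                           noise_sd = 1.5, mirror_axis = "horizontal",
                           rotation_angle = 90, rng_seed = 0L) {
  if (brightness_factor <= 0) stopf("brightness_factor must be > 0")
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  mirror_axis <- match.arg(mirror_axis, c("horizontal", "vertical"))
  structure(list(brightness_factor = brightness_factor,
                 noise_mean = noise_mean, noise_sd = noise_sd,
                 mirror_axis = mirror_axis, rotation_angle = rotation_angle,
                 rng_seed = as.integer(rng_seed)),
            class = "augment_config")
}

#' Augmentation operators
#'
#' `brighten()` multiplies every pixel by `factor` and clips to `[0, 1]`.
#' `add_gaussian_noise()` adds per-pixel Gaussian noise specified in 0-255
#' units (converted internally to the `[0, 1]` scale), clipping afterwards;
#' deterministic given `seed`. `mirror_image()` flips left-right
#' (`"horizontal"`, column 1 moves to column W) or up-down (`"vertical"`).
#' `rotate_image()` rotates clockwise (viewed with row 1 at top); multiples
#' of 90 degrees on square images are exact index permutations, anything else
#' is interpolated on the same canvas (EBImage).
#'
#' @param img H x W x 3 numeric array in `[0, 1]` (mirror/rotate also accept
#'   H x W matrices).
#' @param factor brightness multiplier (> 0).
#' @param mean,sd noise parameters in 0-255 units.
#' @param seed integer seed for the noise draw (`NULL` = current RNG stream).
#' @param axis mirror axis.
#' @param angle rotation angle, degrees.
#' @return transformed image of the same shape.
#' @export
brighten <- function(img, factor = 2) {
  if (factor <= 0) stopf("brightness factor must be > 0, got %g", factor)
  pmin(pmax(img * factor, 0), 1)
}

#' @rdname brighten
#' @export
add_gaussian_noise <- function(img, mean = 1, sd = 1.5, seed = NULL) {
  if (sd < 0) stopf("noise sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  noise <- array(rnorm(length(img), mean, sd) / 255, dim = dim(img))
  pmin(pmax(img + noise, 0), 1)
}

#' @rdname brighten
#' @export
mirror_image <- function(img, axis = "horizontal") {
  axis <- match.arg(axis, c("horizontal", "vertical"))
  nd <- length(dim(img))
  if (axis == "horizontal") {
    if (nd == 2L) img[, ncol(img):1] else img[, dim(img)[2]:1, , drop = FALSE]
  } else {
    if (nd == 2L) img[nrow(img):1, ] else img[dim(img)[1]:1, , , drop = FALSE]
  }
}

#' @rdname brighten
#' @export
rotate_image <- function(img, angle = 90) {
  a <- angle %% 360
  if (a == 0) return(img)
  nd <- length(dim(img))
  H <- dim(img)[1]; W <- dim(img)[2]
  if (a %% 90 == 0 && H == W) {
    # 90 degrees clockwise: out[i, j] = in[H + 1 - j, i]
    rot_cw <- function(x) {
      if (length(dim(x)) == 2L) t(x[H:1, ]) else
        aperm(x[H:1, , , drop = FALSE], c(2, 1, 3))
    }
    out <- img
    for (i in seq_len(a / 90)) out <- rot_cw(out)
    return(out)
  }
  # arbitrary angle: interpolate on the same canvas; EBImage's first axis is x
  arr <- if (nd == 2L) t(img) else aperm(img, c(2, 1, 3))
  rot <- EBImage::rotate(EBImage::Image(arr,
                                        colormode = if (nd == 2L) "Grayscale" else "Color"),
                         -a, output.dim = c(W, H), bg.col = "black")
  rot <- EBImage::imageData(rot)
  out <- if (nd == 2L) t(rot) else aperm(rot, c(2, 1, 3))
  pmin(pmax(out, 0), 1)
}

#' Expand a manifest five-fold with the four enhancement operators
#'
#' Every input row yields itself plus four variants (brightness, noise,
#' mirror, rotation); the `origin` column records the producing operator.
#' With `out_dir` given, variant images are computed and written to
#' `out_dir/<label>/` and the returned paths point at them; without it the
#' expansion is planned only (manifest bookkeeping, e.g. for split-size
#' arithmetic) and no files are touched.
#'
#' @param manifest data.frame with `path`, `label`, and optionally `split`,
#'   `origin` columns.
#' @param config an [augment_config()].
#' @param out_dir directory for materialised variant images, or `NULL`.
#' @return manifest with `5 * nrow(manifest)` rows.
#' @export
enhance_dataset <- function(manifest, config = augment_config(),
                            out_dir = NULL) {
  if (nrow(manifest) == 0) return(manifest)
  ops <- c("brightness", "noise", "mirror", "rotation")
  materialize <- !is.null(out_dir)
  if (materialize) {
    missing <- manifest$path[!file.exists(manifest$path)]
    if (length(missing))
      stopf("missing source images:\n%s", paste(missing, collapse = "\n"))
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stopf("cannot create output directory '%s'", out_dir)
  }
  out <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    base <- tools::file_path_sans_ext(basename(row$path))
    vp <- if (materialize) {
      odir <- file.path(out_dir, row$label)
      if (!dir.exists(odir)) dir.create(odir, recursive = TRUE)
      file.path(odir, sprintf("%s_%s.png", base, ops))
    } else {
      file.path(dirname(row$path), sprintf("%s_%s.png", base, ops))
    }
    if (materialize) {
      img <- read_image(row$path)
      png::writePNG(brighten(img, config$brightness_factor), vp[1])
      png::writePNG(add_gaussian_noise(img, config$noise_mean, config$noise_sd,
                                       seed = derive_seed(config$rng_seed, i)),
                    vp[2])
      png::writePNG(mirror_image(img, config$mirror_axis), vp[3])
      png::writePNG(rotate_image(img, config$rotation_angle), vp[4])
    }
    out[[i]] <- data.frame(
      path = c(row$path, vp),
      label = row$label,
      split = row$split %||% NA_character_,
      origin = c("original", ops))
  }
  do.call(rbind, out)
}

#' Split ratios for train / validation / test
#'
#' @param train,val,test fractions summing to 1 (default 8:1:1).
#' @return list of class `"split_ratios"`.
#' @export
split_ratios <- function(train = 0.8, val = 0.1, test = 0.1) {
  if (abs(train + val + test - 1) > 1e-9)
    stopf("split ratios must sum to 1 (got %g)", train + val + test)
  structure(list(train = train, val = val, test = test),
            class = "split_ratios")
}

#' Stratified random split of a manifest
#'
#' Within every class of size N: `train = floor(train_ratio * N)`,
#' `val = floor(val_ratio * N)`, and the test set takes the remainder — the
#' rounding convention recovered from the published per-class counts (e.g.
#' N = 4405 gives 3524/440/441). Assignment is a seeded random shuffle,
#' stratified by class; no image lands in two splits.
#'
#' @param manifest data.frame with `path`, `label` columns.
#' @param ratios a [split_ratios()].
#' @param seed integer seed.
#' @return list with `train`, `val`, `test` manifests (the `split` column is
#'   filled in each).
#' @export
split_dataset <- function(manifest, ratios = split_ratios(), seed = 0L) {
  if (!inherits(ratios, "split_ratios")) stopf("ratios must be split_ratios()")
  parts <- list(train = NULL, val = NULL, test = NULL)
  labs <- unique(manifest$label)
  for (ci in seq_along(labs)) {
    idx <- which(manifest$label == labs[ci])
    n <- length(idx)
    n_tr <- floor(ratios$train * n + 1e-9)
    n_va <- floor(ratios$val * n + 1e-9)
    n_te <- n - n_tr - n_va
    set.seed(derive_seed(seed, ci))
    idx <- sample(idx)
    tr <- idx[seq_len(n_tr)]
    va <- idx[seq_len(n_va) + n_tr]
    te <- idx[seq_len(n_te) + n_tr + n_va]
    for (nm in c("train", "val", "test")) {
      sel <- switch(nm, train = tr, val = va, test = te)
      if (length(sel)) {
        m <- manifest[sel, ]
        m$split <- nm
        parts[[nm]] <- rbind(parts[[nm]], m)
      }
    }
  }
  empty <- manifest[0, ]
  lapply(parts, function(p) if (is.null(p)) empty else p)
}
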