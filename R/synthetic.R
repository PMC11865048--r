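#' Specification of a synthetic seed photograph
#'
#' Describes the scene the generator emulates: bright ellipsoidal seeds laid
#' out on a grid over a near-black cloth background, photographed from above.
#' Per-class appearance (hue, size, brightness, texture) makes the classes
#' separable while keeping every seed brighter than the 0.4 segmentation
#' threshold and the background well below it, so ground truth is recoverable
#' by thresholding.
#'
#' @param image_size `c(H, W)` in pixels.
#' @param grid `c(rows, cols)` of seed positions; bounding boxes of placed
#'   seeds are disjoint by construction (no overlapping or adhering seeds).
#' @param background_level background gray value in `[0, 0.2]`.
#' @param n_classes number of seed varieties.
#' @param class_appearance data.frame with one row per class and columns
#'   `hue_mean`, `hue_sd`, `saturation`, `axis_a`, `axis_a_sd`, `axis_b`,
#'   `axis_b_sd` (ellipse semi-axes, pixels), `brightness` (in `(0.4, 1]`),
#'   `texture_sd` (multiplicative per-pixel noise amplitude). `NULL` gives a
#'   default palette of well-separated hues.
#' @param rng_seed integer base seed; per-image sub-seeds are derived from it
#'   with [derive_seed()].
#' @return list of class `"scene_spec"`.
#' @export
scene_spec <- function(image_size = c(224L, 224L), grid = c(1L, 1L),
                       background_level = 0.05, n_classes = 8L,
                       class_appearance = NULL, rng_seed = 0L) {
  if (background_level < 0 || background_level > 0.2)
    stopf("background_level must lie in [0, 0.2], got %g", background_level)
  if (n_classes < 1) stopf("n_classes must be >= 1")
  if (is.null(class_appearance))
    class_appearance <- default_class_appearance(n_classes, image_size, grid)
  need <- c("hue_mean", "hue_sd", "saturation", "axis_a", "axis_a_sd",
            "axis_b", "axis_b_sd", "brightness", "texture_sd")
  miss <- setdiff(need, names(class_appearance))
  if (length(miss)) stopf("class_appearance lacks columns: %s",
                          paste(miss, collapse = ", "))
  if (nrow(class_appearance) != n_classes)
    stopf("class_appearance must have %d rows", n_classes)
  if (any(class_appearance$brightness <= 0.4))
    stopf("seed brightness means must exceed the 0.4 segmentation threshold")
  structure(list(image_size = as.integer(image_size), grid = as.integer(grid),
                 background_level = background_level,
                 n_classes = as.integer(n_classes),
                 class_appearance = class_appearance,
                 rng_seed = as.integer(rng_seed)),
            class = "scene_spec")
}

default_class_appearance <- function(n_classes, image_size, grid) {
  cell <- min(image_size / grid)
  a <- 0.30 * cell                       # semi-major axis, pixels
  data.frame(
    hue_mean = (seq_len(n_classes) - 1) / n_classes,
    hue_sd = 0.012,
    saturation = 0.45,
    axis_a = a, axis_a_sd = 0.06 * a,
    axis_b = 0.72 * a, axis_b_sd = 0.05 * a,
    brightness = 0.62 + 0.25 * (seq_len(n_classes) %% 3) / 2,
    texture_sd = 0.04
  )
}

luma <- function(rgb) 0.299 * rgb[1] + 0.587 * rgb[2] + 0.114 * rgb[3]

#' Generate one synthetic seed scene
#'
#' Renders `n_seeds` anti-aliased filled ellipses of one class on a dark
#' background, on the grid laid out in `spec`. Deterministic given `seed`
#' (the caller's RNG state is saved and restored).
#'
#' @param spec a [scene_spec()].
#' @param class_label class index in `1:n_classes`.
#' @param n_seeds number of seeds to place (at most `rows * cols`).
#' @param seed integer seed for this scene.
#' @return list with `image` (H x W x 3 in `[0, 1]`), `mask` (H x W integer
#'   0/1 ground truth) and `boxes` (data.frame of per-seed bounding boxes and
#'   ellipse parameters).
#' @export
generate_scene <- function(spec, class_label, n_seeds, seed = 0L) {
  stopifnot(inherits(spec, "scene_spec"))
  rows <- spec$grid[1]; cols <- spec$grid[2]
  if (n_seeds > rows * cols)
    stopf("n_seeds = %d exceeds grid capacity %d x %d = %d",
          n_seeds, rows, cols, rows * cols)
  if (class_label < 1 || class_label > spec$n_classes)
    stopf("class_label must lie in 1..%d", spec$n_classes)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)

  H <- spec$image_size[1]; W <- spec$image_size[2]
  ch <- H / rows; cw <- W / cols
  app <- spec$class_appearance[class_label, ]
  img <- array(pmax(spec$background_level +
                      rnorm(H * W, 0, 0.004), 0), dim = c(H, W, 3))
  mask <- matrix(0L, H, W)
  boxes <- NULL
  if (n_seeds > 0) {
    cells <- sample.int(rows * cols, n_seeds)
    for (s in seq_len(n_seeds)) {
      r <- (cells[s] - 1) %/% cols + 1
      c <- (cells[s] - 1) %% cols + 1
      a <- max(3, rnorm(1, app$axis_a, app$axis_a_sd))
      b <- max(2, rnorm(1, app$axis_b, app$axis_b_sd))
      # clamp so the (jittered) ellipse stays inside its cell: boxes disjoint
      lim <- min(ch, cw) / 2 - 2
      a <- min(a, lim); b <- min(b, lim)
      jit <- (min(ch, cw) / 2 - max(a, b) - 1)
      cy <- (r - 0.5) * ch + runif(1, -jit, jit)
      cx <- (c - 0.5) * cw + runif(1, -jit, jit)
      th <- runif(1, 0, pi)
      col_rgb <- seed_base_color(app)
      ext <- max(a, b) + 2
      h0 <- max(1L, floor(cy - ext)); h1 <- min(H, ceiling(cy + ext))
      w0 <- max(1L, floor(cx - ext)); w1 <- min(W, ceiling(cx + ext))
      hh <- h0:h1; ww <- w0:w1
      u <- outer(hh - cy, ww - cx, function(dy, dx) dx * cos(th) + dy * sin(th))
      v <- outer(hh - cy, ww - cx, function(dy, dx) -dx * sin(th) + dy * cos(th))
      d <- sqrt((u / a)^2 + (v / b)^2)
      alpha <- pmin(pmax(0.5 - (d - 1) * min(a, b), 0), 1)  # ~1 px AA edge
      inside <- d <= 1
      tex <- 1 + matrix(rnorm(length(d), 0, app$texture_sd), nrow(d))
      for (k in 1:3) {
        px <- img[hh, ww, k]
        img[hh, ww, k] <- px * (1 - alpha) +
          pmin(pmax(col_rgb[k] * tex, 0), 1) * alpha
      }
      mask[hh, ww][inside] <- 1L
      boxes <- rbind(boxes, data.frame(
        seed = s, row = r, col = c, cy = cy, cx = cx, a = a, b = b,
        angle = th, h0 = h0, h1 = h1, w0 = w0, w1 = w1))
    }
  }
  list(image = pmin(pmax(img, 0), 1), mask = mask, boxes = boxes)
}

# Base RGB of one seed; brightness lifted so luma stays above the threshold.
seed_base_color <- function(app) {
  h <- (rnorm(1, app$hue_mean, app$hue_sd)) %% 1
  v <- min(max(rnorm(1, app$brightness, 0.03), 0.5), 0.97)
  rgb <- as.numeric(col2rgb(hsv(h, app$saturation, v))) / 255
  l <- luma(rgb)
  if (l < 0.5) rgb <- pmin(rgb * (0.5 / l), 1)
  rgb
}

#' Generate a labelled synthetic seed-crop dataset on disk
#'
#' Writes `counts_per_class[i]` single-seed crop images for class `i` under
#' `out_dir/<class_name>/<index>.png` plus a `manifest.csv`, and returns the
#' manifest. Each crop is an independent scene with its own derived sub-seed,
#' so any subset is reproducible.
#'
#' @param spec a [scene_spec()]; its grid is ignored for crops (one seed per
#'   image, centred on a 1 x 1 grid).
#' @param counts_per_class non-negative integer vector, one entry per class.
#' @param out_dir output directory (created if needed).
#' @param seed integer base seed.
#' @param class_names optional class names (default `class_1` ...).
#' @return manifest data.frame with columns `path`, `label`, `split`, `origin`.
#' @export
generate_dataset <- function(spec, counts_per_class, out_dir, seed = 0L,
                             class_names = NULL) {
  stopifnot(inherits(spec, "scene_spec"))
  if (length(counts_per_class) != spec$n_classes)
    stopf("counts_per_class must have %d entries", spec$n_classes)
  if (any(counts_per_class < 0)) stopf("counts must be non-negative")
  class_names <- class_names %||% sprintf("class_%d", seq_len(spec$n_classes))
  crop_spec <- spec
  crop_spec$grid <- c(1L, 1L)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    stopf("cannot create output directory '%s'", out_dir)
  rows <- list(); idx <- 0L
  for (ci in seq_len(spec$n_classes)) {
    n <- counts_per_class[ci]
    if (n == 0) next
    cdir <- file.path(out_dir, class_names[ci])
    if (!dir.exists(cdir) && !dir.create(cdir))
      stopf("cannot create class directory '%s'", cdir)
    for (j in seq_len(n)) {
      idx <- idx + 1L
      sc <- generate_scene(crop_spec, ci, 1L, seed = derive_seed(seed, idx))
      p <- file.path(cdir, sprintf("%05d.png", j))
      png::writePNG(sc$image, p)
      rows[[idx]] <- data.frame(path = p, label = class_names[ci],
                                split = NA_character_, origin = "original")
    }
  }
  man <- if (length(rows)) do.call(rbind, rows) else
    data.frame(path = character(), label = character(),
               split = character(), origin = character())
  write.csv(man, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  man
}
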