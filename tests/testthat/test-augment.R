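test_that("brighten multiplies and clips", {
  img <- array(c(0, 100, 200, 255) / 255, dim = c(2, 2, 3))
  expect_identical(brighten(img, 1), img)
  expect_true(all(brighten(array(0, c(2, 2, 3)), 2) == 0))
  out <- brighten(img, 2)
  expect_equal(out[1, 2, 1], 1)                 # 200/255 * 2 clips to 1
  expect_equal(out[2, 1, 1], 200 / 255)
  expect_error(brighten(img, 0), "factor")
})

test_that("gaussian noise respects its degenerate and statistical contracts", {
  img <- array(runif(16 * 16 * 3, 0.2, 0.6), dim = c(16, 16, 3))
  expect_equal(add_gaussian_noise(img, 0, 0, seed = 1), img)
  inc <- add_gaussian_noise(img, 1, 0, seed = 1)
  expect_equal(inc, pmin(img + 1 / 255, 1))
  # law of large numbers: mean increment ~ mean/255 within 3 standard errors
  big <- array(runif(128 * 128 * 3, 0.3, 0.6), dim = c(128, 128, 3))
  out <- add_gaussian_noise(big, 1, 1.5, seed = 7)
  d <- out - big
  se <- (1.5 / 255) / sqrt(length(d))
  expect_lt(abs(mean(d) - 1 / 255), 3 * se)
  # determinism
  expect_identical(out, add_gaussian_noise(big, 1, 1.5, seed = 7))
})

test_that("mirroring is an involution with correct index bookkeeping", {
  img <- array(runif(5 * 7 * 3), dim = c(5, 7, 3))
  expect_identical(mirror_image(mirror_image(img)), img)
  m <- mirror_image(img, "horizontal")
  expect_identical(m[, 7, ], img[, 1, ])        # first column -> last
  v <- mirror_image(img, "vertical")
  expect_identical(v[5, , ], img[1, , ])
  sym <- img
  sym[, , ] <- 0.5
  expect_identical(mirror_image(sym), sym)
})

test_that("rotation by multiples of 90 degrees is exact", {
  img <- array(runif(4 * 4 * 3), dim = c(4, 4, 3))
  expect_identical(rotate_image(img, 0), img)
  r <- img
  for (i in 1:4) r <- rotate_image(r, 90)
  expect_identical(r, img)
  # clockwise convention on a marked 3x3: out[i, j] = in[H + 1 - j, i]
  m <- array(0, dim = c(3, 3, 3)); m[1, 1, ] <- 1   # top-left marker
  r1 <- rotate_image(m, 90)
  expect_equal(r1[1, 3, 1], 1)                  # moves to top-right
  expect_equal(sum(r1), 3)
})

test_that("arbitrary-angle rotation keeps the canvas size", {
  img <- array(runif(8 * 6 * 3), dim = c(8, 6, 3))
  out <- rotate_image(img, 30)
  expect_equal(dim(out), dim(img))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("enhance_dataset is size-exact and labels provenance", {
  expect_equal(nrow(enhance_dataset(virtual_manifest(c(0, 0)))), 0)
  man <- virtual_manifest(c(3, 2))
  out <- enhance_dataset(man)
  expect_equal(nrow(out), 5 * nrow(man))
  expect_equal(as.vector(table(out$origin)[c("original", "brightness",
                                             "noise", "mirror", "rotation")]),
               rep(5L, 5))
  # per published class sizes: 1034 -> 5170, 881 -> 4405
  expect_equal(nrow(enhance_dataset(virtual_manifest(1034))), 5170)
  expect_equal(nrow(enhance_dataset(virtual_manifest(881))), 4405)
})

test_that("enhance_dataset materializes variant images on disk", {
  dir <- withr::local_tempdir()
  spec <- scene_spec(image_size = c(16, 16), n_classes = 2, rng_seed = 3)
  man <- generate_dataset(spec, c(2L, 1L), file.path(dir, "src"), seed = 3)
  out <- enhance_dataset(man, augment_config(), out_dir = file.path(dir, "aug"))
  expect_equal(nrow(out), 15)
  expect_true(all(file.exists(out$path)))
  img <- read_image(out$path[out$origin == "mirror"][1])
  expect_equal(dim(img), c(16L, 16L, 3L))
  bad <- man; bad$path[1] <- file.path(dir, "nope.png")
  expect_error(enhance_dataset(bad, augment_config(),
                               out_dir = file.path(dir, "aug2")), "nope.png")
})

test_that("stratified split reproduces the published per-class arithmetic", {
  man <- virtual_manifest(effective_counts * 5L, seed_class_names)
  sp <- split_dataset(man, split_ratios(), seed = 1)
  sizes <- function(m) sapply(seed_class_names,
                              function(l) sum(m$label == l))
  expect_equal(unname(sizes(sp$train)),
               c(4136, 3524, 3356, 3440, 3668, 2740, 3232, 3816))
  expect_equal(unname(sizes(sp$val)), c(517, 440, 419, 430, 458, 342, 404, 477))
  expect_equal(unname(sizes(sp$test)), c(517, 441, 420, 430, 459, 343, 404, 477))
  expect_equal(nrow(sp$train), 27912)
  expect_equal(nrow(sp$val), 3487)
  expect_equal(nrow(sp$test), 3491)
  # partition: no duplicates, nothing lost
  all_paths <- c(sp$train$path, sp$val$path, sp$test$path)
  expect_equal(sort(all_paths), sort(man$path))
})

test_that("split handles small classes and bad ratios", {
  sp <- split_dataset(virtual_manifest(10), split_ratios(), seed = 2)
  expect_equal(sapply(sp, nrow), c(train = 8L, val = 1L, test = 1L))
  expect_error(split_ratios(0.8, 0.15, 0.1), "sum to 1")
  expect_error(split_dataset(virtual_manifest(10), list(train = 0.8)),
               "split_ratios")
})
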