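test_that("grayscale conversion uses BT.601 luma on [0,1] channels", {
  black <- array(0, dim = c(4, 4, 3))
  white <- array(1, dim = c(4, 4, 3))
  red <- array(rep(c(1, 0, 0), each = 16), dim = c(4, 4, 3))
  expect_true(all(to_grayscale(black) == 0))
  expect_equal(max(abs(to_grayscale(white) - 1)), 0, tolerance = 1e-12)
  expect_equal(unique(as.vector(to_grayscale(red))), 0.299)
  expect_error(to_grayscale(array(0, dim = c(4, 4, 2))), "RGB")
})

test_that("binarize applies the threshold rule with boundary at 1", {
  g <- matrix(c(0.39, 0.4, 0.41, 0), 2, 2)
  m <- binarize(g, 0.4)
  expect_identical(as.vector(m), c(0L, 1L, 1L, 0L))
  expect_true(all(binarize(matrix(0, 3, 3), 0.4) == 0L))
  expect_error(binarize(g, 0), "threshold")
  expect_error(binarize(g, 1.2), "threshold")
})

test_that("binarize is idempotent on its own output", {
  sc <- make_test_scene(n_seeds = 7, seed = 2)
  m1 <- binarize(to_grayscale(sc$image), 0.4)
  m2 <- binarize(m1 * 1.0, 0.4)
  expect_identical(m1, m2)
})

test_that("apply_mask keeps foreground and zeroes background", {
  sc <- make_test_scene(n_seeds = 5, seed = 13)
  img <- sc$image
  ones <- matrix(1L, nrow(sc$mask), ncol(sc$mask))
  expect_identical(apply_mask(img, ones), img)
  zeros <- matrix(0L, nrow(sc$mask), ncol(sc$mask))
  expect_true(all(apply_mask(img, zeros) == 0))
  masked <- apply_mask(img, sc$mask)
  bg <- sc$mask == 0
  for (k in 1:3) expect_true(all(masked[, , k][bg] == 0))
  expect_error(apply_mask(img, ones[1:10, ]), "differ")
})

test_that("extract_seed_crops returns one crop per sufficiently large region", {
  sc <- make_test_scene(n_seeds = 12, seed = 31)
  cfg <- preprocess_config(output_size = 32L)
  masked <- apply_mask(sc$image, sc$mask)
  crops <- extract_seed_crops(masked, sc$mask, cfg)
  expect_length(crops, 12)
  expect_equal(dim(crops[[1]]), c(32L, 32L, 3L))
  # empty mask -> empty list, not an error
  empty <- matrix(0L, 160, 160)
  expect_length(extract_seed_crops(masked, empty, cfg), 0)
  # a region below min_region_area is filtered out
  tiny <- matrix(0L, 160, 160); tiny[5:6, 5:6] <- 1L
  expect_length(extract_seed_crops(masked, tiny, cfg), 0)
})

test_that("a full 10 x 20 grid scene yields 200 crops", {
  spec <- scene_spec(image_size = c(250, 500), grid = c(10, 20),
                     n_classes = 1, rng_seed = 4)
  sc <- generate_scene(spec, 1, 200, seed = 4)
  res <- preprocess_scene(sc$image, preprocess_config(output_size = 16L,
                                                      min_region_area = 20L))
  expect_length(res$crops, 200)
  expect_identical(count_components_oracle(res$mask), 200L)
})

test_that("mask -> apply -> grayscale -> binarize round-trips on scenes", {
  sc <- make_test_scene(n_seeds = 9, seed = 17)
  mask <- binarize(to_grayscale(sc$image), 0.4)
  masked <- apply_mask(sc$image, mask)
  again <- binarize(to_grayscale(masked), 0.4)
  expect_identical(mask, again)
})

test_that("preprocess_dir segments a directory tree into crops", {
  ind <- withr::local_tempdir(); outd <- withr::local_tempdir()
  spec <- scene_spec(image_size = c(80, 80), grid = c(2, 2), n_classes = 2,
                     rng_seed = 6)
  for (ci in 1:2) {
    d <- file.path(ind, sprintf("class_%d", ci)); dir.create(d)
    for (j in 1:2) {
      sc <- generate_scene(spec, ci, 3, seed = 10 * ci + j)
      png::writePNG(sc$image, file.path(d, sprintf("%d.png", j)))
    }
  }
  man <- preprocess_dir(ind, outd, preprocess_config(output_size = 16L,
                                                     min_region_area = 20L))
  expect_equal(nrow(man), 2 * 2 * 3)
  expect_true(all(file.exists(man$path)))
  expect_setequal(unique(man$label), c("class_1", "class_2"))
})
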