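test_that("confusion matrix orients rows as actual, columns as predicted", {
  cm <- confusion_matrix(c(1L, 2L, 3L), c(1L, 2L, 3L), 3)
  expect_true(all(cm == diag(3)))
  cm2 <- confusion_matrix(predicted = c(2L, 2L), actual = c(1L, 2L), 2)
  expect_equal(cm2[1, 2], 1L)
  expect_equal(cm2[2, 2], 1L)
  expect_equal(cm2[1, 1] + cm2[2, 1], 0L)
  expect_error(confusion_matrix(c(1L, 9L), c(1L, 2L), 3), "range")
})

test_that("row sums equal class frequencies (counting oracle)", {
  set.seed(12)
  actual <- sample(1:8, 1000, replace = TRUE)
  pred <- sample(1:8, 1000, replace = TRUE)
  cm <- confusion_matrix(pred, actual, 8)
  expect_equal(unname(rowSums(cm)), unname(as.vector(table(actual))))
  expect_equal(unname(colSums(cm)), unname(as.vector(table(pred))))
  m <- metrics_from_confusion(cm)
  expect_equal(m$accuracy, mean(pred == actual))
})

test_that("metrics reproduce the tabulated formulas", {
  expect_equal(round(f1_score(0.937, 0.950), 3), 0.943)
  ident <- diag(5L) * 3L
  m <- metrics_from_confusion(ident)
  expect_true(all(m$per_class$precision == 1) && all(m$per_class$recall == 1))
  expect_equal(m$accuracy, 1)
  bin <- matrix(c(1L, 1L, 1L, 1L), 2, 2)       # TP=FP=FN=TN=1 for each class
  mb <- metrics_from_confusion(bin)
  expect_equal(mb$per_class$precision, c(0.5, 0.5))
  expect_equal(mb$per_class$recall, c(0.5, 0.5))
  expect_equal(mb$per_class$f1, c(0.5, 0.5))
  expect_equal(mb$per_class$acc, c(0.5, 0.5))
})

test_that("published per-class P/R pairs re-derive their printed F1", {
  p <- c(0.937, 0.940, 0.922, 0.950, 0.943, 0.985, 0.936, 0.912)
  r <- c(0.950, 0.891, 0.933, 0.961, 0.956, 0.973, 0.948, 0.912)
  f1_printed <- c(0.943, 0.915, 0.927, 0.955, 0.949, 0.979, 0.942, 0.912)
  expect_true(all(abs(f1_score(p, r) - f1_printed) <= 0.001))
})

test_that("F1 lies between precision and recall; macro is the class mean", {
  set.seed(13)
  for (i in 1:10) {
    cm <- matrix(rpois(16, 5), 4, 4)
    m <- metrics_from_confusion(cm)
    ok <- !m$per_class$undefined
    expect_true(all(m$per_class$f1[ok] >= pmin(m$per_class$precision,
                                               m$per_class$recall)[ok] - 1e-12))
    expect_true(all(m$per_class$f1[ok] <= pmax(m$per_class$precision,
                                               m$per_class$recall)[ok] + 1e-12))
    expect_equal(unname(m$macro["f1"]), mean(m$per_class$f1))
  }
})

test_that("zero-denominator classes report 0 with a flag and warning", {
  cm <- matrix(0L, 3, 3)
  cm[1, 1] <- 5L; cm[2, 1] <- 2L                 # class 3 absent, never predicted
  expect_warning(m <- metrics_from_confusion(cm), "reported as 0")
  expect_true(m$per_class$undefined[3])
  expect_equal(m$per_class$f1[3], 0)
})

test_that("grad-cam highlights the analytically active region", {
  # toy model: one 3x3 conv (2 channels) + GAP/linear head, hand-set weights
  conv <- seednet:::new_conv_layer(3, 2, 3, stride = 1, pad = 1)
  conv$params$w[] <- 0
  conv$params$w[2, 2, , 1] <- 1          # channel 1 = luminance passthrough
  cls <- seednet:::new_classifier_layer(2, 2)
  cls$params$w[] <- 0
  cls$params$w[1, 1] <- 1                # class 1 reads channel 1
  cls$params$b[] <- 0
  toy <- structure(list(layers = list(conv = conv, classifier = cls),
                        tap_default = 1L,
                        spec = list(input_size = 5L)),
                   class = "seednet_model")
  img <- array(0, dim = c(5, 5, 3))
  img[2, 4, ] <- 1                       # single bright pixel
  hm <- grad_cam(toy, img, target_class = 1)
  expect_true(all(hm >= 0 & hm <= 1))
  peak <- which(hm == max(hm), arr.ind = TRUE)
  expect_true(any(abs(peak[, 1] - 2) <= 1 & abs(peak[, 2] - 4) <= 1))
  # degenerate: all-zero input through the bias-free model -> flat zero map
  hm0 <- grad_cam(toy, array(0, dim = c(5, 5, 3)), 1)
  expect_true(all(hm0 == 0))
  expect_error(grad_cam(toy, img, 5), "target_class")
})

test_that("grad-cam works on the real backbone at reduced size", {
  set.seed(14)
  m <- build_network(network_spec(3, 16, "hp", stages = tiny_stages(),
                                  stem_channels = 4, head_channels = 16))
  img <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  hm <- grad_cam(m, img, 2)
  expect_equal(dim(hm), c(16L, 16L))
  expect_true(all(hm >= 0 & hm <= 1))
  expect_error(grad_cam(m, img, 2, layer = length(m$layers)), "spatial")
})
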