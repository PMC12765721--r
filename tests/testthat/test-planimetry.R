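# Small rendered fixtures shared across segmentation tests
disclosedFixture <- function(seed, pixel_size = 0.08, coverage = 0.19) {
  spec <- syntheticSpec(edge_length = 0.25, pixel_size = pixel_size,
                        coverage_fraction = coverage, seed = seed)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  renderDisclosedImage(crown, pl, spec, seed = seed + 500)
}

test_that("green channel isolates dye contrast", {
  rgbArr <- array(0, c(2, 2, 3))
  rgbArr[1, 1, ] <- c(0, 1, 0)       # pure green
  rgbArr[1, 2, ] <- c(1, 0, 1)       # magenta, dye-like
  rgbArr[2, 1, ] <- c(0.5, 0.5, 0.5)
  img <- DisclosedImage(rgbArr)
  g <- greenChannelGray(img)
  expect_identical(g[1, 1], 255L)
  expect_identical(g[1, 2], 0L)
  expect_identical(g[2, 1], 128L)

  fx <- disclosedFixture(1)
  g <- greenChannelGray(fx$image)
  plaquepx <- fx$truth_classes > 1 & fx$image@roi_pixel_mask
  cleanpx <- fx$truth_classes == 1 & fx$image@roi_pixel_mask
  expect_lt(mean(g[plaquepx]), mean(g[cleanpx]))
})

test_that("training is reproducible and separates separable classes", {
  fx1 <- disclosedFixture(2)
  fx2 <- disclosedFixture(3)
  clf <- trainPixelClassifier(list(fx1$image), list(fx1$truth_classes),
                              seed = 7, ntree = 50)
  seg_a <- segmentDisclosed(fx2$image, clf)
  clf_b <- trainPixelClassifier(list(fx1$image), list(fx1$truth_classes),
                                seed = 7, ntree = 50)
  seg_b <- segmentDisclosed(fx2$image, clf_b)
  expect_identical(seg_a, seg_b)

  # resubstitution on its own training image is near-perfect
  seg_self <- segmentDisclosed(fx1$image, clf, min_component = 1L)
  acc <- mean(seg_self[fx1$image@roi_pixel_mask] ==
              fx1$truth_classes[fx1$image@roi_pixel_mask])
  expect_gt(acc, 0.99)

  expect_error(trainPixelClassifier(list(fx1$image),
                                    list(matrix(0L, 2, 2)), seed = 1),
               "50 labelled")
})

test_that("held-out segmentation reaches IoU 0.90 per plaque class", {
  train <- list(disclosedFixture(4), disclosedFixture(5))
  test_fx <- disclosedFixture(6)
  clf <- trainPixelClassifier(lapply(train, `[[`, "image"),
                              lapply(train, `[[`, "truth_classes"),
                              seed = 11)
  seg <- segmentDisclosed(test_fx$image, clf)
  iou <- classIoU(seg, test_fx$truth_classes)
  expect_true(all(iou >= 0.90))
})

test_that("segmentation ignores content outside the ROI mask", {
  fx <- disclosedFixture(8)
  clf <- trainPixelClassifier(list(fx$image), list(fx$truth_classes),
                              seed = 2, ntree = 50)
  img2 <- fx$image
  rgb2 <- img2@rgb
  out_px <- !img2@roi_pixel_mask
  for (k in 1:3) {
    ch <- rgb2[, , k]
    ch[out_px] <- runif(sum(out_px))    # scribble outside the ROI
    rgb2[, , k] <- ch
  }
  img2 <- DisclosedImage(rgb2, fx$image@roi_pixel_mask, "x")
  expect_identical(segmentDisclosed(fx$image, clf),
                   segmentDisclosed(img2, clf))
})

test_that("speckle filter removes small components and keeps large ones", {
  seg <- matrix(1L, 30, 30)
  seg[2:3, 2] <- 2L                      # 3-px speck
  seg[10:16, 10:17] <- 2L                # 56-px blob
  out <- filterSmallComponents(seg, 5L)
  expect_true(all(out[2:3, 2] == 1L))
  expect_true(all(out[10:16, 10:17] == 2L))
})

test_that("planimetric indices follow their defining identities", {
  seg <- matrix(1L, 10, 10)
  seg[1:2, ] <- 3L                       # 20% dark
  seg[3:5, ] <- 2L                       # 30% light
  pin <- planimetricIndices(seg, matrix(TRUE, 10, 10))
  expect_equal(pin@plani_tot, 50)
  expect_equal(pin@plani_dark, 20)
  expect_equal(pin@plani_light, 30)
  expect_equal(pin@rel_dark, 40)
  expect_equal(pin@rel_light, 60)
  expect_identical(pin@plani_light, pin@plani_tot - pin@plani_dark)
  expect_equal(pin@rel_dark + pin@rel_light, 100)

  none <- planimetricIndices(matrix(1L, 5, 5), matrix(TRUE, 5, 5))
  expect_equal(none@plani_tot, 0)
  expect_true(is.na(none@rel_dark) && is.na(none@rel_light))

  expect_error(planimetricIndices(seg, matrix(FALSE, 10, 10)), "empty")
})

test_that("index error shows no trend against coverage", {
  train <- list(disclosedFixture(20), disclosedFixture(21, coverage = 0.3))
  clf <- trainPixelClassifier(lapply(train, `[[`, "image"),
                              lapply(train, `[[`, "truth_classes"),
                              seed = 3, ntree = 60)
  covs <- seq(0.025, 0.39, length.out = 40)   # stained range ~6-94%
  res <- t(vapply(seq_along(covs), function(i) {
    fx <- disclosedFixture(100 + i, coverage = covs[i])
    seg <- segmentDisclosed(fx$image, clf)
    est <- planimetricIndices(seg, fx$image@roi_pixel_mask)
    tru <- planimetricIndices(fx$truth_classes, fx$image@roi_pixel_mask)
    c(err = abs(est@plani_tot - tru@plani_tot), cov = tru@plani_tot)
  }, c(0, 0)))
  rho <- suppressWarnings(spearmanRho(res[, "err"], res[, "cov"])$rho)
  expect_lt(abs(rho), 0.3)
  # and the indices themselves stay within 2 points of truth
  expect_lt(max(res[, "err"]), 2)
})

test_that("disclosed image round trip through PNG preserves indices", {
  fx <- disclosedFixture(9)
  p1 <- tempfile(fileext = ".png"); p2 <- tempfile(fileext = ".png")
  png::writePNG(fx$image@rgb, p1)
  png::writePNG(fx$image@roi_pixel_mask * 1, p2)
  img <- readDisclosedImage(p1, p2, tooth_id = "11")
  expect_equal(dim(img@rgb), dim(fx$image@rgb))
  expect_identical(img@roi_pixel_mask, fx$image@roi_pixel_mask)
})
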