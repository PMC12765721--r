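## Two-tone disclosed-plaque planimetry: trainable pixel classification of
## RGB screenshots into non-plaque / light-pink / dark-purple, and the
## PLANI indices. The classifier is a random forest over a fixed,
## documented multiscale feature bank (the trainable-segmentation idiom).

#' Construct a DisclosedImage
#'
#' @param rgb H x W x 3 array in [0, 1] (or 0..255, rescaled)
#' @param roi_pixel_mask logical H x W; all-TRUE when NULL
#' @param tooth_id character label
#' @return a \linkS4class{DisclosedImage}
#' @export
DisclosedImage <- function(rgb, roi_pixel_mask = NULL, tooth_id = "NA") {
  if (max(rgb) > 1.001) rgb <- rgb / 255
  if (is.null(roi_pixel_mask))
    roi_pixel_mask <- matrix(TRUE, dim(rgb)[1], dim(rgb)[2])
  new("DisclosedImage", rgb = rgb, roi_pixel_mask = roi_pixel_mask,
      tooth_id = as.character(tooth_id))
}

#' Read a disclosed-plaque PNG
#'
#' @param path RGB(A) PNG
#' @param mask_path optional PNG whose nonzero pixels define the ROI mask
#' @param tooth_id character label
#' @return a \linkS4class{DisclosedImage}
#' @export
readDisclosedImage <- function(path, mask_path = NULL, tooth_id = "NA") {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2L) img <- array(rep(img, 3), c(dim(img), 3))
  img <- img[, , 1:3, drop = FALSE]
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- png::readPNG(mask_path)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    mask <- m > 0.5
  }
  DisclosedImage(img, mask, tooth_id)
}

#' Green channel as 8-bit grayscale
#'
#' The pink/purple disclosing dyes absorb green, so the green channel gives
#' the best plaque/tooth contrast: plaque renders dark, clean enamel light.
#'
#' @param img a \linkS4class{DisclosedImage}
#' @return integer matrix H x W in 0..255
#' @export
greenChannelGray <- function(img) {
  g <- round(255 * img@rgb[, , 2])
  storage.mode(g) <- "integer"
  g
}

## box-filter mean via EBImage::filter2 (circular padding avoided by
## replicate padding through "replicate" not available; use linear filter
## with normalized box kernel and EBImage default) -- adequate for features
boxMean <- function(m, r) {
  k <- matrix(1, 2 * r + 1, 2 * r + 1)
  k <- k / sum(k)
  as.matrix(EBImage::filter2(EBImage::Image(m), k))
}

#' Pixel feature bank
#'
#' Fixed multiscale features per pixel: raw R, G, B; the green channel;
#' Gaussian blurs of the green channel at sigma 1, 2, 4, 8 px; Sobel
#' gradient magnitude; differences of Gaussians (1-2, 2-4, 4-8); local
#' median (radius 2 and 5 px); local variance (radius 2 and 5 px).
#' Pixels outside the ROI mask are replaced by a fixed neutral grey
#' before filtering, so ROI-external content can never leak into ROI
#' features through the blurs (masking correctness).
#'
#' @param img a \linkS4class{DisclosedImage}
#' @return numeric matrix, one row per pixel (column-major pixel order),
#'   with named feature columns
#' @export
pixelFeatures <- function(img) {
  rgbArr <- img@rgb
  out_px <- !img@roi_pixel_mask
  if (any(out_px))
    for (k in 1:3) {
      ch <- rgbArr[, , k]
      ch[out_px] <- 0.5
      rgbArr[, , k] <- ch
    }
  g <- rgbArr[, , 2]
  gi <- EBImage::Image(g)
  blurs <- lapply(c(1, 2, 4, 8), function(s)
    as.matrix(EBImage::gblur(gi, sigma = s)))
  sobx <- matrix(c(-1, -2, -1, 0, 0, 0, 1, 2, 1), 3, 3)
  gx <- as.matrix(EBImage::filter2(gi, sobx))
  gy <- as.matrix(EBImage::filter2(gi, t(sobx)))
  grad <- sqrt(gx^2 + gy^2)
  med2 <- as.matrix(EBImage::medianFilter(gi, 2))
  med5 <- as.matrix(EBImage::medianFilter(gi, 5))
  m2 <- boxMean(g, 2); m5 <- boxMean(g, 5)
  v2 <- pmax(0, boxMean(g^2, 2) - m2^2)
  v5 <- pmax(0, boxMean(g^2, 5) - m5^2)
  feats <- cbind(
    red = as.vector(rgbArr[, , 1]), green = as.vector(g),
    blue = as.vector(rgbArr[, , 3]),
    gauss1 = as.vector(blurs[[1]]), gauss2 = as.vector(blurs[[2]]),
    gauss4 = as.vector(blurs[[3]]), gauss8 = as.vector(blurs[[4]]),
    grad = as.vector(grad),
    dog12 = as.vector(blurs[[1]] - blurs[[2]]),
    dog24 = as.vector(blurs[[2]] - blurs[[3]]),
    dog48 = as.vector(blurs[[3]] - blurs[[4]]),
    median2 = as.vector(med2), median5 = as.vector(med5),
    var2 = as.vector(v2), var5 = as.vector(v5))
  feats
}

#' Train the two-tone pixel classifier
#'
#' Fits a random forest on sparse pixel annotations over the
#' [pixelFeatures()] bank. Labels use 0 = unlabelled, 1 = non_plaque,
#' 2 = light_pink, 3 = dark_purple. Training is reproducible for a fixed
#' seed and training set.
#'
#' @param images list of \linkS4class{DisclosedImage}
#' @param labels list of integer H x W matrices matching `images`
#' @param seed integer RNG seed
#' @param n_per_class maximum training pixels sampled per class
#' @param ntree random-forest size
#' @return a \linkS4class{PixelClassifier}
#' @export
trainPixelClassifier <- function(images, labels, seed = 1L,
                                 n_per_class = 2000L, ntree = 100L) {
  stopifnot(length(images) == length(labels))
  X <- NULL; y <- NULL
  for (i in seq_along(images)) {
    f <- pixelFeatures(images[[i]])
    lab <- as.vector(labels[[i]])
    sel <- lab > 0L
    X <- rbind(X, f[sel, , drop = FALSE])
    y <- c(y, lab[sel])
  }
  cnt <- tabulate(y, nbins = 3L)
  if (any(cnt < 50L))
    stop("need at least 50 labelled pixels per class; got ",
         paste(cnt, collapse = "/"))
  set.seed(seed)
  keep <- unlist(lapply(1:3, function(k) {
    idx <- which(y == k)
    if (length(idx) > n_per_class) sort(sample(idx, n_per_class)) else idx
  }))
  yf <- factor(PLAQUE_CLASSES[y[keep]], levels = PLAQUE_CLASSES)
  set.seed(seed)
  rf <- randomForest::randomForest(X[keep, , drop = FALSE], yf,
                                   ntree = ntree)
  new("PixelClassifier", model = rf, classes = PLAQUE_CLASSES,
      feature_names = colnames(X),
      n_train = setNames(as.integer(table(yf)), PLAQUE_CLASSES),
      seed = as.integer(seed))
}

#' Segment a disclosed-plaque image
#'
#' Predicts one class per ROI pixel; pixels outside the ROI mask are
#' non_plaque. Connected plaque components (4-connectivity on the union of
#' both plaque classes) smaller than `min_component` pixels are removed as
#' speckle.
#'
#' @param img a \linkS4class{DisclosedImage}
#' @param clf a \linkS4class{PixelClassifier}
#' @param min_component minimum plaque component size in px (default 5)
#' @return integer H x W matrix: 1 = non_plaque, 2 = light_pink,
#'   3 = dark_purple
#' @export
segmentDisclosed <- function(img, clf, min_component = 5L) {
  f <- pixelFeatures(img)
  H <- dim(img@rgb)[1]; W <- dim(img@rgb)[2]
  seg <- matrix(1L, H, W)
  inroi <- as.vector(img@roi_pixel_mask)
  if (any(inroi)) {
    pred <- predict(clf@model, f[inroi, , drop = FALSE])
    seg[inroi] <- as.integer(pred)
  }
  filterSmallComponents(seg, min_component)
}

#' Remove small plaque components from a class raster
#'
#' Connected components of the plaque union (classes 2 and 3) smaller
#' than `min_component` pixels are reset to non_plaque.
#'
#' @param seg integer class raster
#' @param min_component minimum component size, px
#' @return filtered raster
#' @export
filterSmallComponents <- function(seg, min_component = 5L) {
  if (min_component <= 1L) return(seg)
  plaque <- seg > 1L
  labm <- EBImage::bwlabel(EBImage::Image(plaque * 1))
  sizes <- table(as.vector(labm)[as.vector(labm) > 0])
  small <- as.integer(names(sizes)[sizes < min_component])
  if (length(small)) seg[as.matrix(labm) %in% small] <- 1L
  seg
}

#' Planimetric indices from a segmentation
#'
#' PLANIdark = 100 x dark pixels / ROI pixels; PLANItot = 100 x (dark +
#' light) / ROI pixels; PLANIlight = PLANItot - PLANIdark (exact
#' subtraction identity); relPLANIdark = PLANIdark / PLANItot x 100 and
#' its light complement, both NA when PLANItot = 0.
#'
#' @param seg integer class raster from [segmentDisclosed()] (or a
#'   ground-truth class raster)
#' @param roi_pixel_mask logical H x W
#' @return a \linkS4class{PlanimetricIndices}
#' @export
planimetricIndices <- function(seg, roi_pixel_mask) {
  n <- sum(roi_pixel_mask)
  if (n == 0L) stop("empty ROI pixel mask")
  s <- seg[roi_pixel_mask]
  dark <- 100 * sum(s == 3L) / n
  tot <- 100 * (sum(s == 3L) + sum(s == 2L)) / n
  light <- tot - dark
  if (tot > 0) {
    rel_dark <- dark / tot * 100
    rel_light <- 100 - rel_dark
  } else {
    rel_dark <- NA_real_; rel_light <- NA_real_
  }
  new("PlanimetricIndices", plani_tot = tot, plani_dark = dark,
      plani_light = light, rel_dark = rel_dark, rel_light = rel_light)
}

setMethod("show", "PlanimetricIndices", function(object) {
  cat(sprintf(
    "PlanimetricIndices: tot %.2f%%, dark %.2f%%, light %.2f%% (rel dark %s%%)\n",
    object@plani_tot, object@plani_dark, object@plani_light,
    if (is.na(object@rel_dark)) "NA" else sprintf("%.1f", object@rel_dark)))
})

#' Per-class intersection-over-union
#'
#' @param seg,truth integer class rasters of equal shape
#' @param classes class codes to evaluate (default plaque classes 2 and 3)
#' @return named numeric IoU per class (NA when a class is absent from
#'   both rasters)
#' @export
classIoU <- function(seg, truth, classes = c(2L, 3L)) {
  vapply(classes, function(k) {
    i <- sum(seg == k & truth == k)
    u <- sum(seg == k | truth == k)
    if (u == 0L) NA_real_ else i / u
  }, 0)
}
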