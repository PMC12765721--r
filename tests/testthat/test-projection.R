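flatField <- function(mesh, d, limit = 0.01) {
  new("ThicknessField", roi = ROIMask("11", seq_len(nVertices(mesh)), "T0"),
      d = if (length(d) == 1) rep(d, nVertices(mesh)) else d,
      a = vertexAreaWeights(mesh), detection_limit = limit)
}

test_that("a flat ROI viewed along its normal renders uniformly", {
  mesh <- flatPatch(21, 21)
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 0.1)
  map <- renderThicknessMap(flatField(mesh, 0.05), mesh, spec,
                            mode = "continuous")
  vals <- map@raster[map@roi_pixel_mask]
  expect_equal(unname(range(vals)), c(0.05, 0.05), tolerance = 1e-12)

  bmap <- renderThicknessMap(flatField(mesh, 0), mesh, spec,
                             mode = "boolean")
  expect_true(all(bmap@raster[bmap@roi_pixel_mask] == 0))
  expect_equal(planiVolmap(bmap), 0)
})

test_that("planiVolmap reports the boolean pixel fraction", {
  mesh <- flatPatch(21, 21)
  v <- vertices(mesh)
  d <- ifelse(v[, 1] < 5, 0.05, 0)      # left half covered
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 0.05)
  bmap <- renderThicknessMap(flatField(mesh, d), mesh, spec,
                             mode = "boolean")
  expect_equal(planiVolmap(bmap), 50, tolerance = 1.5)
  # and agrees with the area-weighted 3D coverage for a flat patch
  expect_equal(planiVolmap(bmap),
               surfaceCoverage(flatField(mesh, d)), tolerance = 1.5)
})

test_that("per-pixel thickness matches a brute-force ray-cast oracle", {
  spec <- syntheticSpec(edge_length = 0.4, seed = 6)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  field <- signedDistanceField(crown$mesh, pl$mesh_t4)
  pspec <- projectionSpec(mesh = crown$mesh, pixel_size = 0.15)
  map <- renderThicknessMap(field, crown$mesh, pspec, mode = "continuous")

  B <- plaquemetry:::projectionBasis(pspec)
  P <- vertices(crown$mesh) %*% t(B)
  Fc <- faces(crown$mesh)
  d <- thickness(field); d[is.na(d)] <- 0
  px <- pspec@pixel_size
  x0 <- min(P[, 1]) - px; y0 <- min(P[, 2]) - px

  rayCast <- function(xp, yp) {
    bestz <- -Inf; bestval <- NA_real_
    for (f in seq_len(nrow(Fc))) {
      tri <- P[Fc[f, ], ]
      det <- (tri[2, 1] - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
             (tri[2, 2] - tri[1, 2]) * (tri[3, 1] - tri[1, 1])
      if (abs(det) < 1e-14) next
      l1 <- ((xp - tri[1, 1]) * (tri[3, 2] - tri[1, 2]) -
             (yp - tri[1, 2]) * (tri[3, 1] - tri[1, 1])) / det
      l2 <- ((tri[2, 1] - tri[1, 1]) * (yp - tri[1, 2]) -
             (tri[2, 2] - tri[1, 2]) * (xp - tri[1, 1])) / det
      l0 <- 1 - l1 - l2
      if (l0 < -1e-9 || l1 < -1e-9 || l2 < -1e-9) next
      z <- l0 * tri[1, 3] + l1 * tri[2, 3] + l2 * tri[3, 3]
      if (z > bestz) {
        bestz <- z
        bestval <- l0 * d[Fc[f, 1]] + l1 * d[Fc[f, 2]] + l2 * d[Fc[f, 3]]
      }
    }
    bestval
  }

  set.seed(3)
  inroi <- which(map@roi_pixel_mask, arr.ind = TRUE)
  pick <- inroi[sample(nrow(inroi), 200), , drop = FALSE]
  for (k in seq_len(nrow(pick))) {
    i <- unname(pick[k, 2]); j <- unname(pick[k, 1])   # col = x, row = y
    got <- map@raster[j, i]
    want <- rayCast(x0 + (i - 1) * px, y0 + (j - 1) * px)
    expect_equal(unname(got), unname(want), tolerance = 1e-6)
  }
})

test_that("tilting a flat ROI by 60 degrees halves its projected area", {
  mesh <- flatPatch(41, 41)
  spec0 <- projectionSpec(c(0, 0, 1), pixel_size = 0.05)
  n0 <- sum(renderThicknessMap(flatField(mesh, 0.05), mesh, spec0,
                               mode = "boolean")@roi_pixel_mask)
  tilted <- applyTransform(axisAngleTransform(c(0, 1, 0), 60 * pi / 180),
                           mesh)
  n1 <- sum(renderThicknessMap(flatField(tilted, 0.05), tilted, spec0,
                               mode = "boolean")@roi_pixel_mask)
  expect_equal(n1 / n0, 0.5, tolerance = 0.02 * 0.5)
})

test_that("planiVolmap is stable under pixel-size halving", {
  spec <- syntheticSpec(edge_length = 0.25, seed = 7)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  field <- signedDistanceField(crown$mesh, pl$mesh_t4)
  vals <- vapply(c(0.08, 0.04), function(px) {
    ps <- projectionSpec(mesh = crown$mesh, pixel_size = px)
    planiVolmap(renderThicknessMap(field, crown$mesh, ps, "boolean"))
  }, 0)
  expect_equal(vals[1], vals[2], tolerance = 0.01 * max(vals))
})

test_that("categorized mode bins at the requested thresholds", {
  mesh <- flatPatch(11, 11)
  v <- vertices(mesh)
  d <- ifelse(v[, 1] < 3, 0.002, ifelse(v[, 1] < 7, 0.07, 0.3))
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 0.2)
  map <- renderThicknessMap(flatField(mesh, d), mesh, spec, "categorized")
  lv <- sort(unique(map@raster[map@roi_pixel_mask]))
  expect_true(all(lv %in% c(0, 0.01, 0.05, 0.10, 0.20)))
  expect_equal(nrow(map@legend), 5L)
})

test_that("an over-coarse raster is rejected", {
  mesh <- flatPatch(5, 5, 1, 1)
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 2)
  expect_error(renderThicknessMap(flatField(mesh, 0.05), mesh, spec),
               "pixel")
})

test_that("16-bit TIFF export preserves the thickness raster", {
  mesh <- flatPatch(11, 11)
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 0.2)
  map <- renderThicknessMap(flatField(mesh, 0.05), mesh, spec,
                            "continuous")
  path <- tempfile(fileext = ".tif")
  writeThicknessTIFF(map, path, max_mm = 0.5)
  img <- tiff::readTIFF(path)
  H <- nrow(map@raster)
  got <- img[H:1, , drop = FALSE][map@roi_pixel_mask] * 0.5
  expect_lt(max(abs(got - 0.05)), 0.5 / 65535)
  expect_true(file.exists(sub("\\.tif$", "_scale.json", path)))
  expect_error(writeThicknessTIFF(
    renderThicknessMap(flatField(mesh, 0.05), mesh, spec, "boolean"),
    path), "continuous")
})

test_that("PNG export writes image and legend sidecar", {
  mesh <- flatPatch(11, 11)
  spec <- projectionSpec(c(0, 0, 1), pixel_size = 0.2)
  map <- renderThicknessMap(flatField(mesh, 0.05), mesh, spec, "boolean")
  path <- tempfile(fileext = ".png")
  writeMapPNG(map, path)
  expect_true(file.exists(path))
  expect_true(file.exists(sub("\\.png$", "_legend.json", path)))
  img <- png::readPNG(path)
  expect_equal(dim(img)[1:2], dim(map@raster))
})
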