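test_that("identical surfaces give a zero field", {
  mesh <- makeCrown(syntheticSpec(edge_length = 0.4, seed = 1))$mesh
  field <- signedDistanceField(mesh, mesh)
  expect_lt(max(abs(thickness(field))), 1e-9)
  expect_equal(sum(areaWeights(field)), surfaceArea(mesh),
               tolerance = 1e-12)
})

test_that("parallel planes measure the exact offset with positive sign", {
  t0 <- flatPatch(11, 11)
  t4 <- flatPatch(11, 11, z = 0.05)
  field <- signedDistanceField(t0, t4)
  expect_equal(unname(thickness(field)), rep(0.05, nVertices(t0)),
               tolerance = 1e-12)
  # surface below the reference reads negative
  fneg <- signedDistanceField(t0, flatPatch(11, 11, z = -0.05))
  expect_lt(max(thickness(fneg)), -0.049)
})

test_that("fast closest-point queries match a brute-force oracle", {
  mesh <- makeCrown(syntheticSpec(edge_length = 0.8, seed = 3))$mesh
  set.seed(5)
  pts <- vertices(mesh)[sample(nVertices(mesh), 25), ] +
    matrix(rnorm(75, 0, 0.3), ncol = 3)
  got <- closestOnMesh(pts, mesh)
  for (i in seq_len(nrow(pts))) {
    oracle <- bruteClosest(pts[i, ], mesh)
    expect_equal(got$dist[i], oracle$dist, tolerance = 1e-9)
  }
})

test_that("an analytic smooth offset is measured to 0.002 mm", {
  fx <- analyticOffsetPair(edge = 0.1)
  field <- signedDistanceField(fx$crown$mesh, fx$t4)
  expect_lt(max(abs(thickness(field) - fx$tfield)), 0.002)
})

test_that("VPI integrates thickness times area above the detection limit", {
  mesh <- flatPatch(11, 11)   # 10 x 10 mm, area 100
  roi <- ROIMask("11", seq_len(nVertices(mesh)), "T0")
  a <- vertexAreaWeights(mesh)
  mk <- function(d) new("ThicknessField", roi = roi,
                        d = rep(d, nVertices(mesh)), a = a,
                        detection_limit = 0.01)
  vol <- computeVPI(mk(0.05))
  expect_equal(vpi(vol), 5, tolerance = 1e-9)
  expect_equal(avpi(vol), 0.05, tolerance = 1e-12)
  expect_equal(coveredFraction(vol), 1)
  expect_equal(avpi(vol), vpi(vol) / vol@roi_area)  # exact identity

  sub <- computeVPI(mk(0.005))                      # below the limit
  expect_equal(vpi(sub), 0)
  expect_equal(coveredFraction(sub), 0)

  neg <- computeVPI(mk(-0.05))                      # abrasion clamped out
  expect_equal(vpi(neg), 0)
  # signed-volume sensitivity mode subtracts it
  expect_equal(computeVPI(mk(-0.05), signed_volume = TRUE)@vpi, 0)
})

test_that("VPI recovers the simulator's analytic volume within 2%", {
  for (sd in c(3, 12)) {
    spec <- syntheticSpec(edge_length = 0.1, seed = sd)
    crown <- makeCrown(spec)
    pl <- addPlaque(crown, spec)
    field <- signedDistanceField(crown$mesh, pl$mesh_t4)
    v <- vpi(computeVPI(field))
    expect_lt(abs(v - pl$truth$true_volume) / pl$truth$true_volume, 0.02)
  }
})

test_that("VPI is monotone, additive over partitions and rigid-invariant", {
  spec <- syntheticSpec(edge_length = 0.2, seed = 4)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  field <- signedDistanceField(crown$mesh, pl$mesh_t4)

  # monotone: pointwise-larger d never decreases VPI
  f2 <- field; f2@d <- field@d + 0.01
  expect_gte(vpi(computeVPI(f2)), vpi(computeVPI(field)))

  # additive: vertex-disjoint sub-ROIs sum to the total
  n <- length(field@d)
  half <- seq_len(n %/% 2)
  split_vpi <- function(idx) {
    fs <- new("ThicknessField",
              roi = ROIMask("11", idx, "T0"),
              d = field@d[idx], a = field@a[idx], detection_limit = 0.01)
    vpi(computeVPI(fs))
  }
  expect_equal(split_vpi(half) + split_vpi(setdiff(seq_len(n), half)),
               vpi(computeVPI(field)), tolerance = 1e-12)

  # rigid invariance: same motion applied to both surfaces
  tr <- axisAngleTransform(c(1, 0.3, 2), 0.7, c(4, -2, 1))
  fieldR <- signedDistanceField(applyTransform(tr, crown$mesh),
                                applyTransform(tr, pl$mesh_t4))
  expect_equal(vpi(computeVPI(fieldR)), vpi(computeVPI(field)),
               tolerance = 1e-9)
})

test_that("VPI error decreases with mesh resolution on an analytic offset", {
  errs <- vapply(c(0.4, 0.2, 0.1), function(h) {
    fx <- analyticOffsetPair(edge = h)
    spec <- fx$spec
    field <- signedDistanceField(fx$crown$mesh, fx$t4)
    v <- vpi(computeVPI(field))
    # independent truth: fine-grid quadrature of the prescribed field
    fg <- plaquemetry:::fineGridQuadrature(spec, 600L)
    tq <- 0.05 + 0.02 * cos(pi * fg$u) * cos(pi * fg$v)
    abs(v - sum(tq * fg$dA))
  }, 0)
  expect_true(all(diff(errs) < 0))
})

test_that("binarized coverage equals the VPI covered fraction bit-exactly", {
  spec <- syntheticSpec(edge_length = 0.2, seed = 10)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  field <- signedDistanceField(crown$mesh, pl$mesh_t4)
  expect_identical(binarizeField(field, field@detection_limit)$covered_fraction,
                   coveredFraction(computeVPI(field)))
  # alternating equal-area toy: half above cutoff
  flat <- flatPatch(2, 3, 1, 2)   # 6 vertices in 2 columns
  af <- new("ThicknessField",
            roi = ROIMask("11", 1:6, "T0"),
            d = c(0.02, 0.005, 0.02, 0.005, 0.02, 0.005),
            a = rep(1, 6), detection_limit = 0.01)
  expect_equal(binarizeField(af)$covered_fraction, 0.5)
})

test_that("insufficient scan coverage fails loudly", {
  t0 <- flatPatch(11, 11)
  # T4 covers only a corner: most vertices have no surface within 1 mm
  t4 <- flatPatch(3, 3, 2, 2, z = 0.02)
  expect_error(signedDistanceField(t0, t4), "coverage")
})
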