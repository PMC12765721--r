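test_that("crown generation is deterministic and plausibly sized", {
  spec <- syntheticSpec(edge_length = 0.3, seed = 14)
  c1 <- makeCrown(spec); c2 <- makeCrown(spec)
  expect_identical(vertices(c1$mesh), vertices(c2$mesh))

  a <- surfaceArea(makeCrown(syntheticSpec(edge_length = 0.2))$mesh)
  expect_gt(a, 50); expect_lt(a, 150)

  # edge length within 20% of target
  mesh <- c1$mesh
  e <- rbind(faces(mesh)[, 1:2], faces(mesh)[, 2:3])
  len <- sqrt(rowSums((vertices(mesh)[e[, 1], ] -
                       vertices(mesh)[e[, 2], ])^2))
  expect_lt(abs(median(len) - 0.3) / 0.3, 0.2)
})

test_that("flat degenerate settings yield a planar rectangle", {
  spec <- syntheticSpec(rx = 5, ry = 5, height = 0, edge_length = 0.5)
  crown <- makeCrown(spec)
  expect_equal(max(abs(vertices(crown$mesh)[, 3])), 0)
  expect_equal(surfaceArea(crown$mesh), 100, tolerance = 1e-9)
})

test_that("plaque coverage calibration hits its target within 2 points", {
  for (target in c(0.1, 0.19, 0.35)) {
    spec <- syntheticSpec(edge_length = 0.3, coverage_fraction = target,
                          seed = 3)
    pl <- addPlaque(makeCrown(spec), spec, n_fine = 400L)
    expect_lt(abs(pl$truth$true_coverage_fraction - target), 0.02)
  }
})

test_that("full uniform coverage on a flat patch integrates exactly", {
  spec <- syntheticSpec(rx = 5, ry = 5, height = 0, edge_length = 0.5,
                        coverage_fraction = 1, field_waves = 0L,
                        gingival_decay = Inf, seed = 1)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 300L)
  tv <- pl$truth$thickness
  expect_equal(diff(range(tv)), 0)           # uniform layer
  expect_equal(pl$truth$true_volume, tv[1] * pl$truth$true_area,
               tolerance = 1e-12)
  expect_equal(pl$truth$true_area, 100, tolerance = 1e-9)
})

test_that("zero coverage leaves the surface untouched", {
  spec <- syntheticSpec(edge_length = 0.3, coverage_fraction = 0, seed = 2)
  crown <- makeCrown(spec)
  pl <- addPlaque(crown, spec, n_fine = 200L)
  expect_identical(vertices(pl$mesh_t4), vertices(crown$mesh))
  expect_equal(pl$truth$true_volume, 0)
  expect_equal(pl$truth$true_coverage_fraction, 0)
})

test_that("true volume grows strictly with maximum thickness", {
  vols <- vapply(c(0.08, 0.15, 0.25), function(mt) {
    spec <- syntheticSpec(edge_length = 0.4, max_thickness = mt, seed = 5)
    addPlaque(makeCrown(spec), spec, n_fine = 250L)$truth$true_volume
  }, 0)
  expect_true(all(diff(vols) > 0))
})

test_that("stained and dark regions nest and hit their area targets", {
  spec <- syntheticSpec(edge_length = 0.3, seed = 6)
  pl <- addPlaque(makeCrown(spec), spec, n_fine = 400L)
  tr <- pl$truth
  expect_true(all(tr$dark <= tr$stained))       # dark subset of stained
  expect_true(all((tr$thickness >= 0.01) <= tr$stained))
  expect_equal(tr$true_stained_fraction,
               spec$stain_ratio * tr$true_coverage_fraction,
               tolerance = 0.05 * tr$true_stained_fraction)
  expect_equal(tr$true_dark_fraction, spec$maturity_fraction,
               tolerance = 0.05)
})

test_that("scan corruption reproduces its nominal noise level and pose", {
  spec <- syntheticSpec(edge_length = 0.1, coverage_fraction = 0)
  mesh <- makeCrown(spec)$mesh                  # > 10^4 vertices
  same <- corruptScan(mesh, noise_sd = 0, rotation_deg = 0,
                      translation_mm = 0, seed = 1)
  expect_identical(vertices(same$mesh), vertices(mesh))

  s <- 0.005
  noisy <- corruptScan(mesh, noise_sd = s, rotation_deg = 0,
                       translation_mm = 0, seed = 2)
  disp <- rowSums((vertices(noisy$mesh) - vertices(mesh)) *
                  vertexNormals(mesh))
  expect_lt(abs(sd(disp) - s) / s, 0.05)

  # pose recovery on a noiseless corrupted mesh
  coarse <- makeCrown(syntheticSpec(edge_length = 0.2))$mesh
  moved <- corruptScan(coarse, noise_sd = 0, rotation_deg = 3,
                       translation_mm = 1, seed = 3)
  rep <- bestFitROI(moved$mesh, coarse,
                    init = preAlign(moved$mesh, coarse))
  comp <- composeTransforms(rep@transform, moved$transform)
  expect_lt(rotationAngle(comp), 1e-3)
  expect_lt(sqrt(sum(translation(comp)^2)), 1e-3)
})

test_that("disclosed-image rendering matches its own ground truth", {
  spec0 <- syntheticSpec(edge_length = 0.3, coverage_fraction = 0,
                         pixel_size = 0.08, seed = 7)
  crown <- makeCrown(spec0)
  pl0 <- addPlaque(crown, spec0, n_fine = 200L)
  r0 <- renderDisclosedImage(crown, pl0, spec0)
  expect_true(all(r0$truth_classes == 1L))

  spec <- syntheticSpec(edge_length = 0.3, pixel_size = 0.08, seed = 8)
  pl <- addPlaque(makeCrown(spec), spec, n_fine = 200L)
  r <- renderDisclosedImage(makeCrown(spec), pl, spec)
  pin <- planimetricIndices(r$truth_classes, r$image@roi_pixel_mask)
  npx <- sum(r$image@roi_pixel_mask)
  expect_equal(pin@plani_tot,
               100 * sum(r$truth_classes > 1) / npx, tolerance = 1e-12)
  expect_equal(pin@plani_dark,
               100 * sum(r$truth_classes == 3) / npx, tolerance = 1e-12)
})

test_that("cohorts are reproducible and clinically coherent", {
  spec <- syntheticSpec(edge_length = 0.4)
  a <- generateCohort(3, 4, spec, seed = 20)
  b <- generateCohort(3, 4, spec, seed = 20)
  expect_identical(a$records, b$records)
  expect_identical(a$site_scores, b$site_scores)
  expect_equal(nrow(a$records), 12L)
  expect_equal(nrow(a$site_scores), 12L * 6L)

  big <- generateCohort(15, 10, spec, seed = 21)
  expect_equal(nrow(big$records), 150L)
  # clinical scores must track true stained coverage
  rho <- spearmanRho(big$records$tmqhpli_tdp_mean,
                     big$records$true_stained_fraction)$rho
  expect_gt(rho, 0.8)
  # volumetric truth in the plausible study range (VPI 0.28-2.00 mm^3)
  expect_gt(median(big$records$true_volume), 0.2)
  expect_lt(median(big$records$true_volume), 2)
})

test_that("two-regime simulator produces a detectable breakpoint", {
  d <- simulateGrowthRegimes(150, seed = 44)
  expect_true(all(d$vpi >= 0))
  fit <- contributionBreakpoint(d)
  expect_false(fit$single_line)
  expect_equal(fit$breakpoint, 32.5, tolerance = 5)
})
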