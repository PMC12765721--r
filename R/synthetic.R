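## Synthetic study generator: smooth crown-like buccal patches, a de-novo
## plaque layer as an outward normal offset with known analytic volume,
## scanner noise and pose perturbation, two-tone disclosed images and
## TMQHPlI-like scores. Ground truth is always computed by independent
## high-resolution quadrature on the parametric surface, never by the
## volumetry module.

#' Synthetic study specification
#'
#' Default values emulate a 4-day de-novo plaque accumulation study on
#' maxillary buccal surfaces: crown patches of premolar/incisor size
#' (about 8 x 10 mm, area 50-150 mm^2), volumetric plaque coverage
#' (thickness at or above the 0.01 mm detection limit) around 19% of the
#' surface, plaque up to ~0.15 mm thick concentrated towards the gingival
#' margin, scanner noise of 0.005 mm and small pose offsets. Disclosing
#' dye also stains films far thinner than the scanner can reconstruct, so
#' the stained region in the rendered image is wider than the volumetric
#' one by `stain_ratio` (about 2.4x); roughly half of the stained area is
#' dark/mature. The stained film outside the volumetric region exists
#' only in the image appearance, never in the T4 geometry.
#'
#' @param rx,ry patch half-widths, mm (mesiodistal, occluso-gingival)
#' @param height crown convexity height, mm (0 = flat patch)
#' @param shape_exp superellipse exponent of the dome profile
#' @param edge_length target mesh edge length, mm
#' @param coverage_fraction target volumetric plaque area fraction
#'   (thickness >= detection limit)
#' @param stain_ratio stained (dye-visible) to volumetric area ratio
#' @param max_thickness maximum plaque thickness, mm
#' @param gingival_decay decay length of the gingival thickness gradient,
#'   mm
#' @param maturity_fraction fraction of the stained area that is
#'   dark/mature (the thickest part)
#' @param field_waves,field_scale smooth random coverage-field parameters
#'   (number of cosine waves, shortest wavelength in mm)
#' @param taper_mm spatial width of the thickness taper at the plaque
#'   boundary, mm (plaque margins thin out gradually, they are not
#'   knife-edges; keeping the slope gentle also keeps the field resolvable
#'   at the mesh edge length)
#' @param min_thickness minimum height of a deposit inside the covered
#'   region, mm: a detectable colony has finite height, so thickness
#'   steps from zero to this floor at the region boundary rather than
#'   passing through the sub-detection range
#' @param detection_limit mm
#' @param scan_noise_sd scanner noise along normals, mm
#' @param pose_rotation_deg,pose_translation_mm pose perturbation magnitudes
#' @param pixel_size rendered image resolution, mm/px
#' @param image_noise_sd additive RGB pixel noise
#' @param seed integer
#' @return a list of class "syntheticSpec"
#' @export
syntheticSpec <- function(rx = 4, ry = 5, height = 1.5, shape_exp = 3,
                          edge_length = 0.1,
                          coverage_fraction = 0.19, stain_ratio = 2.4,
                          max_thickness = 0.15,
                          gingival_decay = 3, maturity_fraction = 0.5,
                          field_waves = 40L, field_scale = 4,
                          taper_mm = 1.2, min_thickness = 0.015,
                          detection_limit = 0.01,
                          scan_noise_sd = 0.005,
                          pose_rotation_deg = 3, pose_translation_mm = 1,
                          pixel_size = 0.05, image_noise_sd = 0.02,
                          seed = 1L) {
  spec <- as.list(environment())
  stopifnot(spec$coverage_fraction >= 0, spec$coverage_fraction <= 1,
            spec$maturity_fraction >= 0, spec$maturity_fraction <= 1,
            spec$rx > 0, spec$ry > 0, spec$edge_length > 0)
  class(spec) <- "syntheticSpec"
  spec
}

## Dome height at parameters (u, v) in [-1, 1]^2. The superellipse dome is
## skewed (fuller towards the gingival margin at v = -1 and slightly
## mesially at u > 0), as real buccal surfaces are; the asymmetry also
## makes the principal axes of the patch unambiguous.
CROWN_SKEW_U <- 0.10
CROWN_SKEW_V <- 0.30

crownHeight <- function(u, v, spec) {
  p <- spec$shape_exp
  B <- (1 - abs(u)^p) * (1 - abs(v)^p)
  S <- 1 + CROWN_SKEW_U * u + CROWN_SKEW_V * (1 - v) / 2
  spec$height * B * S
}

## analytic gradient (dz/du, dz/dv)
crownGradient <- function(u, v, spec) {
  p <- spec$shape_exp
  B <- (1 - abs(u)^p) * (1 - abs(v)^p)
  S <- 1 + CROWN_SKEW_U * u + CROWN_SKEW_V * (1 - v) / 2
  Bu <- -p * abs(u)^(p - 1) * sign(u) * (1 - abs(v)^p)
  Bv <- -p * abs(v)^(p - 1) * sign(v) * (1 - abs(u)^p)
  list(du = spec$height * (Bu * S + B * CROWN_SKEW_U),
       dv = spec$height * (Bv * S - B * CROWN_SKEW_V / 2))
}

crownPoint <- function(u, v, spec) {
  cbind(spec$rx * u, spec$ry * v, crownHeight(u, v, spec))
}

## analytic outward normal (z up out of the crown): n = (-dz/dx, -dz/dy, 1)
crownNormal <- function(u, v, spec) {
  g <- crownGradient(u, v, spec)
  n <- cbind(-g$du / spec$rx, -g$dv / spec$ry, 1)
  n / sqrt(rowSums(n^2))
}

#' Generate a crown-like buccal surface patch
#'
#' A smooth open superellipsoid-profile patch tessellated on a regular
#' parameter grid at approximately the requested edge length, with
#' consistent outward (+z) normals. The ROI is the whole patch.
#'
#' @param spec a [syntheticSpec()]
#' @return list with `mesh` (\linkS4class{SurfaceMesh}), `roi`
#'   (\linkS4class{ROIMask}), `uv` (per-vertex parameters), `nu`, `nv`
#' @export
makeCrown <- function(spec = syntheticSpec()) {
  nu <- max(3L, as.integer(round(2 * spec$rx / spec$edge_length)) + 1L)
  nv <- max(3L, as.integer(round(2 * spec$ry / spec$edge_length)) + 1L)
  if (nu * nv > 4e6) stop("tessellation infeasible: too many vertices")
  us <- seq(-1, 1, length.out = nu)
  vs <- seq(-1, 1, length.out = nv)
  uv <- cbind(rep(us, times = nv), rep(vs, each = nu))
  V <- crownPoint(uv[, 1], uv[, 2], spec)
  idx <- function(i, j) (j - 1L) * nu + i
  i <- rep(seq_len(nu - 1L), times = nv - 1L)
  j <- rep(seq_len(nv - 1L), each = nu - 1L)
  # consistent CCW winding seen from +z
  F1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  F2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  mesh <- SurfaceMesh(V, rbind(F1, F2))
  list(mesh = mesh, roi = ROIMask("11", seq_len(nrow(V)), "T0"),
       uv = uv, nu = nu, nv = nv)
}

## deterministic smooth random field as a cosine series over (x, y) in mm
randomFieldFun <- function(spec, seed_offset = 0L) {
  set.seed(spec$seed + seed_offset)
  J <- spec$field_waves
  kdir <- matrix(rnorm(2 * J), J, 2)
  kdir <- kdir / sqrt(rowSums(kdir^2))
  klen <- 2 * pi / (spec$field_scale * (1 + runif(J))) # wavelengths in [scale, 2 scale]
  phase <- runif(J, 0, 2 * pi)
  amp <- rnorm(J)
  # RMS gradient magnitude of the normalized field, for spatial taper scaling
  grad_rms <- if (J > 0) sqrt(sum(amp^2 * klen^2) / sum(amp^2)) else 1
  fn <- function(x, y) {
    if (J == 0L) return(rep(0, length(x)))
    out <- 0
    for (jj in seq_len(J))
      out <- out + amp[jj] *
        cos(klen[jj] * (kdir[jj, 1] * x + kdir[jj, 2] * y) + phase[jj])
    out / sqrt(sum(amp^2) / 2)    # approx unit variance
  }
  attr(fn, "grad_rms") <- grad_rms
  fn
}

## Precomputed components of the analytic thickness field at points (u, v):
## t(tau) = base * smoothstep((G - tau)/w), with G the gingiva-biased
## coverage field, base the thickness profile and w the taper width
## converted from mm to field units through the field's RMS gradient. The
## C1 smoothstep taper keeps slopes gentle (|grad t| well below 1) so the
## nearest-surface distance read by the volumetry module equals the
## normal-offset thickness to first order.
thicknessParts <- function(spec, u, v) {
  Ffun <- randomFieldFun(spec, 0L)
  Mfun <- randomFieldFun(spec, 1000L)
  x <- spec$rx * u; y <- spec$ry * v
  g <- exp(-(v + 1) * spec$ry / spec$gingival_decay)   # gingival at v = -1
  list(G = Ffun(x, y) + 1.2 * g,
       base = spec$max_thickness * (0.35 + 0.65 * g) *
              (0.75 + 0.25 * pnorm(Mfun(x, y))),
       floor = spec$min_thickness,
       w = spec$taper_mm * attr(Ffun, "grad_rms"))
}

## Inside the covered region {G >= tau} thickness rises smoothly from the
## min_thickness floor to the local base value; outside it is exactly
## zero. The floor keeps the deposit free of sub-detection-limit mass and
## the smoothstep keeps lateral slopes gentle.
thicknessFromParts <- function(parts, tau, w = parts$w) {
  s <- pmin(1, pmax(0, (parts$G - tau) / w))
  s <- s * s * (3 - 2 * s)
  amp <- pmax(parts$base - parts$floor, 0)
  ifelse(parts$G >= tau, parts$floor + amp * s, 0)
}

## area elements |x_u x x_v| du dv on a fine parameter grid
fineGridQuadrature <- function(spec, n_fine) {
  us <- seq(-1 + 1 / n_fine, 1 - 1 / n_fine, length.out = n_fine)
  vs <- seq(-1 + 1 / n_fine, 1 - 1 / n_fine, length.out = n_fine)
  uu <- rep(us, times = n_fine); vv <- rep(vs, each = n_fine)
  g <- crownGradient(uu, vv, spec)
  # x_u = (rx, 0, dz/du), x_v = (0, ry, dz/dv)
  jac <- sqrt((spec$ry * g$du)^2 + (spec$rx * g$dv)^2 +
              (spec$rx * spec$ry)^2)
  du <- 2 / n_fine                       # midpoint rule on n x n cells
  list(u = uu, v = vv, dA = jac * du * du)
}

#' Add a de-novo plaque layer to a crown
#'
#' Defines a smooth analytic plaque-thickness field (thresholded filtered
#' random field biased towards the gingival margin, with a gentle taper at
#' the boundary), calibrates its threshold so the volumetric covered area
#' (thickness at or above the detection limit) hits `coverage_fraction`
#' within +-2%, and offsets the T0 vertices outward along the analytic
#' surface normals. Two further level sets of the same coverage field are
#' calibrated on top: the wider dye-stained region (`stain_ratio` times
#' the volumetric area; its sub-detection film is visible to the dye but
#' leaves no geometric trace) and its thickest `maturity_fraction`, the
#' dark/mature sub-region. All ground-truth integrals use independent
#' fine-grid quadrature of the analytic field.
#'
#' @param crown result of [makeCrown()]
#' @param spec the [syntheticSpec()] used for the crown
#' @param n_fine fine quadrature grid size per axis
#' @return list with `mesh_t4` (\linkS4class{SurfaceMesh}) and `truth`, a
#'   list with true_volume (mm^3), true_area (mm^2),
#'   true_coverage_fraction (volumetric), true_stained_fraction,
#'   true_dark_fraction (dark / stained), per-vertex `thickness`,
#'   `stained` and `dark`, and the applied `transform`
#' @export
addPlaque <- function(crown, spec = syntheticSpec(), n_fine = 800L) {
  quad <- fineGridQuadrature(spec, n_fine)
  qparts <- thicknessParts(spec, quad$u, quad$v)
  totA <- sum(quad$dA)
  covFrac <- function(tau) {
    t <- thicknessFromParts(qparts, tau)
    sum(quad$dA[t >= spec$detection_limit]) / totA
  }
  areaFrac <- function(tau) sum(quad$dA[qparts$G >= tau]) / totA
  bisect <- function(f, target) {
    lo <- -8; hi <- 10
    for (it in 1:60) {
      mid <- (lo + hi) / 2
      if (f(mid) > target) lo <- mid else hi <- mid
      if (hi - lo < 1e-10) break
    }
    (lo + hi) / 2
  }
  if (spec$coverage_fraction <= 0) {
    tau <- 1e6
  } else if (spec$coverage_fraction >= 1) {
    tau <- -1e6
  } else {
    tau <- bisect(covFrac, spec$coverage_fraction)
    if (abs(covFrac(tau) - spec$coverage_fraction) > 0.02)
      warning("coverage calibration off by more than 2 points")
  }
  stained_target <- min(0.95, spec$coverage_fraction * spec$stain_ratio)
  tau_dye <- if (stained_target <= 0) 1e6 else
    min(tau, bisect(areaFrac, stained_target))
  dark_target <- stained_target * spec$maturity_fraction
  tau_dark <- if (dark_target <= 0) 1e6 else bisect(areaFrac, dark_target)

  tq <- thicknessFromParts(qparts, tau)
  true_area <- totA
  true_volume <- sum(tq * quad$dA)
  covered <- tq >= spec$detection_limit
  true_cov <- sum(quad$dA[covered]) / true_area
  stained_q <- qparts$G >= tau_dye | covered
  true_stained <- sum(quad$dA[stained_q]) / true_area
  dark_q <- stained_q & qparts$G >= tau_dark
  true_dark <- if (any(stained_q))
    sum(quad$dA[dark_q]) / sum(quad$dA[stained_q]) else 0

  vparts <- thicknessParts(spec, crown$uv[, 1], crown$uv[, 2])
  tv <- thicknessFromParts(vparts, tau)
  nrm <- crownNormal(crown$uv[, 1], crown$uv[, 2], spec)
  V4 <- crown$mesh@vertices + nrm * tv
  mesh_t4 <- SurfaceMesh(V4, crown$mesh@faces)
  # offset must not fold the surface
  n0 <- faceNormalsRaw(crown$mesh@vertices, crown$mesh@faces)
  n4 <- faceNormalsRaw(V4, mesh_t4@faces)
  if (any(rowSums(n0 * n4) <= 0))
    stop("plaque offset self-intersects: thickness too large for curvature")
  stained_v <- vparts$G >= tau_dye | tv >= spec$detection_limit
  list(mesh_t4 = mesh_t4,
       truth = list(true_volume = true_volume, true_area = true_area,
                    true_coverage_fraction = true_cov,
                    true_stained_fraction = true_stained,
                    true_dark_fraction = true_dark,
                    thickness = tv,
                    stained = stained_v,
                    dark = stained_v & vparts$G >= tau_dark,
                    transform = identityTransform()))
}

#' Corrupt a scan with noise and a pose offset
#'
#' Adds zero-mean Gaussian displacement along vertex normals (scanner
#' noise) and applies a rigid pose perturbation (random axis at the
#' specified magnitudes); the applied transform is returned so recovery
#' can be checked.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param noise_sd mm
#' @param rotation_deg pose rotation magnitude
#' @param translation_mm pose translation magnitude
#' @param seed integer
#' @return list with `mesh` and `transform` (the applied pose)
#' @export
corruptScan <- function(mesh, noise_sd = 0.005, rotation_deg = 3,
                        translation_mm = 1, seed = 1L) {
  set.seed(seed)
  V <- mesh@vertices
  if (noise_sd > 0) {
    nrm <- vertexNormals(mesh)
    V <- V + nrm * rnorm(nrow(V), 0, noise_sd)
  }
  trans <- identityTransform()
  if (rotation_deg != 0 || translation_mm != 0) {
    axis <- normalize3(rnorm(3))
    shift <- normalize3(rnorm(3)) * translation_mm
    trans <- axisAngleTransform(axis, rotation_deg * pi / 180, shift)
  }
  m2 <- applyTransform(trans, SurfaceMesh(V, mesh@faces))
  list(mesh = m2, transform = trans)
}

#' Render a synthetic two-tone disclosed image
#'
#' Orthographic render of the plaque-bearing surface: pale enamel
#' background, pink where plaque is present, purple on the dark (mature)
#' sub-region, plus additive pixel noise. Per-pixel ground-truth class
#' masks are returned for classifier evaluation.
#'
#' @param crown result of [makeCrown()]
#' @param plaque result of [addPlaque()]
#' @param spec the [syntheticSpec()]
#' @param seed RNG seed for pixel noise
#' @return list with `image` (\linkS4class{DisclosedImage}) and
#'   `truth_classes` (integer H x W: 1/2/3)
#' @export
renderDisclosedImage <- function(crown, plaque, spec = syntheticSpec(),
                                 seed = spec$seed) {
  pspec <- projectionSpec(mesh = crown$mesh, pixel_size = spec$pixel_size)
  vals <- cbind(as.numeric(plaque$truth$stained),
                as.numeric(plaque$truth$dark))
  ras <- rasterizeMesh(crown$mesh, vals, pspec)
  H <- ras$H; W <- ras$W
  stainv <- ras$value[, , 1]; darkv <- ras$value[, , 2]
  covered <- ras$covered
  cls <- matrix(1L, H, W)
  cls[covered & !is.na(stainv) & stainv > 0.5] <- 2L
  cls[covered & !is.na(darkv) & darkv > 0.5] <- 3L
  pal <- rbind(non_plaque = c(0.96, 0.93, 0.80),  # pale enamel
               light_pink = c(0.93, 0.45, 0.60),  # erythrosine-like pink
               dark_purple = c(0.42, 0.22, 0.55)) # gentian-violet-like
  img <- array(0, c(H, W, 3))
  for (k in 1:3) {
    ch <- pal[cls, k]
    dim(ch) <- c(H, W)
    ch[!covered] <- 0.55  # neutral background outside the surface
    img[, , k] <- ch
  }
  set.seed(seed)
  img <- img + array(rnorm(length(img), 0, spec$image_noise_sd), dim(img))
  img[] <- pmin(1, pmax(0, img))
  truth <- cls
  truth[!covered] <- 1L
  list(image = DisclosedImage(img, covered, toothId(crown$roi)),
       truth_classes = truth)
}

## Turesky-style banded score from a coverage fraction of the surface:
## 0 none; 1 flecks; 2 thin band (<=1 mm); 3 band up to 1/3; 4 1/3..2/3;
## 5 over 2/3. Band heights converted to area fractions of a ~10 mm tall
## surface.
tureskyFromCoverage <- function(cov, band_mm = 1, height_mm = 10) {
  thin <- band_mm / height_mm
  ifelse(cov <= 0, 0L,
  ifelse(cov < 0.03, 1L,
  ifelse(cov <= thin, 2L,
  ifelse(cov <= 1 / 3, 3L,
  ifelse(cov <= 2 / 3, 4L, 5L)))))
}

#' Simulate a cohort of plaque-bearing surfaces
#'
#' Draws per-surface plaque parameters (volumetric coverage from a beta
#' law centred near 19%, stain ratio log-normal around 2.4, maturity and
#' thickness scales from uniform ranges), computes analytic ground truth
#' for each surface, and synthesizes TMQHPlI site scores from the true
#' stained (TDP) and dark (DDP) coverages via the Turesky band
#' definitions with ordinal examiner noise (+-1 with probability 0.1).
#' Meshes and images are only generated when requested; the record table
#' alone is sufficient for the statistics layer.
#'
#' @param n_subjects,teeth_per_subject cohort dimensions
#' @param spec base [syntheticSpec()]; per-surface fields are varied
#' @param seed integer master seed
#' @param with_meshes also build T0/T4 meshes per surface
#' @param with_images also render disclosed images (implies meshes)
#' @return list with `records` (one row per surface: ids, true coverage /
#'   volume / dark fraction, TMQHPlI means) plus `site_scores`, and
#'   optional `surfaces` (per-surface crown/plaque/image objects)
#' @export
generateCohort <- function(n_subjects = 15L, teeth_per_subject = 10L,
                           spec = syntheticSpec(), seed = 1L,
                           with_meshes = FALSE, with_images = FALSE) {
  if (with_images) with_meshes <- TRUE
  set.seed(seed)
  teeth <- c("14", "13", "12", "11", "21", "22", "23", "24", "15", "25")
  teeth <- teeth[seq_len(teeth_per_subject)]
  n <- n_subjects * teeth_per_subject
  cov <- rbeta(n, 3, 13)                # volumetric: mean ~0.19, SD ~0.09
  ratio <- exp(rnorm(n, log(2.4), 0.15))
  mat <- runif(n, 0.4, 0.6)
  thick <- runif(n, 0.08, 0.22)
  surf_seed <- sample.int(1e6, n)
  records <- NULL
  site_rows <- NULL
  surfaces <- if (with_meshes) vector("list", n) else NULL
  idx <- 0L
  for (s in seq_len(n_subjects)) {
    for (tt in teeth) {
      idx <- idx + 1L
      sp <- spec
      sp$coverage_fraction <- cov[idx]
      sp$stain_ratio <- ratio[idx]
      sp$maturity_fraction <- mat[idx]
      sp$max_thickness <- thick[idx]
      sp$seed <- surf_seed[idx]
      crown <- makeCrown(sp)
      pl <- addPlaque(crown, sp, n_fine = 256L)
      tr <- pl$truth
      # site coverages: mesial/central/distal thirds get correlated noise
      sitecov <- pmin(1, pmax(0, tr$true_stained_fraction *
                                (1 + rnorm(3, 0, 0.15))))
      base <- tureskyFromCoverage(sitecov)
      darkcov <- tr$true_stained_fraction * tr$true_dark_fraction
      sited <- pmin(1, pmax(0, darkcov * (1 + rnorm(3, 0, 0.15))))
      based <- tureskyFromCoverage(sited)
      noise <- function(sc) {
        flip <- runif(3) < 0.1
        pmin(5L, pmax(0L, sc + ifelse(flip, sample(c(-1L, 1L), 3,
                                                   replace = TRUE), 0L)))
      }
      tdp <- noise(base); ddp <- pmin(noise(based), tdp)
      site_rows <- rbind(site_rows, data.frame(
        subject_id = sprintf("S%02d", s), tooth_id = tt,
        variant = rep(c("TDP", "DDP"), each = 3),
        site = rep(c("mesial", "central", "distal"), 2),
        score = c(tdp, ddp), stringsAsFactors = FALSE))
      records <- rbind(records, data.frame(
        subject_id = sprintf("S%02d", s), tooth_id = tt,
        true_volume = tr$true_volume, true_area = tr$true_area,
        true_coverage = tr$true_coverage_fraction,
        true_stained_fraction = tr$true_stained_fraction,
        true_dark_fraction = tr$true_dark_fraction,
        tmqhpli_tdp_mean = mean(tdp), tmqhpli_ddp_mean = mean(ddp),
        stringsAsFactors = FALSE))
      if (with_meshes) {
        scan <- corruptScan(pl$mesh_t4, spec$scan_noise_sd,
                            spec$pose_rotation_deg,
                            spec$pose_translation_mm,
                            seed = surf_seed[idx] + 1L)
        surfaces[[idx]] <- list(
          subject_id = sprintf("S%02d", s), tooth_id = tt,
          crown = crown, plaque = pl, scan = scan,
          image = if (with_images)
            renderDisclosedImage(crown, pl, sp, seed = surf_seed[idx] + 2L))
      }
    }
  }
  rownames(records) <- NULL
  list(records = records, site_scores = site_rows, surfaces = surfaces)
}

#' Simulate a two-regime volume-vs-coverage cohort
#'
#' Generates (total coverage, volume) pairs following a continuous
#' two-segment linear law: below the breakpoint volume grows at
#' `slope_below` per coverage point (lateral spread of thin new plaque),
#' above it at `slope_below * slope_ratio` (vertical thickening of mature
#' plaque), plus Gaussian noise.
#'
#' @param n surfaces
#' @param breakpoint percent coverage (default 32.5)
#' @param slope_below mm^3 per percent
#' @param slope_ratio above/below slope ratio (default 2)
#' @param noise_sd mm^3
#' @param seed integer
#' @return data.frame with `plani_tot` and `vpi`
#' @export
simulateGrowthRegimes <- function(n = 150L, breakpoint = 32.5,
                                  slope_below = 0.015, slope_ratio = 2,
                                  noise_sd = 0.1, seed = 1L) {
  set.seed(seed)
  x <- runif(n, 4, 96)
  y <- 0.1 + slope_below * x +
    slope_below * (slope_ratio - 1) * pmax(x - breakpoint, 0) +
    rnorm(n, 0, noise_sd)
  data.frame(plani_tot = x, vpi = pmax(0, y))
}
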