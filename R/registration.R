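## Rigid registration: coarse principal-axes pre-alignment of whole models,
## then robust trimmed point-to-plane ICP on each ROI pair. T4 (plaque
## bearing) is always moved into the T0 (clean) frame so that positive
## surface deviation means de-novo deposit.

#' Construct a rigid transform
#' @param rotation 3 x 3 proper orthonormal matrix
#' @param translation length-3 numeric (mm)
#' @return a \linkS4class{RigidTransform}
#' @export
rigidTransform <- function(rotation = diag(3), translation = c(0, 0, 0)) {
  new("RigidTransform", rotation = rotation,
      translation = as.numeric(translation))
}

#' Identity transform
#' @return a \linkS4class{RigidTransform}
#' @export
identityTransform <- function() rigidTransform()

#' Rotation from axis and angle
#' @param axis length-3 vector (normalized internally)
#' @param angle radians
#' @param translation optional length-3 (mm)
#' @return a \linkS4class{RigidTransform}
#' @export
axisAngleTransform <- function(axis, angle, translation = c(0, 0, 0)) {
  a <- normalize3(axis)
  K <- matrix(c(0, a[3], -a[2], -a[3], 0, a[1], a[2], -a[1], 0), 3, 3)
  R <- diag(3) + sin(angle) * K + (1 - cos(angle)) * (K %*% K)
  rigidTransform(orthonormalize(R), translation)
}

## re-project a near-rotation onto SO(3) (SVD polar factor)
orthonormalize <- function(R) {
  s <- svd(R)
  R2 <- s$u %*% t(s$v)
  if (det(R2) < 0) R2 <- s$u %*% diag(c(1, 1, -1)) %*% t(s$v)
  R2
}

#' Compose transforms
#' @param a,b \linkS4class{RigidTransform}s; `b` is applied first
#' @return a \linkS4class{RigidTransform} equal to a(b(x))
#' @export
composeTransforms <- function(a, b) {
  rigidTransform(orthonormalize(a@rotation %*% b@rotation),
                 as.numeric(a@rotation %*% b@translation) + a@translation)
}

#' Invert a transform
#' @param x a \linkS4class{RigidTransform}
#' @return its inverse
#' @export
invertTransform <- function(x) {
  rigidTransform(t(x@rotation), as.numeric(-t(x@rotation) %*% x@translation))
}

#' Rotation angle of a transform
#' @param x a \linkS4class{RigidTransform}
#' @return angle in radians (in [0, pi])
#' @export
rotationAngle <- function(x) {
  acos(max(-1, min(1, (sum(diag(x@rotation)) - 1) / 2)))
}

#' Serialize / read a transform as a 4 x 4 homogeneous matrix in JSON
#' @param x a \linkS4class{RigidTransform}
#' @param path JSON path
#' @return `path` (write) or a \linkS4class{RigidTransform} (read)
#' @export
writeTransformJSON <- function(x, path) {
  H <- rbind(cbind(x@rotation, x@translation), c(0, 0, 0, 1))
  jsonlite::write_json(list(matrix = H), path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname writeTransformJSON
#' @export
readTransformJSON <- function(path) {
  H <- jsonlite::fromJSON(path)$matrix
  rigidTransform(orthonormalize(H[1:3, 1:3]), H[1:3, 4])
}

#' Coarse pre-alignment of whole models
#'
#' Aligns centroids and principal axes of the T4 model to the T0 model. The
#' four proper-rotation sign choices of the matched axes are disambiguated
#' by the smallest RMS nearest-surface distance after rotation. Degenerate
#' principal axes (two equal covariance eigenvalues within 1e-9 relative)
#' fall back to centroid-only alignment with a warning.
#'
#' @param mesh_t4 moving \linkS4class{SurfaceMesh} (plaque-bearing scan)
#' @param mesh_t0 fixed \linkS4class{SurfaceMesh} (clean reference)
#' @param n_sample vertices sampled per mesh for the sign disambiguation
#' @return a \linkS4class{RigidTransform} mapping T4 into the T0 frame
#' @export
preAlign <- function(mesh_t4, mesh_t0, n_sample = 1000L) {
  v4 <- mesh_t4@vertices; v0 <- mesh_t0@vertices
  c4 <- colMeans(v4); c0 <- colMeans(v0)
  e4 <- eigen(cov(v4), symmetric = TRUE)
  e0 <- eigen(cov(v0), symmetric = TRUE)
  if (min(diff(sort(e4$values))) < 1e-9 * max(abs(e4$values)) ||
      min(diff(sort(e0$values))) < 1e-9 * max(abs(e0$values))) {
    warning("degenerate principal axes; centroid-only pre-alignment")
    return(rigidTransform(diag(3), c0 - c4))
  }
  U4 <- e4$vectors; U0 <- e0$vectors
  if (det(U4) < 0) U4[, 3] <- -U4[, 3]
  if (det(U0) < 0) U0[, 3] <- -U0[, 3]
  signs <- list(c(1, 1, 1), c(1, -1, -1), c(-1, 1, -1), c(-1, -1, 1))
  idx <- if (nrow(v4) > n_sample)
    round(seq(1, nrow(v4), length.out = n_sample)) else seq_len(nrow(v4))
  best <- NULL; bestRMS <- Inf
  for (s in signs) {
    R <- U0 %*% diag(s) %*% t(U4)
    tr <- rigidTransform(orthonormalize(R), c0 - as.numeric(R %*% c4))
    moved <- applyTransform(tr, v4[idx, , drop = FALSE])
    rms <- sqrt(mean(closestOnMesh(moved, mesh_t0)$dist^2))
    if (rms < bestRMS) { bestRMS <- rms; best <- tr }
  }
  best
}

#' Robust best-fit superimposition of an ROI pair
#'
#' Trimmed point-to-plane iterative closest point. Correspondences are
#' symmetric (moved T4 vertices against the T0 surface and T0 vertices
#' against the moved T4 surface), capped at `max_corr_dist`; at each
#' iteration the `trim_fraction` of pairs with smallest distance is kept
#' and a linearized point-to-plane update solved on it. Because de-novo
#' plaque is a one-sided positive offset, trimming lets the plaque-free
#' geometry anchor the fit without knowing plaque extent in advance.
#'
#' Iterates until the trimmed mean absolute distance changes by less than
#' `tol` or `max_iter` iterations; the best iterate (lowest trimmed mean
#' absolute distance) is returned, flagged non-converged when the tolerance
#' was never reached.
#'
#' @param roi_t4 moving ROI submesh (\linkS4class{SurfaceMesh})
#' @param roi_t0 fixed ROI submesh
#' @param init initial \linkS4class{RigidTransform} (e.g. from [preAlign()])
#' After the trimmed phase converges, a one-sided refinement pass
#' exploits the one-sidedness of plaque directly: scanner noise is
#' estimated from the negative residual tail (deposits never push the T4
#' surface inside T0, so negatives are pure noise), and the fit is
#' re-solved keeping only correspondences with signed residual below
#' about 2.5 estimated noise SDs. This removes the inward bias that
#' fraction-trimming alone leaves when plaque covers a large share of the
#' surface.
#'
#' @param trim_fraction fraction of correspondences kept (default 0.6)
#' @param max_corr_dist correspondence cap, mm (default 1.0)
#' @param tol convergence tolerance on mean abs distance change, mm
#' @param max_iter iteration cap
#' @param refine run the one-sided noise-calibrated refinement pass
#' @return an \linkS4class{AlignmentReport}
#' @export
bestFitROI <- function(roi_t4, roi_t0, init = identityTransform(),
                       trim_fraction = 0.6, max_corr_dist = 1.0,
                       tol = 1e-6, max_iter = 100L, refine = TRUE) {
  stopifnot(trim_fraction > 0, trim_fraction <= 1)
  v4 <- roi_t4@vertices
  v0 <- roi_t0@vertices
  n0 <- vertexNormals(roi_t0)
  fn0 <- faceNormals(roi_t0)

  # symmetric capped correspondences for the current transform:
  # p = point on moved T4, q = matching point on T0, nn = T0 plane normal
  correspondences <- function(cur) {
    m4 <- applyTransform(cur, roi_t4)
    hitA <- closestOnMesh(m4@vertices, roi_t0)
    hitB <- closestOnMesh(v0, m4)
    p <- rbind(m4@vertices, hitB$point)
    q <- rbind(hitA$point, v0)
    nn <- rbind(fn0[hitA$face, , drop = FALSE], n0)
    d <- c(hitA$dist, hitB$dist)
    ok <- d <= max_corr_dist
    if (sum(ok) < 50L) stop("fewer than 50 correspondence points")
    list(p = p[ok, , drop = FALSE], q = q[ok, , drop = FALSE],
         nn = nn[ok, , drop = FALSE], d = d[ok],
         dA = hitA$dist[hitA$dist <= max_corr_dist])
  }
  solveP2P <- function(p, q, nn) {
    # linearized point-to-plane: rows [p x n, n], rhs n.(q - p)
    A <- cbind(p[, 2] * nn[, 3] - p[, 3] * nn[, 2],
               p[, 3] * nn[, 1] - p[, 1] * nn[, 3],
               p[, 1] * nn[, 2] - p[, 2] * nn[, 1],
               nn)
    b <- rowSums(nn * (q - p))
    x <- tryCatch(solve(crossprod(A), crossprod(A, b)),
                  error = function(e) qr.solve(A, b))
    if (sqrt(sum(x[1:3]^2)) < 1e-12) rigidTransform(diag(3), x[4:6])
    else axisAngleTransform(x[1:3], sqrt(sum(x[1:3]^2)), x[4:6])
  }

  totalIter <- 0L

  # fraction-trimmed ICP from a starting transform
  runTrimmed <- function(start, trimf, maxit) {
    cur <- start; best <- start
    bestStats <- c(Inf, 0); prevMean <- Inf
    converged <- FALSE; it <- 0L
    repeat {
      co <- correspondences(cur)
      kd <- sort(co$dA)[seq_len(max(1L, floor(trimf * length(co$dA))))]
      curStats <- c(mean(kd), if (length(kd) > 1) sd(kd) else 0)
      if (curStats[1] < bestStats[1]) { best <- cur; bestStats <- curStats }
      if (abs(prevMean - curStats[1]) < tol) { converged <- TRUE; break }
      prevMean <- curStats[1]
      if (it >= maxit) break
      it <- it + 1L
      nkeep <- min(length(co$d), max(50L, floor(trimf * length(co$d))))
      keep <- order(co$d)[seq_len(nkeep)]
      cur <- composeTransforms(solveP2P(co$p[keep, , drop = FALSE],
                                        co$q[keep, , drop = FALSE],
                                        co$nn[keep, , drop = FALSE]), cur)
    }
    totalIter <<- totalIter + it
    list(trans = best, stats = bestStats, frac = trimf,
         converged = converged)
  }

  # one-sided noise-calibrated refinement; tail_spread measures the
  # sharpness of the lower (noise-only) residual tail: a clean-anchored
  # fit has a tight lower tail, a plaque-anchored one a smeared tail
  oneSided <- function(start) {
    cur <- start
    out <- NULL
    sigma_prev <- Inf
    for (pass in seq_len(30L)) {
      co <- correspondences(cur)
      r <- rowSums(co$nn * (co$p - co$q))   # signed: positive = deposit
      neg <- r[r < 0]
      sigma <- if (length(neg) >= 20L) median(-neg) / 0.6745 else 0
      # monotone non-increasing noise estimate: residual misalignment can
      # only inflate it, and letting it grow feeds back into a wider band
      sigma <- min(sigma, sigma_prev)
      sigma_prev <- sigma
      # symmetric band: an asymmetric one would re-centre with a bias
      keep <- abs(r) <= 2.5 * sigma + 1e-9
      if (sum(keep) < 50L) break
      dk <- co$d[keep]
      out <- list(trans = cur,
                  stats = c(mean(dk), if (length(dk) > 1) sd(dk) else 0),
                  frac = sum(keep) / length(r),
                  tail_spread = diff(quantile(r, c(0.05, 0.25),
                                              names = FALSE)))
      delta <- solveP2P(co$p[keep, , drop = FALSE],
                        co$q[keep, , drop = FALSE],
                        co$nn[keep, , drop = FALSE])
      step <- rotationAngle(delta) * 10 + # ~mm at a 10 mm patch radius
        sqrt(sum(delta@translation^2))
      if (step < tol) break
      cur <- composeTransforms(delta, cur)
      totalIter <<- totalIter + 1L
    }
    out
  }

  phase1 <- runTrimmed(init, trim_fraction, max_iter)
  result <- phase1
  if (refine) {
    candA <- oneSided(phase1$trans)
    # second basin: a low-trim run from the initial pose locks onto the
    # dense clean-point cluster even when plaque dominates the surface
    candB <- NULL
    if (trim_fraction > 0.3) {
      phase1b <- runTrimmed(init, 0.25, min(max_iter, 40L))
      candB <- oneSided(phase1b$trans)
    }
    cands <- Filter(Negate(is.null), list(candA, candB))
    if (length(cands)) {
      spreads <- vapply(cands, function(cc) cc$tail_spread, 0)
      pick <- cands[[which.min(spreads)]]
      pick$converged <- phase1$converged
      result <- pick
    }
  }
  new("AlignmentReport", transform = result$trans,
      mean_abs_distance = result$stats[1], sd_distance = result$stats[2],
      inlier_fraction = min(1, max(1e-12, result$frac)),
      iterations = totalIter,
      converged = isTRUE(phase1$converged))
}
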