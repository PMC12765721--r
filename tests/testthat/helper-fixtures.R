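# Shared fixtures built in code. All meshes are millimetre-scale.

# flat rectangular patch mesh (rows of a regular grid), normals +z
flatPatch <- function(nx = 11L, ny = 11L, sx = 10, sy = 10, z = 0) {
  xs <- seq(0, sx, length.out = nx)
  ys <- seq(0, sy, length.out = ny)
  V <- cbind(rep(xs, times = ny), rep(ys, each = nx), z)
  idx <- function(i, j) (j - 1L) * nx + i
  i <- rep(seq_len(nx - 1L), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx - 1L)
  F1 <- cbind(idx(i, j), idx(i + 1L, j), idx(i + 1L, j + 1L))
  F2 <- cbind(idx(i, j), idx(i + 1L, j + 1L), idx(i, j + 1L))
  SurfaceMesh(V, rbind(F1, F2))
}

# unit cube as a triangle soup (12 faces), for STL fixtures
unitCubeMesh <- function() {
  v <- as.matrix(expand.grid(0:1, 0:1, 0:1))
  colnames(v) <- NULL
  quads <- list(c(1, 2, 4, 3), c(5, 7, 8, 6), c(1, 5, 6, 2),
                c(3, 4, 8, 7), c(1, 3, 7, 5), c(2, 6, 8, 4))
  f <- do.call(rbind, lapply(quads, function(q)
    rbind(q[c(1, 2, 3)], q[c(1, 3, 4)])))
  SurfaceMesh(v, f)
}

# small curved crown pair with an analytic smooth offset field (gentle
# slopes), for measurement-accuracy oracles
analyticOffsetPair <- function(edge = 0.1, t0 = 0.05, amp = 0.02) {
  spec <- syntheticSpec(edge_length = edge, seed = 1)
  crown <- makeCrown(spec)
  uv <- crown$uv
  tfield <- t0 + amp * cos(pi * uv[, 1]) * cos(pi * uv[, 2])
  nrm <- plaquemetry:::crownNormal(uv[, 1], uv[, 2], spec)
  t4 <- SurfaceMesh(vertices(crown$mesh) + nrm * tfield,
                    faces(crown$mesh))
  list(crown = crown, t4 = t4, tfield = tfield, spec = spec)
}

# independent brute-force closest point on a mesh: per-face distance via
# closed-form projection onto the triangle plane + 2D clamping to edges
bruteClosest <- function(p, mesh) {
  V <- vertices(mesh); Fc <- faces(mesh)
  best <- Inf; bestpt <- NULL
  for (f in seq_len(nrow(Fc))) {
    a <- V[Fc[f, 1], ]; b <- V[Fc[f, 2], ]; c <- V[Fc[f, 3], ]
    # minimize |a + s(b-a) + t(c-a) - p|^2 over the simplex by solving
    # the unconstrained problem then clamping over candidate edges
    E1 <- b - a; E2 <- c - a; d0 <- a - p
    G <- rbind(c(sum(E1 * E1), sum(E1 * E2)),
               c(sum(E1 * E2), sum(E2 * E2)))
    rhs <- -c(sum(E1 * d0), sum(E2 * d0))
    st <- tryCatch(solve(G, rhs), error = function(e) c(0, 0))
    cand <- list(st)
    segPt <- function(p0, p1) {
      u <- sum((p - p0) * (p1 - p0)) / sum((p1 - p0)^2)
      u <- min(1, max(0, u))
      p0 + u * (p1 - p0)
    }
    if (st[1] < 0 || st[2] < 0 || sum(st) > 1) {
      pts <- rbind(segPt(a, b), segPt(b, c), segPt(c, a))
    } else {
      pts <- matrix(a + st[1] * E1 + st[2] * E2, 1)
    }
    for (r in seq_len(nrow(pts))) {
      d <- sqrt(sum((pts[r, ] - p)^2))
      if (d < best) { best <- d; bestpt <- pts[r, ] }
    }
  }
  list(dist = best, point = bestpt)
}
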