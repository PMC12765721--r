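## Low-level triangle-mesh geometry. Everything operates on the raw
## vertex/face matrices of a SurfaceMesh; faces are 1-based.

crossprod3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

normalize3 <- function(v) {
  n <- sqrt(sum(v^2))
  if (n < 1e-12) stop("cannot normalize a zero vector")
  v / n
}

#' Construct a SurfaceMesh
#'
#' Builds a validated mesh from raw matrices. Use [readMesh()] for files.
#'
#' @param vertices n x 3 numeric matrix (mm)
#' @param faces m x 3 integer matrix of 1-based vertex indices
#' @param colors optional n x 3 matrix in [0, 1]
#' @return a \linkS4class{SurfaceMesh}
#' @export
SurfaceMesh <- function(vertices, faces, colors = NULL) {
  storage.mode(vertices) <- "double"
  faces <- matrix(as.integer(faces), ncol = 3)
  if (is.null(colors)) colors <- matrix(numeric(0), 0, 3)
  new("SurfaceMesh", vertices = vertices, faces = faces, colors = colors)
}

#' Construct an ROIMask
#'
#' @param tooth_id FDI tooth label (character or number)
#' @param vertex_ids integer vertex indices into the mesh
#' @param timepoint "T0" or "T4"
#' @return an \linkS4class{ROIMask}
#' @export
ROIMask <- function(tooth_id, vertex_ids, timepoint) {
  new("ROIMask", tooth_id = as.character(tooth_id),
      vertex_ids = as.integer(vertex_ids), timepoint = timepoint)
}

#' Construct a ScanPair
#'
#' @param subject_id character
#' @param mesh_t0,mesh_t4 \linkS4class{SurfaceMesh} at the two timepoints
#' @param rois list of `list(t0 = , t4 = )` ROIMask pairs; names taken from
#'   the T0 tooth ids if unnamed
#' @return a \linkS4class{ScanPair}
#' @export
ScanPair <- function(subject_id, mesh_t0, mesh_t4, rois = list()) {
  if (length(rois) && is.null(names(rois)))
    names(rois) <- vapply(rois, function(r) r$t0@tooth_id, character(1))
  new("ScanPair", subject_id = as.character(subject_id),
      mesh_t0 = mesh_t0, mesh_t4 = mesh_t4, rois = rois)
}

## per-face doubled-area vectors; rows = faces
faceNormalsRaw <- function(v, f) {
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
        e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
        e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
}

#' Per-face triangle areas
#' @param mesh a \linkS4class{SurfaceMesh}
#' @return numeric vector, mm^2 per face
#' @export
faceAreas <- function(mesh) {
  n <- faceNormalsRaw(mesh@vertices, mesh@faces)
  0.5 * sqrt(rowSums(n^2))
}

#' Outward unit face normals
#' @param mesh a \linkS4class{SurfaceMesh}
#' @return m x 3 matrix of unit normals (orientation from face winding)
#' @export
faceNormals <- function(mesh) {
  n <- faceNormalsRaw(mesh@vertices, mesh@faces)
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

#' Area-weighted unit vertex normals
#' @param mesh a \linkS4class{SurfaceMesh}
#' @return n x 3 matrix of unit normals
#' @export
vertexNormals <- function(mesh) {
  fn <- faceNormalsRaw(mesh@vertices, mesh@faces) # area-weighted already
  n <- matrix(0, nVertices(mesh), 3)
  f <- mesh@faces
  for (k in 1:3) {
    n[, 1] <- n[, 1] + unname(rowsumAt(fn[, 1], f[, k], nVertices(mesh)))
    n[, 2] <- n[, 2] + unname(rowsumAt(fn[, 2], f[, k], nVertices(mesh)))
    n[, 3] <- n[, 3] + unname(rowsumAt(fn[, 3], f[, k], nVertices(mesh)))
  }
  len <- sqrt(rowSums(n^2))
  len[len < 1e-300] <- 1
  n / len
}

## scatter-add x into bins 1..n
rowsumAt <- function(x, idx, n) {
  out <- numeric(n)
  s <- rowsum(x, idx)
  out[as.integer(rownames(s))] <- s[, 1]
  out
}

#' Barycentric (lumped) per-vertex area weights
#'
#' One third of the total area of triangles incident to each vertex; sums
#' exactly to the mesh surface area.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @return numeric vector of mm^2 weights, one per vertex
#' @export
vertexAreaWeights <- function(mesh) {
  fa <- faceAreas(mesh) / 3
  a <- numeric(nVertices(mesh))
  for (k in 1:3) a <- a + rowsumAt(fa, mesh@faces[, k], nVertices(mesh))
  a
}

#' Merge duplicate vertices and drop degenerate faces
#'
#' Cleanup applied on mesh load: vertices closer than `tol` are merged
#' (grid rounding) and zero-area faces are removed with a warning. The
#' tolerance is far below the 0.01 mm plaque detection limit, so cleanup
#' cannot create apparent plaque.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param tol merge tolerance, mm
#' @return cleaned \linkS4class{SurfaceMesh}
#' @export
cleanMesh <- function(mesh, tol = 1e-6) {
  v <- mesh@vertices; f <- mesh@faces
  key <- paste(round(v[, 1] / tol), round(v[, 2] / tol), round(v[, 3] / tol))
  first <- !duplicated(key)
  map <- match(key, key[first])
  v2 <- v[first, , drop = FALSE]
  col2 <- if (nrow(mesh@colors)) mesh@colors[first, , drop = FALSE] else NULL
  f2 <- matrix(map[f], ncol = 3)
  # degenerate: repeated vertex or (numerically) zero area
  dup <- f2[, 1] == f2[, 2] | f2[, 2] == f2[, 3] | f2[, 1] == f2[, 3]
  m2 <- SurfaceMesh(v2, f2[!dup, , drop = FALSE], col2)
  area <- faceAreas(m2)
  zero <- area <= 1e-12
  ndeg <- sum(dup) + sum(zero)
  if (ndeg > 0) {
    warning(sprintf("dropped %d degenerate face(s) during mesh cleanup", ndeg))
    m2 <- SurfaceMesh(m2@vertices, m2@faces[!zero, , drop = FALSE], col2)
  }
  if (nFaces(m2) == 0L || surfaceArea(m2) <= 0)
    stop("mesh is empty after cleanup")
  m2
}

#' Extract the submesh induced by an ROI
#'
#' Keeps faces whose three vertices all belong to the ROI, re-indexing
#' vertices; records the original vertex ids in `orig_vertex_ids`.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param roi an \linkS4class{ROIMask} on that mesh
#' @return list with `mesh` (the submesh), `orig_vertex_ids`
#' @export
roiSubmesh <- function(mesh, roi) {
  ids <- sort(roi@vertex_ids)
  keep <- logical(nVertices(mesh)); keep[ids] <- TRUE
  f <- mesh@faces
  inroi <- keep[f[, 1]] & keep[f[, 2]] & keep[f[, 3]]
  f2 <- f[inroi, , drop = FALSE]
  if (nrow(f2) == 0L) stop("ROI induces no complete faces")
  map <- integer(nVertices(mesh)); map[ids] <- seq_along(ids)
  sm <- SurfaceMesh(mesh@vertices[ids, , drop = FALSE],
                    matrix(map[f2], ncol = 3),
                    if (nrow(mesh@colors)) mesh@colors[ids, , drop = FALSE])
  list(mesh = sm, orig_vertex_ids = ids)
}

## vertex adjacency as a list of integer vectors (undirected, from edges)
vertexAdjacency <- function(mesh) {
  f <- mesh@faces
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  e <- rbind(e, e[, 2:1])
  adj <- split(e[, 2], e[, 1])
  out <- vector("list", nVertices(mesh))
  out[as.integer(names(adj))] <- lapply(adj, function(x) unique(x))
  out
}

## connected components of a vertex subset under mesh edge connectivity
subsetComponents <- function(mesh, ids) {
  inset <- logical(nVertices(mesh)); inset[ids] <- TRUE
  adj <- vertexAdjacency(mesh)
  comp <- integer(nVertices(mesh))
  cur <- 0L
  for (s in ids) {
    if (comp[s] != 0L) next
    cur <- cur + 1L
    queue <- s; comp[s] <- cur
    while (length(queue)) {
      v <- queue[[1]]; queue <- queue[-1]
      nb <- adj[[v]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp[ids]
}

#' Closest points on a mesh surface
#'
#' Exact nearest point on the triangulated surface for each query point,
#' accelerated by a uniform spatial grid.
#'
#' @param points n x 3 query matrix
#' @param mesh target \linkS4class{SurfaceMesh}
#' @return list with `dist` (mm), `point` (n x 3), `face` (1-based index)
#' @export
closestOnMesh <- function(points, mesh) {
  if (!is.matrix(points)) points <- matrix(points, ncol = 3)
  .cpp_closest_on_mesh(points, mesh@vertices, mesh@faces - 1L)
}

setMethod("applyTransform", signature("RigidTransform", "SurfaceMesh"),
  function(transform, x) {
    SurfaceMesh(applyTransform(transform, x@vertices), x@faces,
                if (nrow(x@colors)) x@colors)
  })

setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, x) {
    t(transform@rotation %*% t(x)) +
      matrix(transform@translation, nrow(x), 3, byrow = TRUE)
  })
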