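## Mesh, ROI and score-table input/output. Units are always millimetres;
## there is no unit auto-detection.

meshFormatFromPath <- function(path) {
  ext <- tolower(sub(".*\\.", "", path))
  if (!ext %in% c("ply", "stl", "obj"))
    stop("cannot infer mesh format from extension: ", path)
  toupper(ext)
}

#' Read a triangulated surface scan
#'
#' Reads PLY (ASCII or binary little-endian), STL (ASCII or binary) or OBJ.
#' The mesh is cleaned on load: duplicate vertices within 1e-6 mm are
#' merged and degenerate (zero-area) faces dropped with a warning.
#' Coordinates are assumed to be millimetres.
#'
#' @param path file path
#' @param format "PLY", "STL" or "OBJ"; inferred from the extension when NULL
#' @param clean logical; apply vertex merge / degenerate-face cleanup
#' @return a \linkS4class{SurfaceMesh}
#' @export
readMesh <- function(path, format = NULL, clean = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  format <- if (is.null(format)) meshFormatFromPath(path) else toupper(format)
  mesh <- switch(format,
    PLY = readPLY(path),
    STL = readSTL(path),
    OBJ = readOBJ(path),
    stop("unsupported mesh format: ", format))
  if (clean) mesh <- cleanMesh(mesh) else validObject(mesh)
  mesh
}

#' Write a mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param path output path; format from extension unless given
#' @param format "PLY", "STL" or "OBJ"
#' @param binary write binary PLY/STL rather than ASCII
#' @param scalar optional per-vertex scalar stored as PLY property "quality"
#' @return `path`, invisibly
#' @export
writeMesh <- function(mesh, path, format = NULL, binary = FALSE,
                      scalar = NULL) {
  format <- if (is.null(format)) meshFormatFromPath(path) else toupper(format)
  switch(format,
    PLY = writePLY(mesh, path, binary = binary, scalar = scalar),
    STL = writeSTL(mesh, path, binary = binary),
    OBJ = writeOBJ(mesh, path),
    stop("unsupported mesh format: ", format))
  invisible(path)
}

## ---------------------------------------------------------------- PLY ----

readPLY <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  # header is always ASCII lines
  header <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("unexpected end of PLY header")
    header <- c(header, line)
    if (trimws(line) == "end_header") break
  }
  if (trimws(header[1]) != "ply") stop("not a PLY file: ", path)
  fmt <- grep("^format ", header, value = TRUE)[1]
  binary <- grepl("binary_little_endian", fmt)
  if (!binary && !grepl("ascii", fmt))
    stop("unsupported PLY format line: ", fmt)

  # parse element/property declarations
  elems <- list(); cur <- NULL
  for (line in header) {
    tok <- strsplit(trimws(line), "\\s+")[[1]]
    if (tok[1] == "element") {
      cur <- tok[2]
      elems[[cur]] <- list(count = as.integer(tok[3]), props = list())
    } else if (tok[1] == "property" && !is.null(cur)) {
      if (tok[2] == "list")
        elems[[cur]]$props[[tok[5]]] <- list(list = TRUE, ctype = tok[3],
                                             vtype = tok[4])
      else
        elems[[cur]]$props[[tok[3]]] <- list(list = FALSE, vtype = tok[2])
    }
  }
  if (is.null(elems$vertex) || is.null(elems$face))
    stop("PLY lacks vertex/face elements")

  plySize <- function(t) switch(t, char = 1L, uchar = 1L, int8 = 1L,
    uint8 = 1L, short = 2L, ushort = 2L, int16 = 2L, uint16 = 2L, int = 4L,
    uint = 4L, int32 = 4L, uint32 = 4L, float = 4L, float32 = 4L,
    double = 8L, float64 = 8L, stop("unknown PLY type ", t))
  plyRead <- function(raw, off, t, n = 1L) {
    sz <- plySize(t)
    what <- if (t %in% c("float", "float32", "double", "float64"))
      "double" else "integer"
    readBin(raw[(off + 1):(off + n * sz)], what, n = n, size = sz,
            endian = "little", signed = !(t %in% c("uchar", "uint8", "ushort",
                                                   "uint16")))
  }

  nv <- elems$vertex$count; nf <- elems$face$count
  vprops <- elems$vertex$props
  fprops <- elems$face$props
  idxname <- intersect(c("vertex_indices", "vertex_index"), names(fprops))[1]
  if (is.na(idxname)) stop("PLY face element lacks a vertex index list")

  if (binary) {
    raw <- readBin(con, "raw", n = file.size(path))
    off <- 0
    vals <- matrix(0, nv, length(vprops))
    colnames(vals) <- names(vprops)
    vsz <- vapply(vprops, function(p) plySize(p$vtype), integer(1))
    stride <- sum(vsz)
    # fast path: fixed-stride vertex block
    for (j in seq_along(vprops)) {
      p <- vprops[[j]]
      offs <- off + cumsum(c(0, vsz))[j] + stride * (seq_len(nv) - 1)
      sz <- plySize(p$vtype)
      vals[, j] <- vapply(offs, function(o) as.numeric(plyRead(raw, o, p$vtype)), 0)
    }
    off <- off + stride * nv
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      for (pn in names(fprops)) {
        p <- fprops[[pn]]
        if (p$list) {
          cnt <- plyRead(raw, off, p$ctype); off <- off + plySize(p$ctype)
          idx <- plyRead(raw, off, p$vtype, cnt)
          off <- off + cnt * plySize(p$vtype)
          if (pn == idxname) {
            if (cnt != 3L) stop("PLY faces must be triangles")
            f[i, ] <- idx + 1L
          }
        } else {
          off <- off + plySize(p$vtype)
        }
      }
    }
  } else {
    body <- readLines(con)
    body <- body[nzchar(trimws(body))]
    vlines <- body[seq_len(nv)]
    flines <- body[nv + seq_len(nf)]
    vals <- do.call(rbind, lapply(strsplit(trimws(vlines), "\\s+"), as.numeric))
    colnames(vals) <- names(vprops)
    ftok <- lapply(strsplit(trimws(flines), "\\s+"), as.integer)
    if (any(vapply(ftok, `[`, 0L, 1) != 3L))
      stop("PLY faces must be triangles")
    f <- do.call(rbind, lapply(ftok, function(x) x[2:4] + 1L))
  }
  v <- vals[, c("x", "y", "z"), drop = FALSE]
  colors <- NULL
  if (all(c("red", "green", "blue") %in% colnames(vals)))
    colors <- vals[, c("red", "green", "blue"), drop = FALSE] / 255
  SurfaceMesh(unname(v), f, colors)
}

writePLY <- function(mesh, path, binary = FALSE, scalar = NULL) {
  v <- mesh@vertices; f <- mesh@faces
  hasc <- nrow(mesh@colors) > 0
  hasq <- !is.null(scalar)
  header <- c("ply",
    sprintf("format %s 1.0",
            if (binary) "binary_little_endian" else "ascii"),
    sprintf("element vertex %d", nrow(v)),
    "property double x", "property double y", "property double z",
    if (hasc) c("property uchar red", "property uchar green",
                "property uchar blue"),
    if (hasq) "property double quality",
    sprintf("element face %d", nrow(f)),
    "property list uchar int vertex_indices",
    "end_header")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(header, con)
  if (binary) {
    cols <- round(mesh@colors * 255)
    for (i in seq_len(nrow(v))) {
      writeBin(as.numeric(v[i, ]), con, size = 8, endian = "little")
      if (hasc) writeBin(as.raw(cols[i, ]), con)
      if (hasq) writeBin(as.numeric(scalar[i]), con, size = 8,
                         endian = "little")
    }
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4, endian = "little")
    }
  } else {
    vl <- apply(v, 1, function(r) paste(format(r, digits = 17),
                                        collapse = " "))
    if (hasc) vl <- paste(vl, apply(round(mesh@colors * 255), 1, paste,
                                    collapse = " "))
    if (hasq) vl <- paste(vl, format(scalar, digits = 17))
    writeLines(vl, con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

## ---------------------------------------------------------------- STL ----

readSTL <- function(path) {
  sz <- file.size(path)
  con <- file(path, "rb")
  on.exit(close(con))
  head80 <- readBin(con, "raw", n = min(80, sz))
  isBinary <- FALSE
  if (sz >= 84) {
    ntri <- readBin(con, "integer", n = 1, size = 4, endian = "little")
    if (!is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)) isBinary <- TRUE
  }
  if (isBinary) {
    tri <- matrix(0, ntri * 3, 3)
    for (i in seq_len(ntri)) {
      vals <- readBin(con, "double", n = 12, size = 4, endian = "little")
      readBin(con, "raw", n = 2) # attribute byte count
      tri[(3 * i - 2):(3 * i), ] <- matrix(vals[4:12], 3, 3, byrow = TRUE)
    }
  } else {
    close(con); on.exit(NULL)
    lines <- readLines(path, warn = FALSE)
    vl <- grep("^\\s*vertex\\s", lines, value = TRUE)
    if (length(vl) == 0L || length(vl) %% 3 != 0L)
      stop("malformed ASCII STL: ", path)
    tri <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                                 function(x) as.numeric(x[2:4])))
  }
  n <- nrow(tri)
  SurfaceMesh(tri, matrix(seq_len(n), ncol = 3, byrow = TRUE))
}

writeSTL <- function(mesh, path, binary = FALSE) {
  v <- mesh@vertices; f <- mesh@faces
  fn <- faceNormals(mesh)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80), con)
    writeBin(as.integer(nrow(f)), con, size = 4, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.numeric(c(fn[i, ], t(v[f[i, ], ]))), con, size = 4,
               endian = "little")
      writeBin(raw(2), con)
    }
  } else {
    out <- c("solid mesh")
    fmt <- function(x) paste(format(x, digits = 17, scientific = TRUE),
                             collapse = " ")
    body <- vapply(seq_len(nrow(f)), function(i) {
      paste0("facet normal ", fmt(fn[i, ]), "\n outer loop\n",
             paste0("  vertex ", apply(v[f[i, ], , drop = FALSE], 1, fmt),
                    collapse = "\n"),
             "\n endloop\nendfacet")
    }, character(1))
    writeLines(c(out, body, "endsolid mesh"), path)
  }
  invisible(path)
}

## ---------------------------------------------------------------- OBJ ----

readOBJ <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vl <- grep("^v\\s", lines, value = TRUE)
  fl <- grep("^f\\s", lines, value = TRUE)
  if (!length(vl) || !length(fl)) stop("malformed OBJ: ", path)
  v <- do.call(rbind, lapply(strsplit(trimws(vl), "\\s+"),
                             function(x) as.numeric(x[2:4])))
  f <- do.call(rbind, lapply(strsplit(trimws(fl), "\\s+"), function(x) {
    idx <- as.integer(sub("/.*", "", x[-1]))
    if (length(idx) != 3L) stop("OBJ faces must be triangles")
    idx
  }))
  SurfaceMesh(v, f)
}

writeOBJ <- function(mesh, path) {
  v <- mesh@vertices; f <- mesh@faces
  writeLines(c(paste("v", format(v[, 1], digits = 17),
                     format(v[, 2], digits = 17),
                     format(v[, 3], digits = 17)),
               paste("f", f[, 1], f[, 2], f[, 3])), path)
  invisible(path)
}

## ---------------------------------------------------------------- ROI ----

#' Read ROI definitions from JSON
#'
#' The JSON document is an array of objects with fields `tooth_id`,
#' `timepoint` ("T0"/"T4") and either `vertex_ids` (1-based) or a closed
#' `boundary` polyline (ordered vertex indices, first = last, consecutive
#' entries joined by mesh edges) plus a `seed_vertex` interior to it, which
#' is flood-filled on the surface. ROIs must induce an edge-connected
#' submesh.
#'
#' @param path JSON file
#' @param mesh the \linkS4class{SurfaceMesh} the ROIs refer to
#' @return list of \linkS4class{ROIMask}
#' @export
readROI <- function(path, mesh) {
  defs <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(defs, function(d) {
    if (is.null(d$timepoint) || !d$timepoint %in% c("T0", "T4"))
      stop("ROI has unknown timepoint: ", d$timepoint)
    if (!is.null(d$vertex_ids)) {
      ids <- as.integer(unlist(d$vertex_ids))
    } else if (!is.null(d$boundary)) {
      ids <- floodFillROI(mesh, as.integer(unlist(d$boundary)),
                          as.integer(d$seed_vertex))
    } else stop("ROI needs vertex_ids or boundary")
    if (max(ids) > nVertices(mesh)) stop("ROI vertex ids exceed mesh")
    roi <- ROIMask(d$tooth_id, ids, d$timepoint)
    if (length(unique(subsetComponents(mesh, roi@vertex_ids))) != 1L)
      stop("ROI for tooth ", d$tooth_id, " is not edge-connected")
    roi
  })
}

#' Flood-fill the interior of a closed surface polyline
#'
#' Grows from `seed` over the vertex adjacency graph without crossing the
#' boundary loop; returns interior plus boundary vertices.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param boundary ordered vertex indices, first equal to last, consecutive
#'   pairs joined by mesh edges
#' @param seed an interior vertex
#' @return integer vertex ids of the enclosed region
#' @export
floodFillROI <- function(mesh, boundary, seed) {
  if (length(boundary) < 4L || boundary[1] != boundary[length(boundary)])
    stop("boundary polyline is not closed")
  loop <- boundary[-length(boundary)]
  adj <- vertexAdjacency(mesh)
  for (i in seq_along(loop)) {
    j <- if (i == length(loop)) 1L else i + 1L
    if (!loop[j] %in% adj[[loop[i]]])
      stop("boundary polyline does not follow mesh edges")
  }
  onloop <- logical(nVertices(mesh)); onloop[loop] <- TRUE
  if (onloop[seed]) stop("seed vertex lies on the boundary")
  visited <- logical(nVertices(mesh))
  visited[seed] <- TRUE
  queue <- seed
  while (length(queue)) {
    v <- queue[[1]]; queue <- queue[-1]
    nb <- adj[[v]]
    nb <- nb[!visited[nb] & !onloop[nb]]
    visited[nb] <- TRUE
    queue <- c(queue, nb)
  }
  if (sum(visited) > nVertices(mesh) / 2)
    warning("flood fill covered more than half the mesh; check seed side")
  sort(c(which(visited), loop))
}

## -------------------------------------------------------------- scores ----

#' Read a TMQHPlI site-score table
#'
#' CSV with columns subject_id, tooth_id, variant (TDP/DDP), site
#' (mesial/central/distal) and score (integer 0-5). Each
#' (subject, tooth, variant) must have exactly the three sites. A dark
#' (DDP) site score exceeding the total (TDP) score at the same site is
#' flagged with a warning, since dark plaque is a subset of total plaque.
#'
#' @param path CSV file
#' @return validated long-format data.frame
#' @export
readScores <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "tooth_id", "variant", "site", "score")
  if (!all(need %in% names(df)))
    stop("scores CSV must have columns: ", paste(need, collapse = ", "))
  df$subject_id <- as.character(df$subject_id)
  df$tooth_id <- as.character(df$tooth_id)
  if (!all(df$variant %in% c("TDP", "DDP"))) stop("variant must be TDP/DDP")
  if (!all(df$site %in% c("mesial", "central", "distal")))
    stop("site must be mesial/central/distal")
  if (any(is.na(df$score)) || any(df$score != round(df$score)) ||
      any(df$score < 0 | df$score > 5))
    stop("scores must be integers in 0..5")
  cnt <- aggregate(site ~ subject_id + tooth_id + variant, df,
                   function(s) length(unique(s)))
  if (any(cnt$site != 3L))
    stop("every (subject, tooth, variant) needs the 3 sites exactly once")
  if (nrow(df) != nrow(unique(df[, c("subject_id", "tooth_id", "variant",
                                     "site")])))
    stop("duplicate site rows present")
  # two-tone consistency: DDP (dark subset) should not exceed TDP
  wide <- merge(df[df$variant == "TDP", c(need[c(1, 2, 4, 5)])],
                df[df$variant == "DDP", c(need[c(1, 2, 4, 5)])],
                by = c("subject_id", "tooth_id", "site"),
                suffixes = c("_tdp", "_ddp"))
  bad <- wide$score_ddp > wide$score_tdp
  if (any(bad))
    warning(sprintf(
      "%d site(s) have DDP score > TDP score (dark plaque should be a subset of total)",
      sum(bad)))
  df
}
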