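## Canonical orthographic rendering of thickness fields. The projection is
## deterministic (view = area-weighted mean outward ROI normal by default)
## so that every rendered map is exactly repeatable, unlike ad-hoc viewer
## screenshots.

#' Build a projection specification
#'
#' @param view_direction unit 3-vector towards the viewer; when NULL and a
#'   mesh is given, the area-weighted mean outward normal of the mesh
#' @param up_vector in-plane "up"; default: global +z made orthogonal to
#'   the view (occluso-gingival convention), falling back to +y when the
#'   view is nearly axial
#' @param pixel_size mm per pixel (default 0.02)
#' @param mesh optional \linkS4class{SurfaceMesh} used for the defaults
#' @return a \linkS4class{ProjectionSpec}
#' @export
projectionSpec <- function(view_direction = NULL, up_vector = NULL,
                           pixel_size = 0.02, mesh = NULL) {
  if (is.null(view_direction)) {
    if (is.null(mesh)) stop("need a mesh to derive the default view")
    fn <- faceNormalsRaw(mesh@vertices, mesh@faces) # area-weighted
    view_direction <- normalize3(colSums(fn))
  } else view_direction <- normalize3(view_direction)
  if (is.null(up_vector)) {
    up_vector <- c(0, 0, 1)
    if (abs(sum(up_vector * view_direction)) > 0.99) up_vector <- c(0, 1, 0)
  }
  up_vector <- up_vector - sum(up_vector * view_direction) * view_direction
  new("ProjectionSpec", view_direction = normalize3(view_direction),
      up_vector = normalize3(up_vector), pixel_size = pixel_size)
}

projectionBasis <- function(spec) {
  w <- spec@view_direction
  v <- spec@up_vector
  u <- normalize3(crossprod3(v, w)) # right-handed: u x v = w
  rbind(u, v, w)
}

## rasterize per-vertex values of a mesh under a projection spec
## returns list(value = H x W x nc array, depth, covered, extent)
rasterizeMesh <- function(mesh, values, spec, pad = 1L) {
  B <- projectionBasis(spec)
  P <- mesh@vertices %*% t(B) # columns: u, v, depth
  px <- spec@pixel_size
  x0 <- min(P[, 1]) - pad * px
  y0 <- min(P[, 2]) - pad * px
  W <- as.integer(ceiling((max(P[, 1]) - x0) / px)) + 1L + pad
  H <- as.integer(ceiling((max(P[, 2]) - y0) / px)) + 1L + pad
  if (!is.matrix(values)) values <- matrix(values, ncol = 1)
  res <- .cpp_rasterize(P, mesh@faces - 1L, values, W, H, x0, y0, px)
  nc <- ncol(values)
  val <- array(res$value, dim = c(W, H, nc)) # x fastest
  val <- aperm(val, c(2, 1, 3)) # rows = y, cols = x
  list(value = val,
       depth = t(matrix(res$depth, W, H)),
       covered = t(matrix(res$covered, W, H)),
       face = t(matrix(res$face, W, H)),
       x0 = x0, y0 = y0, W = W, H = H)
}

#' Render an orthographic thickness map
#'
#' Rasterizes the ROI along the view axis. Each pixel takes the
#' barycentric-interpolated thickness of the front-most intersected
#' triangle (depth test). Modes: `continuous` (thickness in mm),
#' `categorized` (binned at `breaks`), `boolean` (thickness >= cutoff as
#' 1/0). Missing-data vertices render as zero thickness.
#'
#' @param field a \linkS4class{ThicknessField}
#' @param mesh the T0 ROI submesh the field was sampled on
#' @param spec a \linkS4class{ProjectionSpec}; default derived from `mesh`
#' @param mode "continuous", "categorized" or "boolean"
#' @param cutoff boolean-mode cutoff, mm (defaults to the field's
#'   detection limit)
#' @param breaks categorized-mode thresholds, mm
#' @return a \linkS4class{RenderedMap}
#' @export
renderThicknessMap <- function(field, mesh,
                               spec = projectionSpec(mesh = mesh),
                               mode = c("continuous", "categorized",
                                        "boolean"),
                               cutoff = NULL,
                               breaks = c(0.01, 0.05, 0.10, 0.20)) {
  mode <- match.arg(mode)
  stopifnot(length(field@d) == nVertices(mesh))
  d <- field@d
  d[is.na(d)] <- 0
  ras <- rasterizeMesh(mesh, d, spec)
  if (sum(ras$covered) < 10L)
    stop("ROI projects to fewer than 10 pixels; decrease pixel_size")
  thick <- ras$value[, , 1]
  thick[!ras$covered] <- NA_real_
  if (is.null(cutoff)) cutoff <- field@detection_limit
  legend <- data.frame(threshold = numeric(0), color = character(0))
  if (mode == "boolean") {
    raster <- ifelse(ras$covered, as.numeric(thick >= cutoff), NA_real_)
    legend <- data.frame(threshold = c(0, cutoff),
                         color = c("#000000", "#FFFFFF"))
  } else if (mode == "categorized") {
    cats <- findInterval(thick, breaks) # 0 .. length(breaks)
    raster <- matrix(c(0, breaks)[cats + 1L], nrow(thick), ncol(thick))
    cols <- hcl.colors(length(breaks) + 1L, "Inferno", rev = TRUE)
    legend <- data.frame(threshold = c(0, breaks), color = cols)
  } else {
    raster <- thick
    cols <- hcl.colors(7, "Viridis")
    legend <- data.frame(threshold = seq(0, max(0.2, cutoff), length.out = 7),
                         color = cols)
  }
  raster[!ras$covered] <- NA_real_
  new("RenderedMap", raster = raster, roi_pixel_mask = ras$covered,
      spec = spec, mode = mode, legend = legend)
}

#' Planimetric coverage of a Boolean thickness map
#'
#' PLANIvolmap: 100 x (plaque pixels) / (ROI pixels), the planimetric
#' reading of the Boolean 0.01 mm volumetric map.
#'
#' @param map a boolean-mode \linkS4class{RenderedMap}
#' @return percent coverage in [0, 100]
#' @export
planiVolmap <- function(map) {
  if (map@mode != "boolean") stop("planiVolmap needs a boolean-mode map")
  n <- sum(map@roi_pixel_mask)
  if (n == 0L) stop("empty ROI pixel mask")
  100 * sum(map@raster[map@roi_pixel_mask] > 0.5) / n
}

#' Area-weighted 3D coverage for comparison with 2D planimetry
#'
#' Unlike [planiVolmap()], this is computed on the surface itself and is
#' free of projection foreshortening; reporting both quantifies the
#' map-projection distortion inherent to 2D planimetry on curved teeth.
#'
#' @param field a \linkS4class{ThicknessField}
#' @param cutoff mm
#' @return percent coverage in [0, 100]
#' @export
surfaceCoverage <- function(field, cutoff = field@detection_limit) {
  100 * binarizeField(field, cutoff)$covered_fraction
}

#' Write the raw thickness raster as 16-bit grayscale TIFF
#'
#' Thickness in mm is mapped linearly onto the 16-bit range
#' `[0, max_mm]`; pixels outside the ROI are zero. The scale is recorded
#' in a JSON sidecar so values can be recovered exactly.
#'
#' @param map a continuous-mode \linkS4class{RenderedMap}
#' @param path TIFF output path
#' @param max_mm full-scale thickness (default 0.5 mm)
#' @return `path`, invisibly
#' @export
writeThicknessTIFF <- function(map, path, max_mm = 0.5) {
  if (map@mode != "continuous")
    stop("TIFF export needs a continuous-mode map")
  r <- map@raster
  r[!map@roi_pixel_mask | !is.finite(r)] <- 0
  r[] <- pmin(1, pmax(0, r / max_mm))
  H <- nrow(r)
  tiff::writeTIFF(r[H:1, , drop = FALSE], path, bits.per.sample = 16L)
  jsonlite::write_json(list(full_scale_mm = max_mm,
                            pixel_size_mm = map@spec@pixel_size),
                       sub("\\.tiff?$", "_scale.json", path),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Write a rendered map as PNG (with a JSON legend sidecar)
#'
#' @param map a \linkS4class{RenderedMap}
#' @param path PNG output path
#' @param background colour outside the ROI
#' @return `path`, invisibly
#' @export
writeMapPNG <- function(map, path, background = "#D0D0D0") {
  r <- map@raster
  H <- nrow(r); W <- ncol(r)
  img <- array(0, c(H, W, 3))
  bg <- col2rgb(background)[, 1] / 255
  for (k in 1:3) img[, , k] <- bg[k]
  inroi <- map@roi_pixel_mask & is.finite(r)
  if (map@mode == "boolean") {
    for (k in 1:3) {
      ch <- img[, , k]
      ch[inroi] <- ifelse(r[inroi] > 0.5, 1, 0)
      img[, , k] <- ch
    }
  } else {
    rng <- range(r[inroi], finite = TRUE)
    if (diff(rng) <= 0) rng <- rng + c(0, 1e-9)
    pal <- hcl.colors(256, "Viridis")
    idx <- pmin(256L, pmax(1L, 1L + floor(255 * (r - rng[1]) / diff(rng))))
    rgbmat <- col2rgb(pal) / 255
    for (k in 1:3) {
      ch <- img[, , k]
      ch[inroi] <- rgbmat[k, idx[inroi]]
      img[, , k] <- ch
    }
  }
  png::writePNG(img[H:1, , , drop = FALSE], path) # image row 1 at top
  legend_path <- sub("\\.png$", "_legend.json", path)
  jsonlite::write_json(map@legend, legend_path, digits = NA)
  invisible(path)
}
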