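## Central S4 containers. All linear dimensions are millimetres; areas mm^2,
## volumes mm^3. Faces are 1-based vertex-index triples (row-wise).

#' Triangulated tooth-surface mesh
#'
#' A triangle mesh in millimetre units, as exported by intraoral scanners.
#' Faces index into the vertex matrix (1-based). An optional per-vertex RGB
#' matrix (values in [0, 1]) carries scanner colour.
#'
#' @slot vertices numeric matrix, n x 3 (mm).
#' @slot faces integer matrix, m x 3, 1-based vertex indices.
#' @slot colors numeric matrix, n x 3 in [0, 1], or a 0 x 3 matrix if absent.
#' @export
setClass("SurfaceMesh", representation(
  vertices = "matrix",
  faces = "matrix",
  colors = "matrix"
))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; f <- object@faces
  if (ncol(v) != 3L) return("vertices must be an n x 3 matrix")
  if (!all(is.finite(v))) return("vertex coordinates must be finite")
  if (nrow(f) > 0L) {
    if (ncol(f) != 3L) return("faces must be an m x 3 matrix")
    if (min(f) < 1L || max(f) > nrow(v))
      return("face indices out of range")
  }
  if (nrow(object@colors) > 0L &&
      (nrow(object@colors) != nrow(v) || ncol(object@colors) != 3L))
    return("colors must be n x 3 (or empty)")
  TRUE
})

#' Region of interest on a mesh
#'
#' A delineated buccal tooth surface: a subset of vertex indices of one
#' timepoint's mesh, labelled with an FDI tooth number.
#'
#' @slot tooth_id character, FDI two-digit tooth label (e.g. "11", "24").
#' @slot vertex_ids integer vector of unique, valid vertex indices.
#' @slot timepoint character, "T0" or "T4".
#' @export
setClass("ROIMask", representation(
  tooth_id = "character",
  vertex_ids = "integer",
  timepoint = "character"
))

setValidity("ROIMask", function(object) {
  if (length(object@vertex_ids) == 0L) return("ROI is empty")
  if (anyDuplicated(object@vertex_ids)) return("ROI vertex ids must be unique")
  if (any(object@vertex_ids < 1L)) return("ROI vertex ids must be >= 1")
  if (!object@timepoint %in% c("T0", "T4"))
    return("timepoint must be 'T0' or 'T4'")
  TRUE
})

#' Paired scans of one subject
#'
#' Holds the clean baseline (T0) and plaque-bearing follow-up (T4) meshes of
#' one subject, plus per-tooth ROI pairs.
#'
#' @slot subject_id character.
#' @slot mesh_t0,mesh_t4 \linkS4class{SurfaceMesh}.
#' @slot rois named list; each element is \code{list(t0 = ROIMask, t4 =
#'   ROIMask)}, named by tooth id.
#' @export
setClass("ScanPair", representation(
  subject_id = "character",
  mesh_t0 = "SurfaceMesh",
  mesh_t4 = "SurfaceMesh",
  rois = "list"
))

setValidity("ScanPair", function(object) {
  ids <- names(object@rois)
  if (anyDuplicated(ids)) return("duplicate tooth_id in rois")
  for (r in object@rois) {
    if (!is(r$t0, "ROIMask") || !is(r$t4, "ROIMask"))
      return("each roi entry needs ROIMask elements 't0' and 't4'")
    if (r$t0@timepoint != "T0" || r$t4@timepoint != "T4")
      return("roi timepoints must be T0/T4 respectively")
    if (max(r$t0@vertex_ids) > nrow(object@mesh_t0@vertices) ||
        max(r$t4@vertex_ids) > nrow(object@mesh_t4@vertices))
      return("roi vertex ids exceed mesh size")
  }
  TRUE
})

#' Rigid-body transform
#'
#' Proper rigid motion x -> R x + t in mm.
#'
#' @slot rotation 3 x 3 orthonormal matrix, det = +1.
#' @slot translation numeric length-3 (mm).
#' @export
setClass("RigidTransform", representation(
  rotation = "matrix",
  translation = "numeric"
))

setValidity("RigidTransform", function(object) {
  R <- object@rotation
  if (!all(dim(R) == c(3L, 3L))) return("rotation must be 3 x 3")
  if (max(abs(crossprod(R) - diag(3))) > 1e-9)
    return("rotation not orthonormal within 1e-9")
  if (abs(det(R) - 1) > 1e-9) return("det(rotation) must be +1 within 1e-9")
  if (length(object@translation) != 3L) return("translation must be length 3")
  TRUE
})

#' Alignment quality report
#'
#' Result of a best-fit superimposition: the refined transform plus residual
#' statistics on the trimmed (inlier) correspondence set.
#'
#' @slot transform \linkS4class{RigidTransform} mapping T4 into the T0 frame.
#' @slot mean_abs_distance numeric, mm, on inliers.
#' @slot sd_distance numeric, mm.
#' @slot inlier_fraction numeric in (0, 1].
#' @slot iterations integer.
#' @slot converged logical.
#' @export
setClass("AlignmentReport", representation(
  transform = "RigidTransform",
  mean_abs_distance = "numeric",
  sd_distance = "numeric",
  inlier_fraction = "numeric",
  iterations = "integer",
  converged = "logical"
))

setValidity("AlignmentReport", function(object) {
  if (object@mean_abs_distance < 0) return("mean_abs_distance must be >= 0")
  if (object@inlier_fraction <= 0 || object@inlier_fraction > 1)
    return("inlier_fraction must be in (0, 1]")
  TRUE
})

#' Signed plaque-thickness field on an ROI
#'
#' Per-vertex signed point-to-plane distance from the clean T0 ROI surface
#' to the superimposed T4 surface (positive outward = deposit), with
#' per-vertex area weights (one third of incident-triangle area).
#'
#' @slot roi \linkS4class{ROIMask} (T0 reference).
#' @slot d numeric, signed distance per ROI vertex (mm); NA = missing data.
#' @slot a numeric, area weight per ROI vertex (mm^2), all > 0.
#' @slot detection_limit numeric, mm (default 0.01).
#' @export
setClass("ThicknessField", representation(
  roi = "ROIMask",
  d = "numeric",
  a = "numeric",
  detection_limit = "numeric"
))

setValidity("ThicknessField", function(object) {
  n <- length(object@roi@vertex_ids)
  if (length(object@d) != n || length(object@a) != n)
    return("d and a must match ROI vertex count")
  if (any(object@a <= 0)) return("area weights must be > 0")
  if (object@detection_limit <= 0) return("detection_limit must be > 0")
  TRUE
})

#' Volumetric plaque indices for one surface
#'
#' @slot vpi numeric, mm^3 (>= 0).
#' @slot avpi numeric, mm^3/mm^2; exactly vpi / roi_area.
#' @slot roi_area numeric, mm^2.
#' @slot covered_fraction numeric in [0, 1] (area fraction at or above the
#'   detection limit).
#' @slot detection_limit numeric, mm.
#' @export
setClass("VolumetricIndices", representation(
  vpi = "numeric",
  avpi = "numeric",
  roi_area = "numeric",
  covered_fraction = "numeric",
  detection_limit = "numeric"
))

setValidity("VolumetricIndices", function(object) {
  if (object@vpi < 0) return("vpi must be >= 0")
  if (abs(object@avpi - object@vpi / object@roi_area) >
      1e-12 * max(1, abs(object@avpi)))
    return("avpi must equal vpi / roi_area")
  if (object@covered_fraction < 0 || object@covered_fraction > 1)
    return("covered_fraction must be in [0, 1]")
  TRUE
})

#' Orthographic projection specification
#'
#' Deterministic canonical projection used for all rendered maps: view along
#' the (area-weighted) mean outward ROI normal, raster axes from an up
#' vector, square pixels.
#'
#' @slot view_direction unit 3-vector (towards the viewer).
#' @slot up_vector unit 3-vector, not parallel to the view direction.
#' @slot pixel_size numeric, mm per pixel (default 0.02).
#' @export
setClass("ProjectionSpec", representation(
  view_direction = "numeric",
  up_vector = "numeric",
  pixel_size = "numeric"
))

setValidity("ProjectionSpec", function(object) {
  v <- object@view_direction; u <- object@up_vector
  if (length(v) != 3L || length(u) != 3L) return("vectors must be length 3")
  if (abs(sqrt(sum(v^2)) - 1) > 1e-6 || abs(sqrt(sum(u^2)) - 1) > 1e-6)
    return("view and up vectors must be unit length")
  if (sum(abs(crossprod3(v, u))) < 1e-9)
    return("view and up vectors must not be parallel")
  if (object@pixel_size <= 0) return("pixel_size must be > 0")
  TRUE
})

#' Rendered orthographic map
#'
#' Raster of a thickness field seen along the projection axis. `raster`
#' holds thickness (mm) for continuous/categorized modes or 0/1 for boolean
#' mode; `roi_pixel_mask` marks pixels covered by the ROI.
#'
#' @slot raster numeric matrix (rows = y, cols = x).
#' @slot roi_pixel_mask logical matrix, same shape.
#' @slot spec \linkS4class{ProjectionSpec}.
#' @slot mode character: "continuous", "categorized" or "boolean".
#' @slot legend data.frame with columns threshold (mm) and color.
#' @export
setClass("RenderedMap", representation(
  raster = "matrix",
  roi_pixel_mask = "matrix",
  spec = "ProjectionSpec",
  mode = "character",
  legend = "data.frame"
))

setValidity("RenderedMap", function(object) {
  if (!all(dim(object@raster) == dim(object@roi_pixel_mask)))
    return("raster and roi_pixel_mask must have the same shape")
  if (!object@mode %in% c("continuous", "categorized", "boolean"))
    return("unknown mode")
  if (any(object@roi_pixel_mask & !is.finite(object@raster)))
    return("raster must be finite inside the ROI mask")
  TRUE
})

#' Disclosed-plaque RGB image with ROI mask
#'
#' @slot rgb numeric array H x W x 3 in [0, 1].
#' @slot roi_pixel_mask logical matrix H x W, non-empty.
#' @slot tooth_id character.
#' @export
setClass("DisclosedImage", representation(
  rgb = "array",
  roi_pixel_mask = "matrix",
  tooth_id = "character"
))

setValidity("DisclosedImage", function(object) {
  d <- dim(object@rgb)
  if (length(d) != 3L || d[3] != 3L) return("rgb must be H x W x 3")
  if (!all(dim(object@roi_pixel_mask) == d[1:2]))
    return("mask shape must match raster")
  if (!any(object@roi_pixel_mask)) return("ROI pixel mask is empty")
  TRUE
})

#' Trainable pixel classifier for two-tone disclosed plaque
#'
#' Random-forest pixel classifier over a fixed multiscale feature bank
#' (RGB, green channel, Gaussian blurs, gradient magnitude,
#' difference-of-Gaussians, local median and variance), distinguishing
#' non-plaque, light/pink plaque and dark/purple plaque.
#'
#' @slot model the fitted randomForest object.
#' @slot classes character, the three class labels.
#' @slot feature_names character, feature-bank column names.
#' @slot n_train named integer, training pixels per class.
#' @slot seed integer used for training.
#' @export
setClass("PixelClassifier", representation(
  model = "ANY",
  classes = "character",
  feature_names = "character",
  n_train = "integer",
  seed = "integer"
))

PLAQUE_CLASSES <- c("non_plaque", "light_pink", "dark_purple")

#' Planimetric plaque indices for one surface
#'
#' Coverage percentages of the ROI by disclosed plaque. By construction
#' `plani_light = plani_tot - plani_dark` exactly. The relative values are
#' NA (undefined, never zero) when `plani_tot` is 0, to avoid silent bias
#' in downstream correlations.
#'
#' @slot plani_tot,plani_dark,plani_light percent of ROI pixels.
#' @slot rel_dark,rel_light percent of total plaque (NA when undefined).
#' @export
setClass("PlanimetricIndices", representation(
  plani_tot = "numeric",
  plani_dark = "numeric",
  plani_light = "numeric",
  rel_dark = "numeric",
  rel_light = "numeric"
))

setValidity("PlanimetricIndices", function(object) {
  if (object@plani_light != object@plani_tot - object@plani_dark)
    return("plani_light must equal plani_tot - plani_dark exactly")
  if (object@plani_dark < 0 || object@plani_dark > object@plani_tot ||
      object@plani_tot > 100)
    return("need 0 <= plani_dark <= plani_tot <= 100")
  if (!is.na(object@rel_dark) && !is.na(object@rel_light) &&
      abs(object@rel_dark + object@rel_light - 100) > 1e-9)
    return("rel_dark + rel_light must be 100 when defined")
  TRUE
})
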