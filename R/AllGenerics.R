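#' @name plaquemetry-accessors
#' @title Accessors for plaquemetry classes
#' @description Slot accessors; user code should use these rather than `@`.
#' @param object,x an object of the documented class
#' @return the requested component
NULL

#' @rdname plaquemetry-accessors
#' @export
setGeneric("vertices", function(x) standardGeneric("vertices"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("faces", function(x) standardGeneric("faces"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("nFaces", function(x) standardGeneric("nFaces"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("surfaceArea", function(x) standardGeneric("surfaceArea"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("toothId", function(x) standardGeneric("toothId"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("vertexIds", function(x) standardGeneric("vertexIds"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("timepoint", function(x) standardGeneric("timepoint"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("thickness", function(x) standardGeneric("thickness"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("areaWeights", function(x) standardGeneric("areaWeights"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("detectionLimit", function(x) standardGeneric("detectionLimit"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("vpi", function(x) standardGeneric("vpi"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("avpi", function(x) standardGeneric("avpi"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("coveredFraction", function(x) standardGeneric("coveredFraction"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("rotation", function(x) standardGeneric("rotation"))
#' @rdname plaquemetry-accessors
#' @export
setGeneric("translation", function(x) standardGeneric("translation"))

#' Apply a rigid transform
#'
#' Applies a \linkS4class{RigidTransform} (x -> R x + t) to points or to the
#' vertices of a mesh.
#'
#' @param transform a \linkS4class{RigidTransform}
#' @param x a \linkS4class{SurfaceMesh} or an n x 3 coordinate matrix
#' @return an object of the same type as `x`, transformed
#' @export
setGeneric("applyTransform", function(transform, x)
  standardGeneric("applyTransform"))

setMethod("vertices", "SurfaceMesh", function(x) x@vertices)
setMethod("faces", "SurfaceMesh", function(x) x@faces)
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))
setMethod("surfaceArea", "SurfaceMesh", function(x) sum(faceAreas(x)))
setMethod("toothId", "ROIMask", function(x) x@tooth_id)
setMethod("vertexIds", "ROIMask", function(x) x@vertex_ids)
setMethod("timepoint", "ROIMask", function(x) x@timepoint)
setMethod("thickness", "ThicknessField", function(x) x@d)
setMethod("areaWeights", "ThicknessField", function(x) x@a)
setMethod("detectionLimit", "ThicknessField", function(x) x@detection_limit)
setMethod("surfaceArea", "ThicknessField", function(x) sum(x@a))
setMethod("vpi", "VolumetricIndices", function(x) x@vpi)
setMethod("avpi", "VolumetricIndices", function(x) x@avpi)
setMethod("coveredFraction", "VolumetricIndices", function(x) x@covered_fraction)
setMethod("rotation", "RigidTransform", function(x) x@rotation)
setMethod("translation", "RigidTransform", function(x) x@translation)

setMethod("show", "SurfaceMesh", function(object) {
  cat("SurfaceMesh:", nVertices(object), "vertices,", nFaces(object),
      "faces", if (nrow(object@colors)) "(with colour)" else "", "\n")
  cat("  area:", format(surfaceArea(object), digits = 6), "mm^2\n")
})

setMethod("show", "ROIMask", function(object) {
  cat("ROIMask: tooth", object@tooth_id, "@", object@timepoint, "-",
      length(object@vertex_ids), "vertices\n")
})

setMethod("show", "ScanPair", function(object) {
  cat("ScanPair: subject", object@subject_id, "-", length(object@rois),
      "ROI pair(s):", paste(names(object@rois), collapse = ", "), "\n")
})

setMethod("show", "RigidTransform", function(object) {
  ang <- rotationAngle(object) * 180 / pi
  cat(sprintf("RigidTransform: rotation %.4g deg, translation (%.4g, %.4g, %.4g) mm\n",
              ang, object@translation[1], object@translation[2],
              object@translation[3]))
})

setMethod("show", "AlignmentReport", function(object) {
  cat(sprintf(
    "AlignmentReport: mean |d| = %.5f mm (SD %.5f), inliers %.0f%%, %d iteration(s)%s\n",
    object@mean_abs_distance, object@sd_distance,
    100 * object@inlier_fraction, object@iterations,
    if (object@converged) "" else " [NOT CONVERGED]"))
})

setMethod("show", "ThicknessField", function(object) {
  d <- object@d
  cat(sprintf(
    "ThicknessField: tooth %s, %d vertices, area %.3f mm^2, %d missing\n",
    object@roi@tooth_id, length(d), sum(object@a), sum(is.na(d))))
  if (any(!is.na(d)))
    cat(sprintf("  d range [%.4f, %.4f] mm, detection limit %.3g mm\n",
                min(d, na.rm = TRUE), max(d, na.rm = TRUE),
                object@detection_limit))
})

setMethod("show", "VolumetricIndices", function(object) {
  cat(sprintf(
    "VolumetricIndices: VPI %.4f mm^3, AVPI %.5f mm^3/mm^2, area %.3f mm^2, covered %.1f%%\n",
    object@vpi, object@avpi, object@roi_area, 100 * object@covered_fraction))
})

setMethod("show", "RenderedMap", function(object) {
  cat(sprintf("RenderedMap (%s): %d x %d px, %.3g mm/px, %d ROI pixels\n",
              object@mode, ncol(object@raster), nrow(object@raster),
              object@spec@pixel_size, sum(object@roi_pixel_mask)))
})

setMethod("show", "DisclosedImage", function(object) {
  d <- dim(object@rgb)
  cat(sprintf("DisclosedImage: tooth %s, %d x %d px, %d ROI pixels\n",
              object@tooth_id, d[2], d[1], sum(object@roi_pixel_mask)))
})

setMethod("show", "PixelClassifier", function(object) {
  cat("PixelClassifier: classes", paste(object@classes, collapse = "/"),
      "\n  features:", length(object@feature_names),
      "| training pixels:", paste(object@n_train, collapse = "/"),
      "| seed:", object@seed, "\n")
})
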