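## Signed plaque-thickness field on a superimposed ROI pair, and the
## volumetric plaque indices derived from it. The field is sampled on the
## clean T0 vertices so the area normalizer is plaque-independent.

#' Signed plaque-thickness field
#'
#' For every T0 ROI vertex, the signed distance to the nearest point of the
#' (already superimposed) T4 surface. Sign comes from the outward T0 vertex
#' normal: positive means the T4 surface lies outside T0, i.e. de-novo
#' deposit. Vertices whose nearest T4 point is farther than `missing_cap`
#' are marked missing (NA); more than `missing_tol` missing vertices abort
#' with an error (insufficient scan coverage).
#'
#' @param roi_t0 clean reference ROI submesh (\linkS4class{SurfaceMesh})
#' @param aligned_t4 T4 ROI submesh already transformed into the T0 frame
#' @param roi the \linkS4class{ROIMask} the submesh was cut from (metadata
#'   carried into the field); a synthetic whole-submesh mask when NULL
#' @param detection_limit mm, default 0.01
#' @param missing_cap mm, default 1.0
#' @param missing_tol fraction, default 0.2
#' @return a \linkS4class{ThicknessField}
#' @export
signedDistanceField <- function(roi_t0, aligned_t4, roi = NULL,
                                detection_limit = 0.01, missing_cap = 1.0,
                                missing_tol = 0.2) {
  if (is.null(roi))
    roi <- ROIMask("NA", seq_len(nVertices(roi_t0)), "T0")
  hit <- closestOnMesh(roi_t0@vertices, aligned_t4)
  nrm <- vertexNormals(roi_t0)
  sgn <- sign(rowSums(nrm * (hit$point - roi_t0@vertices)))
  sgn[sgn == 0] <- 1
  d <- sgn * hit$dist
  d[hit$dist > missing_cap] <- NA_real_
  if (mean(is.na(d)) > missing_tol)
    stop(sprintf("%.0f%% of ROI vertices lack T4 coverage within %.2g mm",
                 100 * mean(is.na(d)), missing_cap))
  new("ThicknessField", roi = roi, d = d,
      a = vertexAreaWeights(roi_t0), detection_limit = detection_limit)
}

#' Volumetric plaque indices (VPI / AVPI)
#'
#' VPI integrates positive thickness at or above the detection limit over
#' the ROI: VPI = sum(a_v * d_v) over vertices with d_v >= limit. Negative
#' deviations and sub-limit thickness contribute zero (the index quantifies
#' deposit; set `signed_volume = TRUE` to subtract negative deviations for
#' sensitivity analysis). AVPI = VPI / ROI area. Missing-data vertices are
#' excluded from all sums.
#'
#' @param field a \linkS4class{ThicknessField}
#' @param signed_volume subtract negative deviations instead of clamping
#' @return a \linkS4class{VolumetricIndices}
#' @export
computeVPI <- function(field, signed_volume = FALSE) {
  ok <- !is.na(field@d)
  if (!any(ok)) stop("empty thickness field")
  d <- field@d[ok]; a <- field@a[ok]
  lim <- field@detection_limit
  pos <- d >= lim
  vpi <- sum(a[pos] * d[pos])
  if (signed_volume) vpi <- vpi + sum(a[d < 0] * d[d < 0])
  area <- sum(a)
  new("VolumetricIndices", vpi = max(0, vpi), avpi = max(0, vpi) / area,
      roi_area = area, covered_fraction = sum(a[pos]) / area,
      detection_limit = lim)
}

#' Binarize a thickness field at a cutoff
#'
#' Per-vertex plaque-present flag (d >= cutoff) plus the area-weighted
#' covered fraction, the per-vertex analogue of the Boolean 0.01 mm map.
#'
#' @param field a \linkS4class{ThicknessField}
#' @param cutoff mm, default 0.01
#' @return list with `present` (logical per vertex, NA where missing) and
#'   `covered_fraction`
#' @export
binarizeField <- function(field, cutoff = 0.01) {
  stopifnot(cutoff > 0)
  ok <- !is.na(field@d)
  present <- field@d >= cutoff
  frac <- sum(field@a[ok][present[ok]]) / sum(field@a[ok])
  list(present = present, covered_fraction = frac)
}
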