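## End-to-end orchestration: simulate a study directory, measure every
## surface (fail-soft per surface, fail-hard per study), and compute the
## cohort statistics from the per-surface results table alone.

#' Run configuration
#'
#' Central knob set for a study run. All randomness (classifier training,
#' bootstraps) derives from the single `seed`.
#'
#' @param detection_limit mm (default 0.01)
#' @param trim_fraction ICP trim fraction kept (default 0.6)
#' @param pixel_size map/image rendering resolution, mm/px
#' @param seed master RNG seed
#' @param alpha significance level
#' @param roc_cuts coverage dichotomization points, percent
#' @param n_train_images disclosed images used for classifier training
#' @param min_component speckle filter for segmentation, px
#' @param write_artifacts write per-surface PLY/PNG/JSON artifacts
#' @return list of class "runConfig"
#' @export
runConfig <- function(detection_limit = 0.01, trim_fraction = 0.6,
                      pixel_size = 0.05, seed = 1L, alpha = 0.05,
                      roc_cuts = c(10, 25, 50), n_train_images = 2L,
                      min_component = 5L, write_artifacts = FALSE) {
  cfg <- as.list(environment())
  stopifnot(cfg$detection_limit > 0, cfg$trim_fraction > 0,
            cfg$trim_fraction <= 1, cfg$pixel_size > 0)
  class(cfg) <- "runConfig"
  cfg
}

#' Read a run configuration from YAML
#' @param path YAML file with any subset of the [runConfig()] fields
#' @return list of class "runConfig"
#' @export
readRunConfig <- function(path) {
  vals <- yaml::read_yaml(path)
  do.call(runConfig, vals[names(vals) %in% names(formals(runConfig))])
}

#' Simulate a study directory on disk
#'
#' Writes the same formats the measurement pipeline reads: per-surface T0
#' and T4 meshes (PLY), ROI JSON, two-tone disclosed images and label
#' overlays (PNG), TMQHPlI site scores (CSV) and a ground-truth table.
#'
#' @param dir output directory (created)
#' @param n_subjects,teeth_per_subject cohort size
#' @param spec base [syntheticSpec()]
#' @param seed master seed
#' @return the manifest data.frame, invisibly
#' @export
simulateStudy <- function(dir, n_subjects = 4L, teeth_per_subject = 4L,
                          spec = syntheticSpec(edge_length = 0.2),
                          seed = 1L) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (d in c("meshes", "rois", "images", "labels"))
    dir.create(file.path(dir, d), showWarnings = FALSE)
  cohort <- generateCohort(n_subjects, teeth_per_subject, spec, seed,
                           with_images = TRUE)
  manifest <- NULL
  for (surf in cohort$surfaces) {
    id <- paste0(surf$subject_id, "_", surf$tooth_id)
    writeMesh(surf$crown$mesh, file.path(dir, "meshes",
                                         paste0(id, "_t0.ply")))
    writeMesh(surf$scan$mesh, file.path(dir, "meshes",
                                        paste0(id, "_t4.ply")))
    nV <- nVertices(surf$crown$mesh)
    roi <- list(
      list(tooth_id = surf$tooth_id, timepoint = "T0",
           vertex_ids = seq_len(nV)),
      list(tooth_id = surf$tooth_id, timepoint = "T4",
           vertex_ids = seq_len(nVertices(surf$scan$mesh))))
    jsonlite::write_json(roi, file.path(dir, "rois", paste0(id, ".json")),
                         auto_unbox = TRUE, digits = NA)
    png::writePNG(surf$image$image@rgb,
                  file.path(dir, "images", paste0(id, ".png")))
    png::writePNG(surf$image$image@roi_pixel_mask * 1,
                  file.path(dir, "images", paste0(id, "_mask.png")))
    png::writePNG(surf$image$truth_classes / 3,
                  file.path(dir, "labels", paste0(id, ".png")))
    manifest <- rbind(manifest, data.frame(
      subject_id = surf$subject_id, tooth_id = surf$tooth_id, id = id,
      stringsAsFactors = FALSE))
  }
  write.csv(cohort$site_scores, file.path(dir, "scores.csv"),
            row.names = FALSE)
  write.csv(cohort$records, file.path(dir, "ground_truth.csv"),
            row.names = FALSE)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}

#' Measure one tooth surface
#'
#' The per-surface volumetric chain: coarse pre-alignment, trimmed
#' point-to-plane best fit of the ROI pair, signed thickness field, VPI /
#' AVPI, Boolean 0.01 mm map and its planimetric coverage (PLANIvolmap).
#'
#' @param pair a \linkS4class{ScanPair}
#' @param tooth_id which ROI pair to process
#' @param cfg a [runConfig()]
#' @param out_dir artifact directory (used when `cfg$write_artifacts`)
#' @return one-row data.frame: subject_id, tooth_id, vpi, avpi, roi_area,
#'   covered_fraction, plani_volmap, alignment diagnostics
#' @export
runSurface <- function(pair, tooth_id, cfg = runConfig(), out_dir = NULL) {
  if (!tooth_id %in% names(pair@rois))
    stop("no ROI pair for tooth ", tooth_id)
  rp <- pair@rois[[tooth_id]]
  pre <- preAlign(pair@mesh_t4, pair@mesh_t0)
  sub0 <- roiSubmesh(pair@mesh_t0, rp$t0)$mesh
  sub4 <- roiSubmesh(pair@mesh_t4, rp$t4)$mesh
  rep <- bestFitROI(sub4, sub0, init = pre,
                    trim_fraction = cfg$trim_fraction)
  aligned4 <- applyTransform(rep@transform, sub4)
  field <- signedDistanceField(sub0, aligned4, roi = rp$t0,
                               detection_limit = cfg$detection_limit)
  vol <- computeVPI(field)
  pspec <- projectionSpec(mesh = sub0, pixel_size = cfg$pixel_size)
  bmap <- renderThicknessMap(field, sub0, pspec, mode = "boolean")
  pvm <- planiVolmap(bmap)
  if (!is.null(out_dir) && isTRUE(cfg$write_artifacts)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    id <- paste0(pair@subject_id, "_", tooth_id)
    d <- field@d; d[is.na(d)] <- 0
    writeMesh(sub0, file.path(out_dir, paste0(id, "_field.ply")),
              scalar = d)
    writeMapPNG(bmap, file.path(out_dir, paste0(id, "_boolmap.png")))
    writeTransformJSON(rep@transform,
                       file.path(out_dir, paste0(id, "_transform.json")))
  }
  data.frame(subject_id = pair@subject_id, tooth_id = tooth_id,
             vpi = vol@vpi, avpi = vol@avpi, roi_area = vol@roi_area,
             covered_fraction = vol@covered_fraction,
             plani_volmap = pvm,
             align_mean_abs = rep@mean_abs_distance,
             align_converged = rep@converged,
             stringsAsFactors = FALSE)
}

## disclosed-image planimetry for every surface of a study directory
studyPlanimetry <- function(dir, manifest, cfg) {
  imgs <- lapply(manifest$id, function(id)
    readDisclosedImage(file.path(dir, "images", paste0(id, ".png")),
                       file.path(dir, "images", paste0(id, "_mask.png")),
                       tooth_id = sub(".*_", "", id)))
  labs <- lapply(manifest$id, function(id) {
    m <- png::readPNG(file.path(dir, "labels", paste0(id, ".png")))
    if (length(dim(m)) == 3L) m <- m[, , 1]
    matrix(as.integer(round(m * 3)), nrow(m), ncol(m))
  })
  ntr <- min(cfg$n_train_images, length(imgs))
  clf <- trainPixelClassifier(imgs[seq_len(ntr)], labs[seq_len(ntr)],
                              seed = cfg$seed)
  out <- NULL
  for (i in seq_along(imgs)) {
    seg <- segmentDisclosed(imgs[[i]], clf, cfg$min_component)
    pin <- planimetricIndices(seg, imgs[[i]]@roi_pixel_mask)
    out <- rbind(out, data.frame(
      id = manifest$id[i], plani_tot = pin@plani_tot,
      plani_dark = pin@plani_dark, plani_light = pin@plani_light,
      rel_dark = pin@rel_dark, rel_light = pin@rel_light,
      stringsAsFactors = FALSE))
  }
  out
}

#' Cohort statistics from a per-surface results table
#'
#' The full comparison plan over the joined records: Shapiro-Wilk
#' normality per measure, Friedman across the four planimetric measures
#' with pairwise Wilcoxon/Bonferroni post-hocs, the Spearman and
#' Passing-Bablok (on z-scores) matrices over clinical, planimetric and
#' volumetric measures, ROC of VPI against dichotomized coverage, and the
#' two-segment growth-regime model.
#'
#' @param records data.frame with the per-surface measures (columns
#'   `vpi`, `avpi`, `plani_tot`, `plani_dark`, `plani_light`,
#'   `plani_volmap`, and optionally `tmqhpli_tdp_mean`,
#'   `tmqhpli_ddp_mean`)
#' @param cfg a [runConfig()]
#' @return nested list (the stats report)
#' @export
studyStatistics <- function(records, cfg = runConfig()) {
  planiCols <- c("plani_tot", "plani_dark", "plani_light", "plani_volmap")
  measures <- c(planiCols, "vpi", "avpi",
                intersect(c("tmqhpli_tdp_mean", "tmqhpli_ddp_mean"),
                          names(records)))
  rep <- list()
  rep$n_surfaces <- nrow(records)
  rep$descriptives <- lapply(setNames(measures, measures), function(m) {
    x <- records[[m]]
    list(mean = mean(x, na.rm = TRUE), sd = sd(x, na.rm = TRUE),
         min = min(x, na.rm = TRUE), max = max(x, na.rm = TRUE))
  })
  rep$shapiro <- lapply(setNames(measures, measures), function(m) {
    x <- records[[m]][!is.na(records[[m]])]
    if (length(x) < 3L || sd(x) == 0) return(list(W = NA, p = NA))
    shapiroWilk(x)
  })
  cc <- complete.cases(records[, planiCols])
  pm <- as.matrix(records[cc, planiCols])
  rep$friedman <- friedmanTest(pm, p.method = "chisq")
  rep$wilcoxon_pairwise <- wilcoxonPairwiseBonferroni(pm)
  pairs <- t(combn(measures, 2))
  rep$spearman <- lapply(seq_len(nrow(pairs)), function(i) {
    s <- tryCatch(
      spearmanRho(records[[pairs[i, 1]]], records[[pairs[i, 2]]]),
      error = function(e) list(error = conditionMessage(e)))
    c(list(a = pairs[i, 1], b = pairs[i, 2]), s)
  })
  rep$passing_bablok <- lapply(seq_len(nrow(pairs)), function(i) {
    x <- records[[pairs[i, 1]]]; y <- records[[pairs[i, 2]]]
    pb <- tryCatch(passingBablok(x, y, use_zscores = TRUE,
                                 alpha = cfg$alpha),
                   error = function(e) list(error = conditionMessage(e)))
    c(list(a = pairs[i, 1], b = pairs[i, 2]), pb)
  })
  rep$roc <- lapply(
    withCallingHandlers(
      rocDichotomized(records$vpi, records$plani_tot, cfg$roc_cuts),
      warning = function(w) invokeRestart("muffleWarning")),
    function(r) r[c("cut", "auc", "n_pos", "n_neg")])
  rep$breakpoint <- tryCatch(
    contributionBreakpoint(records),
    error = function(e) list(error = conditionMessage(e)))
  rep
}

#' Run a full study from a directory
#'
#' Measures every manifest surface (fail-soft: an erroring surface is
#' recorded as failed and the run continues), merges disclosed-image
#' planimetry and TMQHPlI scores, writes the per-surface results CSV, and
#' computes the cohort statistics from that CSV alone. Deterministic for
#' fixed inputs and seed. Errors only if every surface fails.
#'
#' @param dir study directory (see [simulateStudy()] for the layout)
#' @param cfg a [runConfig()]
#' @param out_dir results directory (default `dir`/results)
#' @return list with `records`, `manifest`, `stats`, and output paths
#' @export
runStudy <- function(dir, cfg = runConfig(), out_dir = file.path(dir,
                                                                 "results")) {
  manifest <- read.csv(file.path(dir, "manifest.csv"),
                       stringsAsFactors = FALSE,
                       colClasses = c(tooth_id = "character"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  status <- character(nrow(manifest))
  rows <- vector("list", nrow(manifest))
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$id[i]
    res <- tryCatch({
      m0 <- readMesh(file.path(dir, "meshes", paste0(id, "_t0.ply")))
      m4 <- readMesh(file.path(dir, "meshes", paste0(id, "_t4.ply")))
      rois <- readROI(file.path(dir, "rois", paste0(id, ".json")),
                      mesh = m0)
      tp <- vapply(rois, timepoint, "")
      pair <- ScanPair(manifest$subject_id[i], m0, m4,
                       list(list(t0 = rois[[which(tp == "T0")]],
                                 t4 = rois[[which(tp == "T4")]])))
      runSurface(pair, manifest$tooth_id[i], cfg, out_dir = out_dir)
    }, error = function(e) e)
    if (inherits(res, "error")) {
      status[i] <- paste0("failed: ", conditionMessage(res))
    } else {
      status[i] <- "ok"
      rows[[i]] <- res
    }
  }
  if (!any(status == "ok")) stop("all surfaces failed")
  records <- do.call(rbind, rows[status == "ok"])
  # disclosed-image planimetry (when images are present)
  if (dir.exists(file.path(dir, "images"))) {
    pl <- studyPlanimetry(dir, manifest[status == "ok", , drop = FALSE],
                          cfg)
    records <- cbind(records, pl[match(paste0(records$subject_id, "_",
                                              records$tooth_id), pl$id),
                                 -1, drop = FALSE])
  }
  # TMQHPlI means (when scores are present)
  sc_path <- file.path(dir, "scores.csv")
  if (file.exists(sc_path)) {
    recs <- summarizeScores(readScores(sc_path))
    for (v in c("TDP", "DDP")) {
      sub <- recs[recs$variant == v, ]
      m <- match(paste0(records$subject_id, "_", records$tooth_id),
                 paste0(sub$subject_id, "_", sub$tooth_id))
      records[[paste0("tmqhpli_", tolower(v), "_mean")]] <- sub$mean_score[m]
      records[[paste0("tmqhpli_", tolower(v), "_rounded")]] <-
        sub$rounded_score[m]
    }
  }
  manifest$status <- status
  write.csv(records, file.path(out_dir, "surface_records.csv"),
            row.names = FALSE)
  write.csv(manifest, file.path(out_dir, "manifest.csv"), row.names = FALSE)
  stats <- if (length(unique(records$subject_id)) >= 2L) {
    studyStatistics(records, cfg)
  } else {
    message("fewer than 2 subjects; statistics skipped")
    NULL
  }
  if (!is.null(stats)) {
    jsonlite::write_json(stats, file.path(out_dir, "stats.json"),
                         auto_unbox = TRUE, digits = NA, na = "null")
    roc_pts <- do.call(rbind, lapply(names(stats$roc), function(nm) {
      r <- suppressWarnings(rocDichotomized(records$vpi, records$plani_tot,
                                            stats$roc[[nm]]$cut))[[1]]
      cbind(cut = r$cut, r$roc)
    }))
    if (!is.null(roc_pts))
      write.csv(roc_pts, file.path(out_dir, "roc_points.csv"),
                row.names = FALSE)
  }
  list(records = records, manifest = manifest, stats = stats,
       out_dir = out_dir)
}
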