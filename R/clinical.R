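## TMQHPlI score handling. One record per (subject, tooth, variant): the
## mean of the three site scores (mesial, central, distal) and its
## half-up rounding to the nearest whole score.

#' Round half away from zero (half-up for non-negative scores)
#' @param x numeric
#' @return integer-valued numeric
#' @export
roundHalfUp <- function(x) floor(x + 0.5)

#' Summarize TMQHPlI site scores per tooth surface
#'
#' Aggregates a validated long site-score table (see [readScores()]) to one
#' row per (subject, tooth, variant): the three site scores, their mean and
#' the mean rounded half-up to the nearest whole score (the grouping value
#' used when stratifying by clinical score). A DDP mean exceeding the TDP
#' mean on the same surface triggers a consistency warning (dark plaque is
#' a subset of total) but does not halt: real scoring noise exists.
#'
#' @param scores long-format data.frame from [readScores()]
#' @return data.frame with columns subject_id, tooth_id, variant, mesial,
#'   central, distal, mean_score, rounded_score
#' @export
summarizeScores <- function(scores) {
  key <- interaction(scores$subject_id, scores$tooth_id, scores$variant,
                     drop = TRUE)
  parts <- split(scores, key)
  out <- do.call(rbind, lapply(parts, function(p) {
    s <- setNames(p$score, p$site)
    m <- unname(sum(s[c("mesial", "central", "distal")]) / 3)
    data.frame(subject_id = p$subject_id[1], tooth_id = p$tooth_id[1],
               variant = p$variant[1],
               mesial = unname(s["mesial"]), central = unname(s["central"]),
               distal = unname(s["distal"]),
               mean_score = m, rounded_score = roundHalfUp(m),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out <- out[order(out$subject_id, out$tooth_id, out$variant), ]
  wide <- merge(out[out$variant == "TDP", c("subject_id", "tooth_id",
                                            "mean_score")],
                out[out$variant == "DDP", c("subject_id", "tooth_id",
                                            "mean_score")],
                by = c("subject_id", "tooth_id"),
                suffixes = c("_tdp", "_ddp"))
  bad <- wide$mean_score_ddp > wide$mean_score_tdp
  if (any(bad))
    warning(sprintf(
      "%d surface(s) have DDP mean > TDP mean (dark plaque should be a subset of total)",
      sum(bad)))
  rownames(out) <- NULL
  out
}
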