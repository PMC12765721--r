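#' Reference cohort descriptive statistics
#'
#' Published descriptive statistics (mean, SD, range) of the clinical,
#' planimetric and volumetric plaque indices measured at day 4 in a
#' 15-subject, 147-surface de-novo plaque accumulation study on maxillary
#' buccal surfaces. Useful as a plausibility anchor for simulated
#' cohorts; a well-known internal consistency of this table is that mean
#' total disclosed-plaque coverage exceeds the Boolean volumetric-map
#' coverage by a factor of about 2.47, because the disclosing dye stains
#' films far below the 0.01 mm volumetric detection limit.
#'
#' @return data.frame with columns measure, mean, sd, min, max
#' @export
referenceCohortTable <- function() {
  read.csv(system.file("extdata", "reference_cohort_table.csv",
                       package = "plaquemetry"),
           stringsAsFactors = FALSE)
}
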