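#' Quantify a set of ROIs end to end
#'
#' Runs detection ([clusterRoi()]), per-vesicle measurement
#' ([measureClusters()]) and volume-normalized counting ([countRois()])
#' over a list of ROIs belonging to one condition.
#'
#' @param rois list of [SmlmRoi-class] objects.
#' @param config an [AssayConfig-class].
#' @return list with `clusterSets` (per-ROI [EvClusterSet-class]),
#'   `measurements` (row-bound per-vesicle metrics), `counts` (per-ROI
#'   EV/uL) and `summary` (one-row cohort statistics).
#' @examples
#' cfg <- simConfig(nEv = 150, fractionPositive = 0, nRoi = 2L,
#'                  backgroundDensity = 0.2, seed = 3)
#' sim <- simulateAssay(cfg, "MmCD81", c("MmCD9", "MmCD63", "MmCD81"))
#' ac <- assayConfig("MmCD81", c("MmCD9", "MmCD63", "MmCD81"),
#'                   volumeRawUl = 1)
#' q <- quantifyRois(sim$rois, ac)
#' q$counts
#' @export
quantifyRois <- function(rois, config) {
  stopifnot(is(config, "AssayConfig"))
  clusterSets <- lapply(rois, clusterRoi, config = config)
  measurements <- do.call(rbind, lapply(seq_along(rois), function(i) {
    measureClusters(clusterSets[[i]], rois[[i]], config)
  }))
  counts <- countRois(clusterSets, config)
  list(clusterSets = clusterSets, measurements = measurements,
       counts = counts, summary = summarizeCohort(counts))
}
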