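#' Simulation configuration for the forward assay simulator
#'
#' Holds the ground-truth parameters of the simulated vesicle population and
#' imaging model. Defaults describe a plasma-like experiment: ~80 nm
#' log-normal vesicles whose tetraspanin copy numbers scale with membrane
#' area, stained antibodies blinking an average of 14 times, and a sparse
#' uniform background of nonspecific localizations.
#'
#' @slot nEv number of vesicles to simulate.
#' @slot fractionPositive fraction of vesicles carrying the HsCD81 tracer.
#' @slot diameterMedianNm median vesicle diameter (nm) of the log-normal law.
#' @slot diameterLogSd log-scale standard deviation of the diameter law.
#' @slot markerMeanPerSpecies named numeric; mean copy number per species for
#'   a reference 80 nm vesicle (scaled by `(diameter/80)^2`).
#' @slot labelProb probability that a marker copy is bound by a labeled
#'   antibody.
#' @slot captureProbPerCopy per-copy probability of capture by the coverslip
#'   antibody.
#' @slot nonspecificRate expected nonspecifically immobilized vesicles per ROI.
#' @slot locsPerAntibodyMean mean localizations emitted per bound antibody.
#' @slot locSigmaNm isotropic localization precision (nm, per axis).
#' @slot backgroundDensity background localizations per square micrometre.
#' @slot roiWidthNm,roiHeightNm ROI dimensions in nm.
#' @slot nRoi number of regions of interest.
#' @slot seed master seed; every stage derives its own stream from it.
#' @seealso [simConfig()]
#' @export
setClass("SimConfig",
  slots = c(
    nEv = "integer",
    fractionPositive = "numeric",
    diameterMedianNm = "numeric",
    diameterLogSd = "numeric",
    markerMeanPerSpecies = "numeric",
    labelProb = "numeric",
    captureProbPerCopy = "numeric",
    nonspecificRate = "numeric",
    locsPerAntibodyMean = "numeric",
    locSigmaNm = "numeric",
    backgroundDensity = "numeric",
    roiWidthNm = "numeric",
    roiHeightNm = "numeric",
    nRoi = "integer",
    seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  isProb <- function(p) length(p) == 1 && is.finite(p) && p >= 0 && p <= 1
  if (length(object@nEv) != 1 || is.na(object@nEv) || object@nEv < 1)
    msg <- c(msg, "nEv must be a positive integer")
  if (!isProb(object@fractionPositive))
    msg <- c(msg, "fractionPositive must lie in [0, 1]")
  if (!isProb(object@labelProb))
    msg <- c(msg, "labelProb must lie in [0, 1]")
  if (!isProb(object@captureProbPerCopy) || object@captureProbPerCopy == 0)
    msg <- c(msg, "captureProbPerCopy must lie in (0, 1]")
  if (object@diameterMedianNm <= 0)
    msg <- c(msg, "diameterMedianNm must be > 0")
  if (object@diameterLogSd < 0)
    msg <- c(msg, "diameterLogSd must be >= 0")
  if (is.null(names(object@markerMeanPerSpecies)) ||
      !all(names(object@markerMeanPerSpecies) %in% evMarkerSpecies()))
    msg <- c(msg, "markerMeanPerSpecies must be named with known species")
  if (any(object@markerMeanPerSpecies < 0))
    msg <- c(msg, "markerMeanPerSpecies must be >= 0")
  if (object@nonspecificRate < 0)
    msg <- c(msg, "nonspecificRate must be >= 0")
  if (object@locsPerAntibodyMean < 1)
    msg <- c(msg, "locsPerAntibodyMean must be >= 1")
  if (object@locSigmaNm < 0)
    msg <- c(msg, "locSigmaNm must be >= 0")
  if (object@backgroundDensity < 0)
    msg <- c(msg, "backgroundDensity must be >= 0")
  if (object@roiWidthNm <= 0 || object@roiHeightNm <= 0)
    msg <- c(msg, "ROI dimensions must be > 0")
  if (object@nRoi < 1)
    msg <- c(msg, "nRoi must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a simulation configuration
#'
#' @param nEv number of vesicles to simulate.
#' @param fractionPositive fraction of vesicles carrying the HsCD81 tracer.
#' @param diameterMedianNm median vesicle diameter in nm (default 80, the
#'   diameter reported for CD81-positive vesicles immunopurified from raw
#'   biofluids).
#' @param diameterLogSd log-sd of the log-normal diameter law (default 0.3,
#'   reproducing diameter coefficients of variation of ~0.2-0.4).
#' @param markerMeanPerSpecies named mean copy numbers at the 80 nm reference
#'   diameter. Defaults give ~14-17 detected markers per vesicle under the
#'   mouse-panel stain and ~14 detected HsCD81 per tracer-positive vesicle,
#'   matching the detected-marker averages of the assay this simulator
#'   emulates.
#' @param labelProb antibody labeling efficiency per marker copy.
#' @param captureProbPerCopy per-copy capture probability.
#' @param nonspecificRate nonspecific captures per ROI.
#' @param locsPerAntibodyMean mean blink count per bound antibody (default 14,
#'   the calibration constant of the assay).
#' @param locSigmaNm localization precision (nm per axis).
#' @param backgroundDensity background localizations per um^2.
#' @param roiWidthNm,roiHeightNm ROI dimensions in nm (default 50 x 50 um).
#' @param nRoi number of ROIs (default 20, the plasma design).
#' @param seed master seed.
#' @return A validated [SimConfig-class] object.
#' @examples
#' cfg <- simConfig(nEv = 100, fractionPositive = 0.15, seed = 7)
#' cfg
#' @export
simConfig <- function(nEv,
                      fractionPositive,
                      diameterMedianNm = 80,
                      diameterLogSd = 0.3,
                      markerMeanPerSpecies = c(MmCD9 = 6.7, MmCD63 = 6.7,
                                               MmCD81 = 6.7, HsCD81 = 20),
                      labelProb = 0.7,
                      captureProbPerCopy = 0.35,
                      nonspecificRate = 0,
                      locsPerAntibodyMean = 14,
                      locSigmaNm = 10,
                      backgroundDensity = 0.5,
                      roiWidthNm = 50000,
                      roiHeightNm = 50000,
                      nRoi = 20L,
                      seed = 1L) {
  cfg <- try(new("SimConfig",
    nEv = as.integer(nEv),
    fractionPositive = as.numeric(fractionPositive),
    diameterMedianNm = as.numeric(diameterMedianNm),
    diameterLogSd = as.numeric(diameterLogSd),
    markerMeanPerSpecies = markerMeanPerSpecies,
    labelProb = as.numeric(labelProb),
    captureProbPerCopy = as.numeric(captureProbPerCopy),
    nonspecificRate = as.numeric(nonspecificRate),
    locsPerAntibodyMean = as.numeric(locsPerAntibodyMean),
    locSigmaNm = as.numeric(locSigmaNm),
    backgroundDensity = as.numeric(backgroundDensity),
    roiWidthNm = as.numeric(roiWidthNm),
    roiHeightNm = as.numeric(roiHeightNm),
    nRoi = as.integer(nRoi),
    seed = as.integer(seed)
  ), silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("invalid simulation configuration: ", attr(cfg, "condition")$message,
         call. = FALSE)
  cfg
}

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nEv, "EVs,",
      sprintf("%.1f%% tracer-positive,", 100 * object@fractionPositive),
      object@nRoi, "ROI(s) of",
      sprintf("%g x %g um,", object@roiWidthNm / 1000,
              object@roiHeightNm / 1000),
      "seed", object@seed, "\n")
})

#' Assay configuration
#'
#' Describes one capture/stain qSMLM experiment: the coverslip capture
#' antibody, the fluorescent stain panel, the raw-biofluid volume incubated
#' on the coverslip, and the calibration constants of the analysis (`L`
#' localizations per antibody, minimum of `M` localizations per cluster,
#' Voronoi density-threshold multiplier `alpha`).
#'
#' @slot captureTarget species bound by the coverslip antibody.
#' @slot stainPanel species detected by the fluorescent antibody stain.
#' @slot volumeRawUl raw biofluid volume incubated, in microlitres.
#' @slot L localizations per single fluorescent antibody (calibration).
#' @slot M minimum localizations per reported cluster.
#' @slot alpha Voronoi cell-area threshold multiplier.
#' @slot sigmaDefaultNm fallback localization precision when tables carry none.
#' @slot excludeBoundaryClusters drop clusters touching the ROI edge.
#' @seealso [assayConfig()], [readAssayConfig()]
#' @export
setClass("AssayConfig",
  slots = c(
    captureTarget = "character",
    stainPanel = "character",
    volumeRawUl = "numeric",
    L = "numeric",
    M = "integer",
    alpha = "numeric",
    sigmaDefaultNm = "numeric",
    excludeBoundaryClusters = "logical"
  )
)

setValidity("AssayConfig", function(object) {
  msg <- character()
  if (length(object@captureTarget) != 1 ||
      !object@captureTarget %in% evMarkerSpecies())
    msg <- c(msg, "captureTarget: unknown marker species")
  if (length(object@stainPanel) < 1 ||
      !all(object@stainPanel %in% evMarkerSpecies()))
    msg <- c(msg, "stainPanel: unknown marker species")
  if (!length(object@volumeRawUl) || !is.finite(object@volumeRawUl) ||
      object@volumeRawUl <= 0)
    msg <- c(msg, "volume_raw_ul must be > 0")
  if (!is.finite(object@L) || object@L <= 0)
    msg <- c(msg, "L must be > 0")
  if (is.na(object@M) || object@M < 1)
    msg <- c(msg, "M must be >= 1")
  if (!is.finite(object@alpha) || object@alpha <= 0)
    msg <- c(msg, "alpha must be > 0")
  if (object@sigmaDefaultNm < 0)
    msg <- c(msg, "sigma_default must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct an assay configuration
#'
#' @param captureTarget coverslip capture species, e.g. `"MmCD81"`.
#' @param stainPanel character vector of stained species.
#' @param volumeRawUl incubated raw-biofluid volume in microlitres.
#' @param L localizations per antibody calibration constant (default 14).
#' @param M minimum localizations per cluster (default 40).
#' @param alpha Voronoi cell-area threshold multiplier (default 0.5).
#' @param sigmaDefaultNm fallback localization precision in nm (default 12).
#' @param excludeBoundaryClusters drop clusters touching the ROI edge
#'   (default TRUE).
#' @return A validated [AssayConfig-class] object.
#' @examples
#' assayConfig("MmCD81", c("MmCD9", "MmCD63", "MmCD81"), volumeRawUl = 1)
#' @export
assayConfig <- function(captureTarget, stainPanel, volumeRawUl,
                        L = 14, M = 40L, alpha = 0.5, sigmaDefaultNm = 12,
                        excludeBoundaryClusters = TRUE) {
  cfg <- try(new("AssayConfig",
    captureTarget = as.character(captureTarget),
    stainPanel = as.character(stainPanel),
    volumeRawUl = as.numeric(volumeRawUl),
    L = as.numeric(L),
    M = as.integer(M),
    alpha = as.numeric(alpha),
    sigmaDefaultNm = as.numeric(sigmaDefaultNm),
    excludeBoundaryClusters = isTRUE(excludeBoundaryClusters)
  ), silent = TRUE)
  if (inherits(cfg, "try-error"))
    stop("invalid assay configuration: ", attr(cfg, "condition")$message,
         call. = FALSE)
  cfg
}

setMethod("show", "AssayConfig", function(object) {
  cat("AssayConfig: capture", object@captureTarget,
      "| stain", paste(object@stainPanel, collapse = "+"),
      "|", object@volumeRawUl, "uL | L =", object@L,
      "| M =", object@M, "| alpha =", object@alpha, "\n")
})

#' A region of interest with its localization table
#'
#' One imaged field of a capture coverslip. Localizations are stored as a
#' data.frame with columns `id`, `frame`, `x`, `y` (nm, origin at the ROI
#' lower-left corner, y upward) and optionally `sigma` (nm) and `intensity`.
#'
#' @slot roiId identifier of the ROI.
#' @slot widthNm,heightNm physical ROI dimensions in nm.
#' @slot localizations localization data.frame.
#' @slot coverslipId identifier of the parent coverslip.
#' @seealso [smlmRoi()], [readLocalizations()]
#' @export
setClass("SmlmRoi",
  slots = c(
    roiId = "character",
    widthNm = "numeric",
    heightNm = "numeric",
    localizations = "data.frame",
    coverslipId = "character"
  )
)

setValidity("SmlmRoi", function(object) {
  msg <- character()
  if (object@widthNm <= 0 || object@heightNm <= 0)
    msg <- c(msg, "ROI dimensions must be > 0")
  loc <- object@localizations
  need <- c("id", "frame", "x", "y")
  if (!all(need %in% names(loc)))
    msg <- c(msg, paste("localizations must have columns",
                        paste(need, collapse = ", ")))
  else if (nrow(loc)) {
    if (any(loc$x < 0 | loc$x > object@widthNm |
            loc$y < 0 | loc$y > object@heightNm))
      msg <- c(msg, "localizations outside the ROI bounds")
    if (anyDuplicated(loc$id))
      msg <- c(msg, "duplicate localization ids within one ROI")
    if ("sigma" %in% names(loc) && any(loc$sigma < 0, na.rm = TRUE))
      msg <- c(msg, "sigma must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a region of interest
#'
#' @param roiId ROI identifier.
#' @param widthNm,heightNm ROI dimensions in nm.
#' @param localizations data.frame with at least `x` and `y` in nm; `id` and
#'   `frame` are added when absent.
#' @param coverslipId parent coverslip identifier.
#' @return A validated [SmlmRoi-class] object.
#' @export
smlmRoi <- function(roiId, widthNm, heightNm,
                    localizations = data.frame(), coverslipId = NA_character_) {
  loc <- as.data.frame(localizations)
  if (!nrow(loc)) {
    loc <- data.frame(id = integer(), frame = integer(),
                      x = numeric(), y = numeric())
  } else {
    if (!"id" %in% names(loc)) loc$id <- seq_len(nrow(loc))
    if (!"frame" %in% names(loc)) loc$frame <- seq_len(nrow(loc))
  }
  new("SmlmRoi", roiId = as.character(roiId), widthNm = as.numeric(widthNm),
      heightNm = as.numeric(heightNm), localizations = loc,
      coverslipId = as.character(coverslipId))
}

setMethod("show", "SmlmRoi", function(object) {
  cat("SmlmRoi", object@roiId, ":", nrow(object@localizations),
      "localizations in",
      sprintf("%g x %g um\n", object@widthNm / 1000, object@heightNm / 1000))
})

#' Voronoi tessellation of one ROI
#'
#' Result of [tessellate()]: one Voronoi cell per spatially distinct
#' localization, clipped to the ROI rectangle. Exact coordinate duplicates
#' are merged before tessellation and carry a multiplicity, which counts
#' toward cluster sizes downstream.
#'
#' @slot roiId parent ROI.
#' @slot widthNm,heightNm ROI dimensions in nm.
#' @slot cells data.frame with columns `cellId`, `x`, `y`, `multiplicity`,
#'   `area` (nm^2) and `touchesBoundary`.
#' @slot edges two-column integer matrix of cell ids sharing a Voronoi edge
#'   of positive length.
#' @slot assignment integer vector mapping each input localization (row of
#'   the ROI table) to its cellId.
#' @slot locId original localization ids, parallel to `assignment`.
#' @export
setClass("VoronoiTessellation",
  slots = c(
    roiId = "character",
    widthNm = "numeric",
    heightNm = "numeric",
    cells = "data.frame",
    edges = "matrix",
    assignment = "integer",
    locId = "integer"
  )
)

setMethod("show", "VoronoiTessellation", function(object) {
  cat("VoronoiTessellation of ROI", object@roiId, ":",
      nrow(object@cells), "cells (",
      length(object@assignment), "localizations ),",
      nrow(object@edges), "adjacencies\n")
})

#' Detected vesicle clusters of one ROI
#'
#' Result of [extractClusters()] / [clusterRoi()]: connected components of
#' density-retained Voronoi cells with at least `M` member localizations.
#'
#' @slot roiId parent ROI.
#' @slot clusters data.frame with columns `clusterId`, `roiId`, `nLoc`,
#'   `centroidX`, `centroidY`, `touchesBoundary`.
#' @slot membership data.frame mapping `locId` to `clusterId`.
#' @slot nBoundaryExcluded clusters discarded for touching the ROI edge.
#' @slot nBelowMin components discarded for having fewer than M members.
#' @export
setClass("EvClusterSet",
  slots = c(
    roiId = "character",
    clusters = "data.frame",
    membership = "data.frame",
    nBoundaryExcluded = "integer",
    nBelowMin = "integer"
  )
)

setMethod("show", "EvClusterSet", function(object) {
  cat("EvClusterSet of ROI", object@roiId, ":", nrow(object@clusters),
      "clusters (", object@nBelowMin, "below size minimum,",
      object@nBoundaryExcluded, "boundary-excluded )\n")
})

#' @describeIn SmlmRoi-class localization table accessor
#' @param object an object of the documented class.
#' @export
setGeneric("localizations", function(object) standardGeneric("localizations"))

#' @rdname SmlmRoi-class
#' @export
setMethod("localizations", "SmlmRoi", function(object) object@localizations)

#' Number of localizations in an ROI
#' @param object an [SmlmRoi-class] object.
#' @export
setGeneric("nLocalizations", function(object) standardGeneric("nLocalizations"))

#' @rdname nLocalizations
#' @export
setMethod("nLocalizations", "SmlmRoi",
          function(object) nrow(object@localizations))

#' @describeIn VoronoiTessellation-class per-cell table accessor
#' @param object an object of the documented class.
#' @export
setGeneric("cellInfo", function(object) standardGeneric("cellInfo"))

#' @rdname VoronoiTessellation-class
#' @export
setMethod("cellInfo", "VoronoiTessellation", function(object) object@cells)

#' @describeIn VoronoiTessellation-class Voronoi adjacency accessor
#' @export
setGeneric("cellAdjacency", function(object) standardGeneric("cellAdjacency"))

#' @rdname VoronoiTessellation-class
#' @export
setMethod("cellAdjacency", "VoronoiTessellation", function(object) object@edges)

#' @describeIn EvClusterSet-class cluster table accessor
#' @param object an object of the documented class.
#' @export
setGeneric("clusterTable", function(object) standardGeneric("clusterTable"))

#' @rdname EvClusterSet-class
#' @export
setMethod("clusterTable", "EvClusterSet", function(object) object@clusters)

#' @describeIn EvClusterSet-class localization-to-cluster map accessor
#' @export
setGeneric("clusterMembership",
           function(object) standardGeneric("clusterMembership"))

#' @rdname EvClusterSet-class
#' @export
setMethod("clusterMembership", "EvClusterSet",
          function(object) object@membership)
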