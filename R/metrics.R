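# Per-vesicle biophysical quantities: detected tetraspanin count via the
# L-localizations-per-antibody calibration, and diameter via inversion of
# the projected-sphere second moment with a Gaussian-precision correction.

#' Detected markers from a localization count
#'
#' The blinking calibration of the assay: one bound fluorescent antibody
#' emits on average `L` localizations, so a cluster of `nLoc` localizations
#' corresponds to `nLoc / L` detected marker proteins. Kept real-valued;
#' rounding happens only at display.
#'
#' @param nLoc localization count(s), >= 0.
#' @param L localizations per antibody (default 14).
#' @return `nLoc / L`.
#' @examples
#' markerCount(40)   # ~3 detected markers: the positivity floor
#' markerCount(14)   # exactly one antibody
#' @export
markerCount <- function(nLoc, L = 14) {
  if (!is.finite(L) || L <= 0) stop("L must be > 0", call. = FALSE)
  if (any(nLoc < 0)) stop("nLoc must be >= 0", call. = FALSE)
  nLoc / L
}

#' Vesicle diameter from member localizations
#'
#' For antibodies anchored uniformly on a sphere of radius R and imaged in
#' orthographic projection, the mean squared in-plane distance from the
#' centre is 2R^2/3; localization noise of sd `sigma` per axis adds
#' 2*sigma^2. The estimator inverts this:
#' `D = 2 * sqrt(1.5 * max(0, m2 - 2 sigma^2))`, where m2 is the mean
#' squared radial distance of the members from their centroid. Returns 0
#' when the precision correction exceeds the observed spread.
#'
#' @param xy two-column matrix or data.frame of member positions (nm).
#' @param sigmaNm localization precision per axis (nm); scalar or
#'   per-localization vector.
#' @return Diameter estimate in nm (>= 0).
#' @examples
#' th <- seq(0, 2 * pi, length.out = 200)
#' ring <- cbind(40 * cos(th), 40 * sin(th))  # all anchors on the equator
#' estimateDiameter(ring, sigmaNm = 0)        # sqrt(1.5) * 80
#' @export
estimateDiameter <- function(xy, sigmaNm = 0) {
  xy <- as.matrix(xy)
  if (nrow(xy) < 2)
    stop("diameter is undefined for fewer than 2 localizations",
         call. = FALSE)
  if (any(sigmaNm < 0)) stop("sigma must be >= 0", call. = FALSE)
  cx <- mean(xy[, 1]); cy <- mean(xy[, 2])
  m2 <- mean((xy[, 1] - cx)^2 + (xy[, 2] - cy)^2)
  correction <- 2 * mean(sigmaNm^2)
  2 * sqrt(1.5 * max(0, m2 - correction))
}

# per-cluster sigma: localization sigma column if present, else the ROI
# median sigma, else the configured default
clusterSigma <- function(memberSigma, roiSigma, config) {
  if (length(memberSigma) && any(is.finite(memberSigma)))
    return(memberSigma[is.finite(memberSigma)])
  if (length(roiSigma) && any(is.finite(roiSigma)))
    return(median(roiSigma[is.finite(roiSigma)]))
  config@sigmaDefaultNm
}

#' Measure detected clusters of one ROI
#'
#' Converts each cluster of an [EvClusterSet-class] into per-vesicle
#' quantities: localization count, detected markers (`nLoc / L`), diameter
#' estimate, and the mean squared radial spread of its members.
#'
#' @param clusterSet an [EvClusterSet-class].
#' @param roi the [SmlmRoi-class] the clusters were detected in.
#' @param config an [AssayConfig-class] (supplies `L` and the fallback
#'   localization precision).
#' @return data.frame with columns `clusterId`, `roiId`, `nLoc`, `markers`,
#'   `diameterNm`, `meanR2`.
#' @export
measureClusters <- function(clusterSet, roi, config) {
  stopifnot(is(clusterSet, "EvClusterSet"), is(roi, "SmlmRoi"),
            is(config, "AssayConfig"))
  loc <- roi@localizations
  mem <- merge(clusterSet@membership, loc, by.x = "locId", by.y = "id")
  cl <- clusterSet@clusters
  if (!nrow(cl)) {
    return(data.frame(clusterId = integer(), roiId = character(),
                      nLoc = integer(), markers = numeric(),
                      diameterNm = numeric(), meanR2 = numeric()))
  }
  roiSigma <- if ("sigma" %in% names(loc)) loc$sigma else numeric()
  res <- lapply(seq_len(nrow(cl)), function(i) {
    m <- mem[mem$clusterId == cl$clusterId[i], , drop = FALSE]
    sig <- clusterSigma(if ("sigma" %in% names(m)) m$sigma else numeric(),
                        roiSigma, config)
    d <- estimateDiameter(m[, c("x", "y")], sig)
    cx <- mean(m$x); cy <- mean(m$y)
    data.frame(clusterId = cl$clusterId[i], roiId = cl$roiId[i],
               nLoc = cl$nLoc[i],
               markers = markerCount(cl$nLoc[i], config@L),
               diameterNm = d,
               meanR2 = mean((m$x - cx)^2 + (m$y - cy)^2))
  })
  do.call(rbind, res)
}

#' Cohort averages of per-vesicle metrics
#'
#' Arithmetic means and coefficients of variation (sample sd / mean) of the
#' detected-marker count and diameter over a set of measured vesicles — the
#' per-cohort `TSPAN/EV` average and mean diameter `D_Av`.
#'
#' @param measurements data.frame from [measureClusters()] (rows from
#'   several ROIs may be concatenated).
#' @return One-row data.frame: `nEv`, `tspanPerEvAv`, `tspanCv`, `dAvNm`,
#'   `diameterCv`. CVs are `NA` with a warning when only one vesicle is
#'   supplied.
#' @export
summarizeEvMetrics <- function(measurements) {
  if (!nrow(measurements))
    stop("cannot summarize an empty measurement set", call. = FALSE)
  n <- nrow(measurements)
  if (n < 2)
    warning("coefficient of variation undefined for a single vesicle")
  cv <- function(v) if (n < 2) NA_real_ else sd(v) / mean(v)
  data.frame(nEv = n,
             tspanPerEvAv = mean(measurements$markers),
             tspanCv = cv(measurements$markers),
             dAvNm = mean(measurements$diameterNm),
             diameterCv = cv(measurements$diameterNm))
}
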