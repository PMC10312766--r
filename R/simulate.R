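# Forward simulator of the single-vesicle capture/stain dSTORM assay.
# Three stages mirror the physical experiment: a vesicle population in the
# biofluid, antibody capture onto the coverslip, and stained-antibody
# blinking into localization tables. Every stage derives its own seed
# stream from the master seed, so stages and ROIs are reproducible
# independently of evaluation order.

# zero-truncated Poisson via inverse-CDF restricted to k >= 1
rztpois <- function(n, lambda) {
  if (n == 0) return(integer())
  p0 <- ppois(0, lambda)
  u <- runif(n, p0, 1)
  qpois(u, lambda)
}

#' Simulate a vesicle population
#'
#' Draws `nEv` vesicles with log-normal diameters and per-species marker
#' copy numbers that are Poisson with mean proportional to membrane area
#' (`(diameter/80 nm)^2`). A vesicle is tracer-positive with probability
#' `fractionPositive`; tracer-positive vesicles draw their HsCD81 copy
#' number from a zero-truncated Poisson (at least one copy), tracer-negative
#' vesicles carry none, so tracer positivity and HsCD81 presence coincide
#' exactly.
#'
#' @param cfg a [SimConfig-class] object.
#' @return data.frame with one row per vesicle: `evId`, `diameterNm`, one
#'   copy-number column per species, and `tracerPositive`.
#' @examples
#' pop <- simulateEvPopulation(simConfig(nEv = 50, fractionPositive = 0.2))
#' head(pop)
#' @export
simulateEvPopulation <- function(cfg) {
  stopifnot(is(cfg, "SimConfig"))
  validObject(cfg)
  set.seed(deriveSeed(cfg@seed, 1L))
  n <- cfg@nEv
  d <- rlnorm(n, meanlog = log(cfg@diameterMedianNm),
              sdlog = cfg@diameterLogSd)
  areaScale <- (d / 80)^2
  pos <- runif(n) < cfg@fractionPositive
  pop <- data.frame(evId = seq_len(n), diameterNm = d)
  tracer <- tracerSpecies()
  for (sp in evMarkerSpecies()) {
    lam <- unname(cfg@markerMeanPerSpecies[sp])
    if (is.na(lam)) lam <- 0
    if (sp == tracer) {
      k <- integer(n)
      k[pos] <- rztpois(sum(pos), lam * areaScale[pos])
      pop[[sp]] <- k
    } else {
      pop[[sp]] <- rpois(n, lam * areaScale)
    }
  }
  pop$tracerPositive <- pos
  pop
}

#' Simulate antibody capture onto the coverslip
#'
#' A vesicle carrying `k` copies of the capture target is immobilized with
#' probability `1 - (1 - pCap)^k` (zero copies: never captured
#' specifically). Additionally, a Poisson(`nonspecificRate`) number of
#' vesicles per ROI is immobilized regardless of composition. Captured
#' vesicles receive a uniform-random ROI and position within it.
#'
#' @param population data.frame from [simulateEvPopulation()].
#' @param captureTarget species bound by the coverslip antibody.
#' @param cfg the [SimConfig-class] used to generate the population.
#' @return The captured subset of `population` with extra columns `roi`,
#'   `cx`, `cy` (centre, nm) and `nonspecific`.
#' @export
simulateCapture <- function(population, captureTarget, cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (!captureTarget %in% evMarkerSpecies())
    stop("unknown capture species: ", captureTarget, call. = FALSE)
  set.seed(deriveSeed(cfg@seed, 2L))
  k <- population[[captureTarget]]
  pCapture <- 1 - (1 - cfg@captureProbPerCopy)^k
  specific <- runif(nrow(population)) < pCapture

  nonspecific <- rep(FALSE, nrow(population))
  if (cfg@nonspecificRate > 0) {
    nExtra <- sum(rpois(cfg@nRoi, cfg@nonspecificRate))
    candidates <- which(!specific)
    if (nExtra > 0 && length(candidates) > 0) {
      pick <- candidates[sample.int(length(candidates),
                                    min(nExtra, length(candidates)))]
      nonspecific[pick] <- TRUE
    }
  }

  captured <- population[specific | nonspecific, , drop = FALSE]
  captured$nonspecific <- nonspecific[specific | nonspecific]
  nc <- nrow(captured)
  captured$roi <- if (nc) sample.int(cfg@nRoi, nc, replace = TRUE) else integer()
  captured$cx <- runif(nc, 0, cfg@roiWidthNm)
  captured$cy <- runif(nc, 0, cfg@roiHeightNm)
  rownames(captured) <- NULL
  captured
}

# uniform points on a sphere of radius R, orthographically projected to the
# coverslip plane; returns offsets from the vesicle centre
projectedSphereOffsets <- function(radii) {
  n <- length(radii)
  z <- runif(n, -1, 1) * radii
  phi <- runif(n, 0, 2 * pi)
  r <- sqrt(pmax(0, radii^2 - z^2))
  cbind(dx = r * cos(phi), dy = r * sin(phi))
}

#' Simulate localization tables for captured vesicles
#'
#' Each copy of a stained species is bound by a labeled antibody with
#' probability `labelProb`; each bound antibody anchors at a uniform point
#' on the vesicle's spherical surface (orthographic projection) and emits a
#' geometric number of localizations (support >= 1) with mean
#' `locsPerAntibodyMean`; each localization adds isotropic Gaussian noise of
#' sd `locSigmaNm` per axis. Background localizations form a spatial Poisson
#' process at `backgroundDensity` per um^2. Localizations falling outside
#' the ROI rectangle are discarded (edge vignetting). The truth table links
#' every emitted in-bounds localization to its vesicle or to background
#' (`evId = -1`).
#'
#' @param captured data.frame as returned by [simulateCapture()] (columns
#'   `evId`, `diameterNm`, per-species copies, `roi`, `cx`, `cy`).
#' @param stainPanel character vector of stained species.
#' @param cfg a [SimConfig-class] object.
#' @return list with elements `rois` (list of [SmlmRoi-class], one per ROI),
#'   `truth` (data.frame `locId`, `evId`, `species`, `roiId`) and
#'   `antibodies` (one row per bound antibody: `roiId`, `evId`, `species`,
#'   `abId`, `nBlinks`).
#' @export
simulateLocalizations <- function(captured, stainPanel, cfg) {
  stopifnot(is(cfg, "SimConfig"))
  if (length(stainPanel) < 1)
    stop("stain panel must not be empty", call. = FALSE)
  if (!all(stainPanel %in% evMarkerSpecies()))
    stop("unknown species in stain panel: ",
         paste(setdiff(stainPanel, evMarkerSpecies()), collapse = ", "),
         call. = FALSE)
  if (cfg@roiWidthNm <= 0 || cfg@roiHeightNm <= 0)
    stop("ROI dimensions must be positive", call. = FALSE)

  rois <- vector("list", cfg@nRoi)
  truthList <- vector("list", cfg@nRoi)
  abList <- vector("list", cfg@nRoi)
  pBlink <- 1 / cfg@locsPerAntibodyMean
  areaUm2 <- cfg@roiWidthNm * cfg@roiHeightNm / 1e6

  for (i in seq_len(cfg@nRoi)) {
    set.seed(deriveSeed(cfg@seed, 100L + i))
    roiId <- sprintf("roi%03d", i)
    ev <- captured[!is.na(captured$roi) & captured$roi == i, , drop = FALSE]

    # one row per (vesicle, species) with its bound-antibody count
    anchorX <- numeric(0); anchorY <- numeric(0)
    abEv <- integer(0); abSpecies <- character(0)
    for (sp in stainPanel) {
      nAb <- if (nrow(ev)) rbinom(nrow(ev), ev[[sp]], cfg@labelProb) else integer()
      idx <- rep.int(seq_len(nrow(ev)), nAb)
      if (length(idx)) {
        off <- projectedSphereOffsets(ev$diameterNm[idx] / 2)
        anchorX <- c(anchorX, ev$cx[idx] + off[, "dx"])
        anchorY <- c(anchorY, ev$cy[idx] + off[, "dy"])
        abEv <- c(abEv, ev$evId[idx])
        abSpecies <- c(abSpecies, rep.int(sp, length(idx)))
      }
    }
    nAbTot <- length(anchorX)
    blinks <- if (nAbTot) rgeom(nAbTot, pBlink) + 1L else integer()

    locIdx <- rep.int(seq_len(nAbTot), blinks)
    x <- anchorX[locIdx] + rnorm(length(locIdx), 0, cfg@locSigmaNm)
    y <- anchorY[locIdx] + rnorm(length(locIdx), 0, cfg@locSigmaNm)
    evId <- abEv[locIdx]
    species <- abSpecies[locIdx]

    nBg <- rpois(1, cfg@backgroundDensity * areaUm2)
    x <- c(x, runif(nBg, 0, cfg@roiWidthNm))
    y <- c(y, runif(nBg, 0, cfg@roiHeightNm))
    evId <- c(evId, rep.int(-1L, nBg))
    species <- c(species, rep.int("background", nBg))

    keep <- x >= 0 & x <= cfg@roiWidthNm & y >= 0 & y <= cfg@roiHeightNm
    x <- x[keep]; y <- y[keep]; evId <- evId[keep]; species <- species[keep]
    n <- length(x)
    ord <- sample.int(n)  # shuffle so row order carries no ground truth
    loc <- data.frame(
      id = seq_len(n),
      frame = sort(sample.int(max(10L * n, 1L), n, replace = TRUE)),
      x = x[ord], y = y[ord],
      sigma = rep.int(cfg@locSigmaNm, n),
      intensity = round(rlnorm(n, log(1000), 0.3), 1)
    )
    rois[[i]] <- smlmRoi(roiId, cfg@roiWidthNm, cfg@roiHeightNm, loc,
                         coverslipId = "sim")
    truthList[[i]] <- data.frame(locId = loc$id, evId = evId[ord],
                                 species = species[ord],
                                 roiId = rep.int(roiId, n))
    abList[[i]] <- if (nAbTot) {
      data.frame(roiId = roiId, evId = abEv, species = abSpecies,
                 abId = seq_len(nAbTot), nBlinks = blinks)
    } else {
      data.frame(roiId = character(), evId = integer(),
                 species = character(), abId = integer(), nBlinks = integer())
    }
  }
  list(rois = rois,
       truth = do.call(rbind, truthList),
       antibodies = do.call(rbind, abList))
}

#' Simulate one complete capture/stain experiment
#'
#' Convenience wrapper chaining [simulateEvPopulation()],
#' [simulateCapture()] and [simulateLocalizations()].
#'
#' @param cfg a [SimConfig-class] object.
#' @param captureTarget coverslip capture species.
#' @param stainPanel stained species.
#' @return list with `rois`, `truth`, `antibodies`, `population`, `captured`.
#' @examples
#' cfg <- simConfig(nEv = 60, fractionPositive = 0.15, nRoi = 2L,
#'                  backgroundDensity = 0.1, seed = 11)
#' sim <- simulateAssay(cfg, "MmCD81", c("MmCD9", "MmCD63", "MmCD81"))
#' sim$rois[[1]]
#' @export
simulateAssay <- function(cfg, captureTarget, stainPanel) {
  population <- simulateEvPopulation(cfg)
  captured <- simulateCapture(population, captureTarget, cfg)
  sim <- simulateLocalizations(captured, stainPanel, cfg)
  c(sim, list(population = population, captured = captured))
}
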