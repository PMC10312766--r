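# Voronoi-tessellation density clustering of one ROI: tessellate the
# localization cloud, retain localizations whose cell is small relative to
# the ROI median (high local density), and report connected components of
# the retained cells with at least M member localizations.

#' Voronoi tessellation of an ROI's localizations
#'
#' Computes the Voronoi diagram of the (deduplicated) localization
#' positions, clipped to the ROI rectangle. Cell areas are positive and
#' partition the ROI exactly; two cells are adjacent when they share a
#' polygon edge of positive length (vertex-only contact does not connect).
#' Exact coordinate duplicates are merged beforehand and recorded as a
#' multiplicity, which counts toward cluster sizes downstream.
#'
#' Fewer than four spatially distinct localizations, or an all-collinear
#' cloud, cannot be tessellated; an empty tessellation is returned with a
#' warning.
#'
#' @param roi an [SmlmRoi-class].
#' @return A [VoronoiTessellation-class].
#' @examples
#' roi <- smlmRoi("demo", 1000, 1000,
#'                data.frame(x = c(250, 750, 250, 750),
#'                           y = c(250, 250, 750, 750)))
#' tess <- tessellate(roi)
#' cellInfo(tess)$area / (1000 * 1000)  # four quarter cells
#' @export
tessellate <- function(roi) {
  stopifnot(is(roi, "SmlmRoi"))
  loc <- roi@localizations
  emptyTess <- function() {
    new("VoronoiTessellation", roiId = roi@roiId, widthNm = roi@widthNm,
        heightNm = roi@heightNm,
        cells = data.frame(cellId = integer(), x = numeric(), y = numeric(),
                           multiplicity = integer(), area = numeric(),
                           touchesBoundary = logical()),
        edges = matrix(integer(), 0, 2),
        assignment = integer(), locId = integer())
  }
  if (nrow(loc) == 0) {
    warning("ROI ", roi@roiId, " has no localizations")
    return(emptyTess())
  }

  # merge exact duplicates, keep multiplicity
  keyOrd <- order(loc$x, loc$y)
  xo <- loc$x[keyOrd]; yo <- loc$y[keyOrd]
  newGroup <- c(TRUE, xo[-1] != xo[-length(xo)] | yo[-1] != yo[-length(yo)])
  groupOfSorted <- cumsum(newGroup)
  assignment <- integer(nrow(loc))
  assignment[keyOrd] <- groupOfSorted
  ux <- xo[newGroup]; uy <- yo[newGroup]
  mult <- as.integer(tabulate(groupOfSorted))
  nCells <- length(ux)

  collinear <- function(x, y) {
    if (length(x) < 3) return(TRUE)
    dx <- x - x[1]; dy <- y - y[1]
    span <- max(abs(dx), abs(dy))
    if (span == 0) return(TRUE)
    all(abs(dx * dy[2] - dy * dx[2]) < 1e-9 * span^2) ||
      all(abs(dx[2]) < 1e-12 & abs(dy[2]) < 1e-12)
  }
  if (nCells < 4) {
    warning("ROI ", roi@roiId, ": fewer than 4 distinct localizations; ",
            "tessellation skipped")
    return(emptyTess())
  }
  if (collinear(ux, uy)) {
    warning("ROI ", roi@roiId, ": localizations are collinear; ",
            "tessellation skipped")
    return(emptyTess())
  }

  res <- cpp_voronoi(ux, uy, roi@widthNm, roi@heightNm, FALSE)
  cells <- data.frame(cellId = seq_len(nCells), x = ux, y = uy,
                      multiplicity = mult, area = res$area,
                      touchesBoundary = res$touchesBoundary)
  new("VoronoiTessellation", roiId = roi@roiId, widthNm = roi@widthNm,
      heightNm = roi@heightNm, cells = cells, edges = res$edges,
      assignment = assignment, locId = as.integer(loc$id))
}

#' First-rank density threshold on the tessellation
#'
#' Retains the localizations whose first-rank local density — localization
#' count over area of the cell together with its edge-sharing neighbours —
#' is at least `1/alpha` times the ROI-average density (total
#' localizations over ROI area). With the default `alpha = 0.5` this is
#' the classic "local density at least twice the average" criterion of
#' Voronoi SMLM segmentation. Averaging over the first neighbour rank
#' keeps a cluster's outermost cells (whose own cells stretch into empty
#' background) while still rejecting isolated background points, and the
#' criterion is scale-free. Decreasing `alpha` never enlarges the
#' retained set.
#'
#' @param tess a [VoronoiTessellation-class].
#' @param alpha positive threshold multiplier (default 0.5).
#' @return Integer vector of retained `cellId`s.
#' @export
thresholdDensity <- function(tess, alpha = 0.5) {
  stopifnot(is(tess, "VoronoiTessellation"))
  if (!is.finite(alpha) || alpha <= 0)
    stop("alpha must be > 0", call. = FALSE)
  cells <- tess@cells
  n <- nrow(cells)
  if (!n) return(integer())
  e <- tess@edges
  nbrCount <- numeric(n)
  nbrArea <- numeric(n)
  if (nrow(e)) {
    agg1 <- rowsum(cbind(cells$multiplicity[e[, 2]], cells$area[e[, 2]]),
                   e[, 1])
    agg2 <- rowsum(cbind(cells$multiplicity[e[, 1]], cells$area[e[, 1]]),
                   e[, 2])
    i1 <- as.integer(rownames(agg1)); i2 <- as.integer(rownames(agg2))
    nbrCount[i1] <- nbrCount[i1] + agg1[, 1]
    nbrArea[i1] <- nbrArea[i1] + agg1[, 2]
    nbrCount[i2] <- nbrCount[i2] + agg2[, 1]
    nbrArea[i2] <- nbrArea[i2] + agg2[, 2]
  }
  dens1 <- (cells$multiplicity + nbrCount) / (cells$area + nbrArea)
  avgDensity <- sum(cells$multiplicity) / (tess@widthNm * tess@heightNm)
  cells$cellId[dens1 >= avgDensity / alpha]
}

#' Extract vesicle clusters from retained Voronoi cells
#'
#' Cluster cores are the connected components of the retained cells under
#' shared-edge Voronoi adjacency. A morphological closure then recovers a
#' cluster's fringe: unretained cells whose strict majority of Voronoi
#' neighbours already belongs to one cluster are attached to it,
#' iteratively until stable. (A dense cluster's outermost localizations
#' have large cells stretching into empty background and fail the density
#' threshold even though they belong to the vesicle; the majority rule
#' reclaims them while leaving isolated background points unattached.)
#'
#' Clusters with fewer than `M` member localizations (counting
#' duplicate-coordinate multiplicity) are discarded; when
#' `excludeBoundary` is set, clusters whose core cells touch the ROI
#' rectangle edge are discarded and counted separately (truncation bias).
#' Cluster centroids are arithmetic means of member localization
#' positions.
#'
#' @param tess a [VoronoiTessellation-class].
#' @param retained integer vector of retained cellIds (from
#'   [thresholdDensity()]).
#' @param M minimum localizations per reported cluster (default 40).
#' @param excludeBoundary drop clusters touching the ROI edge (default TRUE).
#' @param closure attach majority-surrounded fringe cells (default TRUE).
#' @return An [EvClusterSet-class].
#' @export
extractClusters <- function(tess, retained, M = 40L, excludeBoundary = TRUE,
                            closure = TRUE) {
  stopifnot(is(tess, "VoronoiTessellation"))
  cells <- tess@cells
  emptySet <- function(nBoundary = 0L, nBelow = 0L) {
    new("EvClusterSet", roiId = tess@roiId,
        clusters = data.frame(clusterId = integer(), roiId = character(),
                              nLoc = integer(), centroidX = numeric(),
                              centroidY = numeric(),
                              touchesBoundary = logical()),
        membership = data.frame(locId = integer(), clusterId = integer()),
        nBoundaryExcluded = nBoundary, nBelowMin = nBelow)
  }
  if (!length(retained)) return(emptySet())
  if (!all(retained %in% cells$cellId))
    stop("retained ids are not a subset of the tessellation cells",
         call. = FALSE)

  nCell <- nrow(cells)
  inSet <- logical(nCell)
  inSet[retained] <- TRUE
  e <- tess@edges
  keepEdge <- inSet[e[, 1]] & inSet[e[, 2]]
  g <- igraph::graph_from_edgelist(
    matrix(as.character(e[keepEdge, , drop = FALSE]), ncol = 2),
    directed = FALSE)
  g <- g + igraph::vertices(setdiff(as.character(retained),
                                    igraph::V(g)$name))
  comp <- igraph::components(g)
  coreCell <- as.integer(igraph::V(g)$name)

  compOfCell <- rep(NA_integer_, nCell)
  compOfCell[coreCell] <- comp$membership
  isCore <- logical(nCell)
  isCore[coreCell] <- TRUE

  if (closure && nrow(e)) {
    deg <- tabulate(c(e[, 1], e[, 2]), nbins = nCell)
    eLen <- sqrt((cells$x[e[, 1]] - cells$x[e[, 2]])^2 +
                 (cells$y[e[, 1]] - cells$y[e[, 2]])^2)
    # attachment radius per component: twice the largest nearest-neighbour
    # spacing inside the core, so fringe points at the cluster's own
    # spacing scale are reclaimed but distant background never is
    bothCore <- !is.na(compOfCell[e[, 1]]) & !is.na(compOfCell[e[, 2]]) &
      compOfCell[e[, 1]] == compOfCell[e[, 2]]
    if (any(bothCore)) {
      nnDist <- rep(Inf, nCell)
      ec <- e[bothCore, , drop = FALSE]
      el <- eLen[bothCore]
      agg1 <- tapply(el, ec[, 1], min)
      agg2 <- tapply(el, ec[, 2], min)
      i1 <- as.integer(names(agg1)); i2 <- as.integer(names(agg2))
      nnDist[i1] <- pmin(nnDist[i1], agg1)
      nnDist[i2] <- pmin(nnDist[i2], agg2)
      withNN <- is.finite(nnDist)
      rAttach <- 2 * tapply(nnDist[withNN], compOfCell[withNN], max)
    } else {
      rAttach <- numeric()
    }
    for (iter in 1:8) {
      a1 <- compOfCell[e[, 1]]
      a2 <- compOfCell[e[, 2]]
      c1 <- is.na(a1) & !is.na(a2)
      c2 <- is.na(a2) & !is.na(a1)
      if (!any(c1) && !any(c2)) break
      votes <- data.table::data.table(
        cell = c(e[c1, 1], e[c2, 2]),
        comp = c(a2[c1], a1[c2]),
        len = c(eLen[c1], eLen[c2]))
      tallied <- votes[, list(N = .N, minLen = min(len)),
                       by = c("cell", "comp")]
      data.table::setorderv(tallied, c("cell", "N"), c(1L, -1L))
      best <- tallied[!duplicated(tallied$cell), ]
      lim <- rAttach[as.character(best$comp)]
      attach <- best[best$N * 2L > deg[best$cell] &
                     is.finite(lim) & best$minLen <= lim, ]
      if (!nrow(attach)) break
      compOfCell[attach$cell] <- attach$comp
    }
  }

  multip <- cells$multiplicity
  assigned <- which(!is.na(compOfCell))
  cid <- compOfCell[assigned]
  sizes <- tapply(multip[assigned], cid, sum)
  wx <- tapply(cells$x[assigned] * multip[assigned], cid, sum) / sizes
  wy <- tapply(cells$y[assigned] * multip[assigned], cid, sum) / sizes
  # boundary contact judged on core cells only: the attached fringe has
  # cells stretching into empty space, which says nothing about truncation
  coreTouch <- tapply(cells$touchesBoundary[coreCell] & isCore[coreCell],
                      compOfCell[coreCell], any)
  touch <- coreTouch[names(sizes)]

  bigEnough <- sizes >= M
  nBelow <- sum(!bigEnough)
  onEdge <- touch & bigEnough
  keep <- if (excludeBoundary) bigEnough & !touch else bigEnough
  nBoundary <- if (excludeBoundary) sum(onEdge) else 0L

  ids <- as.integer(names(sizes))[keep]
  if (!length(ids)) return(emptySet(as.integer(nBoundary),
                                    as.integer(nBelow)))

  ord <- order(-sizes[keep])
  clusters <- data.frame(
    clusterId = seq_along(ids),
    roiId = tess@roiId,
    nLoc = as.integer(sizes[keep][ord]),
    centroidX = as.numeric(wx[keep][ord]),
    centroidY = as.numeric(wy[keep][ord]),
    touchesBoundary = as.logical(touch[keep][ord])
  )
  finalOf <- setNames(rep(NA_integer_, comp$no), as.character(seq_len(comp$no)))
  finalOf[as.character(ids[ord])] <- seq_along(ids)
  clusterOfCell <- rep(NA_integer_, nCell)
  clusterOfCell[assigned] <- finalOf[as.character(cid)]

  memberCluster <- clusterOfCell[tess@assignment]
  membership <- data.frame(locId = tess@locId, clusterId = memberCluster)
  membership <- membership[!is.na(membership$clusterId), , drop = FALSE]
  rownames(membership) <- NULL

  new("EvClusterSet", roiId = tess@roiId, clusters = clusters,
      membership = membership, nBoundaryExcluded = as.integer(nBoundary),
      nBelowMin = as.integer(nBelow))
}

#' Detect vesicle clusters in one ROI
#'
#' Runs the full per-ROI detection chain: [tessellate()],
#' [thresholdDensity()] with the configured `alpha`, and
#' [extractClusters()] with the configured `M` and boundary handling.
#'
#' @param roi an [SmlmRoi-class].
#' @param config an [AssayConfig-class].
#' @return An [EvClusterSet-class].
#' @export
clusterRoi <- function(roi, config) {
  stopifnot(is(config, "AssayConfig"))
  tess <- tessellate(roi)
  retained <- if (nrow(tess@cells)) thresholdDensity(tess, config@alpha)
              else integer()
  extractClusters(tess, retained, M = config@M,
                  excludeBoundary = config@excludeBoundaryClusters)
}
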