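# Independent brute-force Voronoi oracle: builds each cell by clipping the
# ROI rectangle against the perpendicular-bisector half-planes of ALL other
# points (no Delaunay involved), tracking which neighbour produced each
# polygon edge. Quadratic and only usable at small n, which is the point:
# it shares no code path with the package's triangulation-based
# implementation.
oracleVoronoi <- function(x, y, w, h) {
  n <- length(x)
  areas <- numeric(n)
  touches <- logical(n)
  adj <- matrix(FALSE, n, n)
  lenTol <- 1e-10 * max(w, h)
  for (i in seq_len(n)) {
    px <- c(0, w, w, 0)
    py <- c(0, 0, h, h)
    lab <- rep(-1L, 4)
    for (j in seq_len(n)[-i]) {
      dx <- x[j] - x[i]; dy <- y[j] - y[i]
      mx <- (x[i] + x[j]) / 2; my <- (y[i] + y[j]) / 2
      f <- (px - mx) * dx + (py - my) * dy
      nx <- ny <- numeric(0); nl <- integer(0)
      nv <- length(px)
      for (k in seq_len(nv)) {
        k2 <- if (k == nv) 1L else k + 1L
        in1 <- f[k] <= 0; in2 <- f[k2] <= 0
        if (in1) { nx <- c(nx, px[k]); ny <- c(ny, py[k]); nl <- c(nl, lab[k]) }
        if (in1 != in2) {
          t <- f[k] / (f[k] - f[k2])
          nx <- c(nx, px[k] + t * (px[k2] - px[k]))
          ny <- c(ny, py[k] + t * (py[k2] - py[k]))
          nl <- c(nl, if (in1) j else lab[k])
        }
      }
      px <- nx; py <- ny; lab <- nl
      if (length(px) < 3) break
    }
    nv <- length(px)
    if (nv >= 3) {
      k2 <- c(seq_len(nv)[-1], 1L)
      areas[i] <- 0.5 * abs(sum(px * py[k2] - px[k2] * py))
      elen <- sqrt((px[k2] - px)^2 + (py[k2] - py)^2)
      touches[i] <- any(lab == -1L & elen > lenTol)
      for (j in unique(lab[lab > 0 & elen > lenTol])) adj[i, j] <- TRUE
    }
  }
  list(areas = areas, touches = touches, adj = adj & t(adj))
}

# edge matrix -> canonical sorted pair strings, for set comparison
edgeKey <- function(e) {
  if (!nrow(e)) return(character())
  sort(paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2])))
}

# Greedy one-to-one matching of detected clusters to true vesicles by
# majority vote over the truth table. Returns per-cluster majority evId
# (-1 = background) and the matched-pair count.
matchClustersToTruth <- function(clusterSet, truth) {
  mem <- clusterMembership(clusterSet)
  if (!nrow(mem)) {
    return(list(majority = integer(), purity = numeric(), nMatched = 0L))
  }
  mem$evId <- truth$evId[match(mem$locId, truth$locId)]
  bycl <- split(mem$evId, mem$clusterId)
  majority <- vapply(bycl, function(v) {
    t <- sort(table(v), decreasing = TRUE)
    as.integer(names(t)[1])
  }, integer(1))
  purity <- vapply(bycl, function(v) {
    max(table(v)) / length(v)
  }, numeric(1))
  matched <- majority[majority != -1L]
  list(majority = majority, purity = purity,
       nMatched = length(unique(matched)))
}

# planted well-separated vesicles: fixed diameters/copies, grid centres
plantedCaptured <- function(nRoi, evPerRoi = 5L, diameterNm = 80,
                            copies = 12L, roiSizeNm = 50000, seed = 99) {
  set.seed(seed)
  gx <- c(0.25, 0.75, 0.5, 0.25, 0.75)[seq_len(evPerRoi)] * roiSizeNm
  gy <- c(0.25, 0.25, 0.5, 0.75, 0.75)[seq_len(evPerRoi)] * roiSizeNm
  n <- nRoi * evPerRoi
  df <- data.frame(
    evId = seq_len(n),
    diameterNm = diameterNm,
    MmCD9 = 0L, MmCD63 = 0L, MmCD81 = copies, HsCD81 = 0L,
    tracerPositive = FALSE,
    roi = rep(seq_len(nRoi), each = evPerRoi),
    cx = rep(gx, nRoi) + runif(n, -2000, 2000),
    cy = rep(gy, nRoi) + runif(n, -2000, 2000)
  )
  df
}
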