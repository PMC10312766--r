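# Voronoi tessellation and density clustering: geometry against an
# independent brute-force oracle, partition conservation, threshold
# monotonicity, the minimum-cluster-size guarantee, and recovery of
# planted vesicles.

mousePanel <- c("MmCD9", "MmCD63", "MmCD81")

test_that("four symmetric points split a square ROI into quarter cells", {
  roi <- smlmRoi("sym", 1000, 1000,
                 data.frame(x = c(250, 750, 250, 750),
                            y = c(250, 250, 750, 750)))
  tess <- tessellate(roi)
  expect_equal(cellInfo(tess)$area, rep(250000, 4), tolerance = 1e-9)
  expect_true(all(cellInfo(tess)$touchesBoundary))
  # diagonal neighbours meet only at the centre point: not adjacent
  keys <- edgeKey(cellAdjacency(tess))
  expect_setequal(keys, c("1 2", "1 3", "2 4", "3 4"))
})

test_that("cell areas partition the ROI exactly", {
  for (seed in 1:3) {
    set.seed(seed)
    n <- c(50, 500, 3000)[seed]
    w <- 20000; h <- 12000
    roi <- smlmRoi(paste0("p", seed), w, h,
                   data.frame(x = runif(n, 0, w), y = runif(n, 0, h)))
    tess <- tessellate(roi)
    expect_true(all(cellInfo(tess)$area > 0))
    expect_lt(abs(sum(cellInfo(tess)$area) - w * h) / (w * h), 1e-6)
  }
})

test_that("areas, adjacency and boundary flags match the brute-force oracle", {
  for (seed in c(11, 12)) {
    set.seed(seed)
    n <- 80
    w <- 5000; h <- 4000
    x <- runif(n, 0, w); y <- runif(n, 0, h)
    roi <- smlmRoi("o", w, h, data.frame(x = x, y = y))
    tess <- tessellate(roi)
    # oracle fed in cell order (tessellation deduplicates by sorting)
    ci <- cellInfo(tess)
    oracle <- oracleVoronoi(ci$x, ci$y, w, h)
    expect_equal(ci$area, oracle$areas, tolerance = 1e-8)
    expect_identical(ci$touchesBoundary, oracle$touches)
    oracleEdges <- which(oracle$adj & upper.tri(oracle$adj), arr.ind = TRUE)
    expect_setequal(edgeKey(cellAdjacency(tess)),
                    edgeKey(oracleEdges[, c(2, 1), drop = FALSE]))
  }
})

test_that("degenerate geometries return an empty tessellation with warning", {
  roi0 <- smlmRoi("e", 100, 100)
  expect_warning(t0 <- tessellate(roi0), "no localizations")
  expect_identical(nrow(cellInfo(t0)), 0L)

  roi3 <- smlmRoi("few", 100, 100, data.frame(x = c(1, 2, 3), y = c(1, 2, 1)))
  expect_warning(t3 <- tessellate(roi3), "fewer than 4")
  expect_identical(nrow(cellInfo(t3)), 0L)

  roiLine <- smlmRoi("line", 100, 100,
                     data.frame(x = c(10, 20, 30, 40), y = c(10, 20, 30, 40)))
  expect_warning(tl <- tessellate(roiLine), "collinear")
  expect_identical(nrow(cellInfo(tl)), 0L)
})

test_that("duplicate coordinates are merged with multiplicity", {
  set.seed(3)
  base <- data.frame(x = runif(20, 0, 1000), y = runif(20, 0, 1000))
  dup <- rbind(base, base[1:5, ])
  roi <- smlmRoi("dup", 1000, 1000, dup)
  tess <- tessellate(roi)
  expect_identical(nrow(cellInfo(tess)), 20L)
  expect_identical(sum(cellInfo(tess)$multiplicity), 25L)
  expect_identical(length(tess@assignment), 25L)
})

test_that("density threshold is monotone and vacuous at large alpha", {
  set.seed(7)
  n <- 800
  roi <- smlmRoi("thr", 10000, 10000,
                 data.frame(x = runif(n, 0, 10000), y = runif(n, 0, 10000)))
  tess <- tessellate(roi)
  expect_identical(sort(thresholdDensity(tess, 1e9)),
                   cellInfo(tess)$cellId)
  r3 <- thresholdDensity(tess, 0.3)
  r5 <- thresholdDensity(tess, 0.5)
  expect_true(all(r3 %in% r5))
  # uniform Poisson background at alpha = 0.5 retains under half the points
  expect_lt(length(r5) / n, 0.5)
  expect_error(thresholdDensity(tess, 0), "alpha")
})

test_that("components below M localizations are never reported", {
  # retained set constructed to be one connected 39-cell component:
  # rejected at M = 40, reported at M = 39
  set.seed(42)
  blob <- data.frame(x = 25000 + rnorm(39, 0, 30),
                     y = 25000 + rnorm(39, 0, 30))
  bg <- data.frame(x = runif(300, 0, 50000), y = runif(300, 0, 50000))
  roi <- smlmRoi("blob", 50000, 50000, rbind(blob, bg))
  tess <- tessellate(roi)
  cells <- cellInfo(tess)
  ret <- cells$cellId[abs(cells$x - 25000) < 500 &
                      abs(cells$y - 25000) < 500]
  expect_identical(length(ret), 39L)
  cs40 <- extractClusters(tess, ret, M = 40L, closure = FALSE)
  expect_identical(nrow(clusterTable(cs40)), 0L)
  expect_gt(cs40@nBelowMin, 0L)
  cs39 <- extractClusters(tess, ret, M = 39L, closure = FALSE)
  expect_identical(nrow(clusterTable(cs39)), 1L)
  expect_identical(clusterTable(cs39)$nLoc, 39L)
  # empty retained set is fine
  expect_identical(nrow(clusterTable(extractClusters(tess, integer(), 40L))),
                   0L)
  expect_error(extractClusters(tess, c(1L, 10000L), 40L), "subset")
})

test_that("no reported cluster falls below M and members are disjoint", {
  cfg <- simConfig(nEv = 250, fractionPositive = 0.2, nRoi = 1L, seed = 19)
  sim <- simulateAssay(cfg, "MmCD81", mousePanel)
  ac <- assayConfig("MmCD81", mousePanel, volumeRawUl = 1)
  cs <- clusterRoi(sim$rois[[1]], ac)
  expect_true(all(clusterTable(cs)$nLoc >= 40L))
  mem <- clusterMembership(cs)
  expect_false(anyDuplicated(mem$locId) > 0)
  # nLoc equals the membership accounting
  counts <- table(mem$clusterId)
  expect_identical(as.integer(counts[as.character(clusterTable(cs)$clusterId)]),
                   clusterTable(cs)$nLoc)
})

test_that("clustering is invariant to row order of the input table", {
  cfg <- simConfig(nEv = 150, fractionPositive = 0.2, nRoi = 1L, seed = 23)
  sim <- simulateAssay(cfg, "MmCD81", mousePanel)
  roi <- sim$rois[[1]]
  ac <- assayConfig("MmCD81", mousePanel, volumeRawUl = 1)
  cs1 <- clusterRoi(roi, ac)

  set.seed(1)
  loc <- localizations(roi)[sample.int(nLocalizations(roi)), ]
  roiShuffled <- smlmRoi(roi@roiId, roi@widthNm, roi@heightNm, loc)
  cs2 <- clusterRoi(roiShuffled, ac)

  sets1 <- lapply(split(clusterMembership(cs1)$locId,
                        clusterMembership(cs1)$clusterId), sort)
  sets2 <- lapply(split(clusterMembership(cs2)$locId,
                        clusterMembership(cs2)$clusterId), sort)
  expect_setequal(unname(vapply(sets1, paste, character(1), collapse = ",")),
                  unname(vapply(sets2, paste, character(1), collapse = ",")))
})

test_that("well-separated planted vesicles are recovered with F1 >= 0.99", {
  cfg <- simConfig(nEv = 25, fractionPositive = 0, nRoi = 5L,
                   backgroundDensity = 0.05, labelProb = 1, seed = 101)
  captured <- plantedCaptured(nRoi = 5, copies = 20L, seed = 101)
  sim <- simulateLocalizations(captured, "MmCD81", cfg)
  ac <- assayConfig("MmCD81", "MmCD81", volumeRawUl = 1)
  tp <- 0; fp <- 0; fn <- 0
  for (i in seq_len(5)) {
    roi <- sim$rois[[i]]
    cs <- clusterRoi(roi, ac)
    ct <- clusterTable(cs)
    truthRoi <- sim$truth[sim$truth$roiId == roi@roiId, ]
    m <- matchClustersToTruth(cs, truthRoi)
    expect_identical(nrow(ct), 5L)
    tp <- tp + m$nMatched
    fp <- fp + nrow(ct) - m$nMatched
    fn <- fn + 5 - m$nMatched
    # centroids land within 20 nm of the planted centres
    planted <- captured[captured$roi == i, ]
    for (k in seq_len(nrow(ct))) {
      dmin <- min(sqrt((planted$cx - ct$centroidX[k])^2 +
                       (planted$cy - ct$centroidY[k])^2))
      expect_lt(dmin, 20)
    }
    # membership F1 against the truth table
    mem <- clusterMembership(cs)
    mem$evId <- truthRoi$evId[match(mem$locId, truthRoi$locId)]
    nEvLoc <- sum(truthRoi$evId > 0)
    prec <- sum(mem$evId > 0) / nrow(mem)
    rec <- sum(mem$evId > 0) / nEvLoc
    f1 <- 2 * prec * rec / (prec + rec)
    expect_gte(f1, 0.99)
  }
  expect_identical(fp + fn, 0)
})
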