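# Forward simulator: population composition, capture law, blinking model,
# background process, determinism, and ground-truth bookkeeping.

mousePanel <- c("MmCD9", "MmCD63", "MmCD81")

test_that("tracer-positive fraction follows the configured probability", {
  pop0 <- simulateEvPopulation(simConfig(nEv = 1000, fractionPositive = 0,
                                         seed = 4))
  expect_identical(sum(pop0$tracerPositive), 0L)
  expect_true(all(pop0$HsCD81 == 0))

  pop1 <- simulateEvPopulation(simConfig(nEv = 1000, fractionPositive = 1,
                                         seed = 4))
  expect_identical(sum(pop1$tracerPositive), 1000L)
  expect_true(all(pop1$HsCD81 >= 1))

  # binomial sampling bound: within 3 sd of f at n = 10000
  pop <- simulateEvPopulation(simConfig(nEv = 10000, fractionPositive = 0.15,
                                        seed = 21))
  fHat <- mean(pop$tracerPositive)
  expect_lt(abs(fHat - 0.15), 3 * sqrt(0.15 * 0.85 / 10000))
})

test_that("tracer positivity coincides exactly with HsCD81 presence", {
  pop <- simulateEvPopulation(simConfig(nEv = 5000, fractionPositive = 0.3,
                                        seed = 8))
  expect_identical(pop$tracerPositive, pop$HsCD81 >= 1)
  expect_true(all(pop$diameterNm > 0))
  for (sp in evMarkerSpecies()) {
    expect_true(all(pop[[sp]] >= 0 & pop[[sp]] == round(pop[[sp]])))
  }
})

test_that("copy numbers scale with membrane area", {
  cfg <- simConfig(nEv = 20000, fractionPositive = 0, diameterLogSd = 0.5,
                   seed = 13)
  pop <- simulateEvPopulation(cfg)
  small <- pop$diameterNm < 60
  large <- pop$diameterNm > 110
  ratio <- mean(pop$MmCD9[large]) / mean(pop$MmCD9[small])
  expected <- mean((pop$diameterNm[large] / 80)^2) /
    mean((pop$diameterNm[small] / 80)^2)
  expect_lt(abs(ratio / expected - 1), 0.15)
})

test_that("capture follows 1 - (1 - p)^k", {
  # EVs without the capture epitope are never captured specifically
  cfg <- simConfig(nEv = 2000, fractionPositive = 0, seed = 31)
  pop <- simulateEvPopulation(cfg)
  cap <- simulateCapture(pop, "HsCD81", cfg)
  expect_identical(nrow(cap), 0L)

  # p = 1 with k >= 1 copies: always captured
  cfg1 <- simConfig(nEv = 500, fractionPositive = 1, captureProbPerCopy = 1,
                    seed = 32)
  pop1 <- simulateEvPopulation(cfg1)
  cap1 <- simulateCapture(pop1, "HsCD81", cfg1)
  expect_identical(nrow(cap1), 500L)

  # closed form vs Monte-Carlo at p = 0.2, k = 5
  n <- 1e5
  cfgMc <- simConfig(nEv = n, fractionPositive = 0, captureProbPerCopy = 0.2,
                     seed = 33)
  popMc <- data.frame(evId = seq_len(n), diameterNm = 80,
                      MmCD9 = 0L, MmCD63 = 0L, MmCD81 = 5L, HsCD81 = 0L,
                      tracerPositive = FALSE)
  capMc <- simulateCapture(popMc, "MmCD81", cfgMc)
  pTrue <- 1 - 0.8^5
  se <- sqrt(pTrue * (1 - pTrue) / n)
  expect_lt(abs(nrow(capMc) / n - pTrue), 3 * se)

  expect_error(simulateCapture(popMc, "CD63", cfgMc), "unknown capture")
})

test_that("blink counts are geometric with the configured mean", {
  cfg <- simConfig(nEv = 1, fractionPositive = 0, nRoi = 1L,
                   backgroundDensity = 0, labelProb = 0.7, seed = 41)
  captured <- data.frame(evId = 1L, diameterNm = 80,
                         MmCD9 = 15000L, MmCD63 = 0L, MmCD81 = 0L,
                         HsCD81 = 0L, tracerPositive = FALSE,
                         roi = 1L, cx = 25000, cy = 25000)
  sim <- simulateLocalizations(captured, "MmCD9", cfg)
  ab <- sim$antibodies
  expect_gt(nrow(ab), 1e4)
  expect_true(all(ab$nBlinks >= 1))
  expect_lt(abs(mean(ab$nBlinks) / 14 - 1), 0.02)
})

test_that("background is a spatial Poisson process of the right intensity", {
  cfg <- simConfig(nEv = 1, fractionPositive = 0, nRoi = 1L,
                   backgroundDensity = 1, seed = 55)
  empty <- data.frame(evId = integer(), diameterNm = numeric(),
                      MmCD9 = integer(), MmCD63 = integer(),
                      MmCD81 = integer(), HsCD81 = integer(),
                      tracerPositive = logical(), roi = integer(),
                      cx = numeric(), cy = numeric())
  sim <- simulateLocalizations(empty, mousePanel, cfg)
  n <- nLocalizations(sim$rois[[1]])
  expect_lt(abs(n - 2500), 3 * sqrt(2500))
  expect_true(all(sim$truth$evId == -1))
})

test_that("nothing is emitted when labeling and background are off", {
  cfg <- simConfig(nEv = 50, fractionPositive = 0, nRoi = 2L,
                   labelProb = 0, backgroundDensity = 0, seed = 60)
  sim <- simulateAssay(cfg, "MmCD81", mousePanel)
  expect_true(all(vapply(sim$rois, nLocalizations, integer(1)) == 0L))
  expect_identical(nrow(sim$truth), 0L)
})

test_that("stain panel must be non-empty and known", {
  cfg <- simConfig(nEv = 10, fractionPositive = 0, nRoi = 1L, seed = 2)
  pop <- simulateEvPopulation(cfg)
  cap <- simulateCapture(pop, "MmCD81", cfg)
  expect_error(simulateLocalizations(cap, character(), cfg), "empty")
  expect_error(simulateLocalizations(cap, "CD99", cfg), "unknown species")
})

test_that("identical configurations reproduce byte-identical tables", {
  cfg <- simConfig(nEv = 120, fractionPositive = 0.2, nRoi = 3L, seed = 77)
  a <- simulateAssay(cfg, "MmCD81", mousePanel)
  b <- simulateAssay(cfg, "MmCD81", mousePanel)
  expect_identical(lapply(a$rois, localizations),
                   lapply(b$rois, localizations))
  expect_identical(a$truth, b$truth)

  cfg2 <- simConfig(nEv = 120, fractionPositive = 0.2, nRoi = 3L, seed = 78)
  c2 <- simulateAssay(cfg2, "MmCD81", mousePanel)
  expect_false(identical(localizations(a$rois[[1]]),
                         localizations(c2$rois[[1]])))
})

test_that("every localization is attributed to exactly one EV or background", {
  cfg <- simConfig(nEv = 200, fractionPositive = 0.2, nRoi = 2L, seed = 91)
  sim <- simulateAssay(cfg, "MmCD81", mousePanel)
  for (i in seq_along(sim$rois)) {
    roi <- sim$rois[[i]]
    tr <- sim$truth[sim$truth$roiId == roi@roiId, ]
    expect_identical(sort(tr$locId), sort(localizations(roi)$id))
    expect_false(anyDuplicated(tr$locId) > 0)
    expect_true(all(tr$evId %in% c(-1L, sim$captured$evId)))
  }
})

test_that("mean bound antibodies per EV tracks labeling probability", {
  cfg <- simConfig(nEv = 600, fractionPositive = 0, nRoi = 1L,
                   backgroundDensity = 0, labelProb = 0.6, seed = 17)
  pop <- simulateEvPopulation(cfg)
  cap <- simulateCapture(pop, "MmCD81", cfg)
  sim <- simulateLocalizations(cap, mousePanel, cfg)
  nAb <- nrow(sim$antibodies)
  expected <- 0.6 * sum(cap$MmCD9 + cap$MmCD63 + cap$MmCD81)
  expect_lt(abs(nAb / expected - 1), 0.05)
})

test_that("invalid simulation configurations are rejected", {
  expect_error(simConfig(nEv = 0, fractionPositive = 0.5), "invalid")
  expect_error(simConfig(nEv = 10, fractionPositive = 1.5), "invalid")
  expect_error(simConfig(nEv = 10, fractionPositive = 0.5,
                         captureProbPerCopy = 0), "invalid")
  expect_error(simConfig(nEv = 10, fractionPositive = 0.5,
                         roiWidthNm = -5), "invalid")
})
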