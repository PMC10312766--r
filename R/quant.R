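# Volume-normalized counting and the paired capture/stain contribution
# estimators. Cohort fractions are ratios of cohort mean EV/uL values (not
# means of per-ROI ratios), matching the arithmetic used to derive the
# published percentages from per-condition means; uncertainty comes from a
# seeded nonparametric bootstrap over ROIs.

#' Count detected vesicles per ROI, normalized to biofluid volume
#'
#' @param clusterSets list of [EvClusterSet-class] objects (one per ROI).
#' @param config an [AssayConfig-class]; supplies `volume_raw_ul`.
#' @return data.frame with columns `roiId`, `nEv`, `evPerUl`.
#' @examples
#' # 202 clusters from 1 uL of plasma -> 202 EV/uL
#' @export
countRois <- function(clusterSets, config) {
  stopifnot(is(config, "AssayConfig"))
  if (config@volumeRawUl <= 0)
    stop("volume_raw_ul must be > 0", call. = FALSE)
  data.frame(
    roiId = vapply(clusterSets, function(s) s@roiId, character(1)),
    nEv = vapply(clusterSets, function(s) nrow(s@clusters), integer(1)),
    evPerUl = vapply(clusterSets, function(s) nrow(s@clusters), integer(1)) /
      config@volumeRawUl
  )
}

#' Cohort statistics of EV/uL counts
#'
#' Mean, median, standard error of the mean (sample sd over sqrt(n)) and
#' coefficient of variation (sample sd over mean) of per-ROI EV/uL values.
#'
#' @param counts numeric vector of per-ROI EV/uL values, or a data.frame
#'   from [countRois()] (its `evPerUl` column is used).
#' @param condition optional condition label carried into the output.
#' @return One-row data.frame: `condition`, `nRoi`, `mean`, `median`,
#'   `sem`, `cv`. With a single ROI, `sem` and `cv` are `NA` with a
#'   warning; with mean zero, `cv` is `NA` with a warning.
#' @examples
#' summarizeCohort(c(10, 12, 8, 10))
#' @export
summarizeCohort <- function(counts, condition = NA_character_) {
  if (is.data.frame(counts)) counts <- counts$evPerUl
  counts <- as.numeric(counts)
  if (!length(counts)) stop("empty cohort", call. = FALSE)
  n <- length(counts)
  m <- mean(counts)
  if (n < 2) {
    warning("sem and cv undefined for a single ROI")
    s <- NA_real_
  } else {
    s <- sd(counts)
  }
  cv <- if (is.na(s)) NA_real_ else if (m == 0) {
    warning("cv undefined for zero mean")
    NA_real_
  } else s / m
  data.frame(condition = condition, nRoi = n, mean = m,
             median = median(counts), sem = s / sqrt(n), cv = cv)
}

#' ROI count implied by printed summary statistics
#'
#' The identity `n = (sd / sem)^2 = (cv * mean / sem)^2` recovers the
#' number of replicate ROIs from a cohort's printed mean, SEM and CV — an
#' internal-consistency check on published summary tables.
#'
#' @param mean,sem,cv cohort summary statistics.
#' @return Implied replicate count (real-valued).
#' @export
impliedRoiCount <- function(mean, sem, cv) {
  if (any(sem <= 0)) stop("sem must be > 0", call. = FALSE)
  (cv * mean / sem)^2
}

.ratioOfMeans <- function(num, denom, what) {
  mNum <- mean(num)
  mDen <- mean(denom)
  if (mDen == 0)
    stop("undefined fraction: ", what, " denominator cohort mean is 0",
         call. = FALSE)
  mNum / mDen
}

#' Stain-based contribution fraction
#'
#' Ratio of cohort mean EV/uL of reference-captured vesicles staining
#' positively for the tracer to the cohort mean of reference-captured
#' vesicles staining for the full marker panel. Accepts cohort summaries
#' (from [summarizeCohort()]), per-ROI count vectors, or scalar means.
#'
#' @param test numerator cohort: tracer stain.
#' @param denom denominator cohort: panel stain.
#' @return The fraction (numerator mean / denominator mean).
#' @examples
#' contributionStain(23.0, 202)  # ~0.114
#' @export
contributionStain <- function(test, denom) {
  .contribution(test, denom, "stain")
}

#' Capture-based contribution fraction
#'
#' Ratio of cohort mean EV/uL captured on the tracer-specific antibody to
#' the cohort mean captured on the reference-species antibody, both stained
#' with the full marker panel. Capture requires only a single tracer
#' molecule per vesicle, so this estimator avoids the detected-marker
#' positivity floor of the stain-based estimator.
#'
#' @inheritParams contributionStain
#' @return The fraction.
#' @examples
#' contributionCapture(35.4, 202)  # ~0.175
#' @export
contributionCapture <- function(test, denom) {
  .contribution(test, denom, "capture")
}

.contribution <- function(test, denom, what) {
  toCounts <- function(x) {
    if (is.data.frame(x)) {
      if ("evPerUl" %in% names(x)) return(x$evPerUl)
      if ("mean" %in% names(x)) return(x$mean)
      stop("cannot interpret cohort input", call. = FALSE)
    }
    as.numeric(x)
  }
  .ratioOfMeans(toCounts(test), toCounts(denom), what)
}

#' Contribution estimate with background correction and bootstrap CI
#'
#' Computes a contribution fraction as the ratio of cohort mean EV/uL
#' values, the same ratio in a control cohort (assay background), and the
#' background-corrected fraction `max(0, f - f_background)`. A seeded
#' nonparametric bootstrap over ROIs (resampling each cohort's ROIs with
#' replacement) yields a percentile 95% interval for the corrected
#' fraction.
#'
#' @param testNum,testDenom per-ROI EV/uL vectors of the test cohort's
#'   numerator and denominator conditions.
#' @param ctrlNum,ctrlDenom per-ROI EV/uL vectors of the control cohort
#'   processed with the identical estimator, or `NULL` when no control was
#'   run (background then `NA`, with a warning).
#' @param nBoot bootstrap resamples (default 2000).
#' @param seed bootstrap seed.
#' @return One-row data.frame: `f`, `fBackground`, `fCorrected`, `ciLow`,
#'   `ciHigh`, `nRoiTest`, `nRoiCtrl`.
#' @export
estimateContribution <- function(testNum, testDenom,
                                 ctrlNum = NULL, ctrlDenom = NULL,
                                 nBoot = 2000L, seed = 1L) {
  testNum <- as.numeric(testNum)
  testDenom <- as.numeric(testDenom)
  f <- .ratioOfMeans(testNum, testDenom, "test")
  haveCtrl <- !is.null(ctrlNum) && !is.null(ctrlDenom)
  fBg <- if (haveCtrl) {
    .ratioOfMeans(as.numeric(ctrlNum), as.numeric(ctrlDenom), "control")
  } else {
    warning("no control cohort: background not subtracted")
    NA_real_
  }
  corrected <- if (haveCtrl) max(0, f - fBg) else f

  set.seed(deriveSeed(seed, 17L))
  stat <- function() {
    fr <- mean(sample(testNum, replace = TRUE)) /
      mean(sample(testDenom, replace = TRUE))
    if (haveCtrl) {
      bg <- mean(sample(as.numeric(ctrlNum), replace = TRUE)) /
        mean(sample(as.numeric(ctrlDenom), replace = TRUE))
      max(0, fr - bg)
    } else {
      fr
    }
  }
  boots <- vapply(seq_len(nBoot), function(i) stat(), numeric(1))
  boots <- boots[is.finite(boots)]
  ci <- quantile(boots, c(0.025, 0.975), names = FALSE)
  data.frame(f = f, fBackground = fBg, fCorrected = corrected,
             ciLow = ci[1], ciHigh = ci[2],
             nRoiTest = length(testNum),
             nRoiCtrl = if (haveCtrl) length(as.numeric(ctrlNum)) else 0L)
}

#' Compare groups after log transformation
#'
#' Per-vesicle diameters and marker counts are right-skewed; groups are
#' compared on the natural-log scale. Two groups: Welch two-sample t-test.
#' More than two: one-way analysis of variance. Non-positive values are
#' excluded with a message reporting their count.
#'
#' @param ... two or more numeric vectors, or a single list of them.
#' @return list with `pValue`, `statistic`, `method`, `nExcluded`.
#' @export
compareLog <- function(...) {
  groups <- list(...)
  if (length(groups) == 1 && is.list(groups[[1]])) groups <- groups[[1]]
  if (length(groups) < 2)
    stop("need at least two groups", call. = FALSE)
  nExcluded <- 0L
  groups <- lapply(groups, function(g) {
    g <- as.numeric(g)
    bad <- !is.finite(g) | g <= 0
    nExcluded <<- nExcluded + sum(bad)
    log(g[!bad])
  })
  if (nExcluded)
    message(nExcluded, " non-positive value(s) excluded before ",
            "log transformation")
  if (any(lengths(groups) < 2))
    stop("every group needs at least 2 positive values", call. = FALSE)
  if (length(groups) == 2) {
    ht <- t.test(groups[[1]], groups[[2]])
    list(pValue = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "Welch two-sample t-test on log values",
         nExcluded = nExcluded)
  } else {
    vals <- unlist(groups)
    grp <- factor(rep.int(seq_along(groups), lengths(groups)))
    ht <- oneway.test(vals ~ grp, var.equal = TRUE)
    list(pValue = unname(ht$p.value), statistic = unname(ht$statistic),
         method = "one-way ANOVA on log values", nExcluded = nExcluded)
  }
}
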