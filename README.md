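# smlmEV

Single-vesicle detection and quantification from single-molecule
localization microscopy (SMLM) data, for researchers mapping which cell
types contribute to the extracellular-vesicle (EV) populations of blood
plasma, CSF and other biofluids.

## The problem and the method

In a capture/stain qSMLM assay, raw biofluid is incubated on a coverslip
functionalized with a capture antibody (e.g. anti-mouse-CD81 to bind all
mouse exosomes, or anti-human-CD81 to bind only exosomes carrying an
HsCD81 tracer expressed by one cell type). Captured vesicles are stained
with fluorophore-labeled antibodies against exosomal tetraspanins and
imaged by dSTORM. The result, per region of interest (ROI), is a table of
localizations — one fitted position per fluorophore blink.

`smlmEV` implements the downstream analysis chain:

1. **Detection** — Voronoi tessellation of each ROI's localization cloud.
   A localization is retained when its first-rank local density (count over
   area of its cell plus edge-sharing neighbours) is at least `1/α` times
   the ROI-average density (α = 0.5). Connected components of retained
   cells, closed by a majority-vote fringe reattachment, are candidate
   vesicles; only clusters with at least *M* = 40 localizations are
   reported, and clusters touching the ROI edge are excluded.
2. **Per-vesicle metrics** — detected tetraspanins
   *TSPAN/EV* = *n*<sub>loc</sub> / *L*, with *L* = 14 localizations per
   single fluorescent antibody (blinking calibration), so the 40-localization
   floor corresponds to ~3 detected marker proteins. Diameter from the
   projected-sphere second moment:
   *D̂* = 2 · √(1.5 · max(0, m₂ − 2σ²)), where m₂ is the mean squared
   radial distance of member localizations and σ the localization
   precision.
3. **Counting** — detected vesicles per ROI, normalized to the incubated
   raw-biofluid volume (EV/µL), with cohort mean/median/SEM/CV.
4. **Contribution estimators** — the fraction of a biofluid's exosomes
   contributed by a tracer-expressing cell type, either *stain-based*
   (reference capture, tracer stain vs panel stain) or *capture-based*
   (tracer capture vs reference capture, panel stain in both), computed as
   ratios of cohort mean EV/µL, with control-animal background
   subtraction and a seeded bootstrap 95% interval.
5. **Forward simulator** — log-normal vesicle diameters, area-scaled
   Poisson tetraspanin copy numbers, per-copy capture, antibody labeling,
   geometric blink counts (mean *L*), Gaussian localization noise and
   uniform background, with a full truth table — so every stage above is
   validated by parameter recovery.

## Worked example

Simulate a plasma-like experiment (1000 vesicles, 15% tracer-positive,
5 ROIs per capture condition), run the pipeline, and estimate the
tracer-positive contribution:

```r
library(smlmEV)
mousePanel <- c("MmCD9", "MmCD63", "MmCD81")

cfgRef <- simConfig(nEv = 1000, fractionPositive = 0.15, nRoi = 5L, seed = 1)
cfgTrc <- simConfig(nEv = 1000, fractionPositive = 0.15, nRoi = 5L, seed = 2)
simRef <- simulateAssay(cfgRef, "MmCD81", mousePanel)  # reference capture
simTrc <- simulateAssay(cfgTrc, "HsCD81", mousePanel)  # tracer capture

ac  <- assayConfig("MmCD81", mousePanel, volumeRawUl = 1)
ref <- quantifyRois(simRef$rois, ac)
trc <- quantifyRois(simTrc$rois, ac)
ref$summary
#>   condition nRoi  mean median      sem         cv
#> 1      <NA>    5 147.8    145 4.091455 0.06189966

estimateContribution(trc$counts$evPerUl, ref$counts$evPerUl,
                     ctrlNum = rep(0, 5), ctrlDenom = ref$counts$evPerUl,
                     nBoot = 1000, seed = 1)
#>           f fBackground fCorrected     ciLow    ciHigh nRoiTest nRoiCtrl
#> 1 0.1786198           0  0.1786198 0.1609815 0.1972083        5        5
```

The reference capture detects ~148 EV/µL per ROI, and the capture-based
estimator returns 0.179 (95% CI 0.161–0.197) for a planted fraction of
0.15 — the slight upward bias reflects the finite capture efficiency of
the reference antibody relative to the (multi-copy) tracer capture, and
shrinks as the per-copy capture probability rises. At the full 20-ROI
design the estimate lands within ±0.03 of truth (see
`tests/testthat/test-acceptance.R`).

The same estimators applied to the bundled reference cohort summaries
(`referenceCohortSummaries()`) reproduce the headline percentages of the
assay the package models:

```r
100 * contributionStain(23.0, 202)    # 11.4  (% of plasma exosomes, stain-based)
100 * contributionCapture(35.4, 202)  # 17.5  (capture-based)
100 * contributionCapture(0.8, 517)   # 0.15  (control-animal background)
```

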