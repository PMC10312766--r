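---
title: "Single-vesicle qSMLM analysis: models, estimators and design choices"
author: "smlmEV"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-vesicle qSMLM analysis: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smlmEV)
```

# The assay and its observables

A capture/stain qSMLM experiment immobilizes extracellular vesicles (EVs)
from a raw biofluid on an antibody-functionalized coverslip, stains them
with fluorophore-labeled anti-tetraspanin antibodies, and images them by
dSTORM. The raw observable per region of interest (ROI) is a table of
localizations: one fitted (x, y) position per fluorophore blink, in nm.
Three facts shape the whole analysis:

* a single bound antibody blinks repeatedly — on average **L = 14
  localizations per antibody** in the calibration this package adopts —
  so localization counts are antibody counts times ~14;
* an EV of diameter ~80 nm carries its epitopes on a spherical surface
  whose orthographic projection spreads localizations over a disk of that
  diameter, broadened by the localization precision σ;
* nonspecific binding adds a sparse, spatially uniform background of
  localizations.

The pipeline detects EVs as localization clusters, converts each cluster
to detected-marker and diameter estimates, counts clusters per ROI
normalized to incubated biofluid volume, and forms ratio estimators of
cell-type contributions between paired capture/stain conditions.

# Detection by Voronoi tessellation

Each ROI is tessellated (compiled Bowyer–Watson Delaunay triangulation;
Voronoi cells are built per localization as the ROI rectangle intersected
with the bisector half-planes of its Delaunay neighbours, which equals
the true Voronoi cell restricted to the rectangle). Cell areas therefore
partition the ROI exactly; the test suite checks conservation to 1e-6
relative error and checks areas, adjacency and boundary flags against an
independent brute-force all-pairs construction.

**Density rule.** A localization is retained when its *first-rank local
density* — the localization count of its cell plus edge-sharing
neighbours, divided by their summed area — is at least `1/alpha` times
the ROI-average density (total localizations / ROI area), with
`alpha = 0.5`: the classic "local density at least twice the average"
criterion. Two alternatives were considered and rejected on parameter
recovery grounds:

* *median cell area*: in realistic data most localizations sit inside
  vesicle clusters, so the ROI median cell area is itself an in-cluster
  area; a relative-to-median cutoff then retains only overlapping-blink
  hot spots and fragments vesicles (recovered recall ~0.3 in
  development-time experiments, diameters collapsing toward σ);
* *raw cell area vs mean*: retains cluster interiors but drops the
  cluster's outermost localizations, whose cells stretch into empty
  background; membership recall saturates near 0.9.

First-rank averaging keeps those fringe cells (their neighbourhood is
dominated by dense cluster cells) while isolated background cells remain
below threshold. The criterion is scale-free: doubling all coordinates
changes nothing.

**Clusters.** Retained cells are grouped into connected components under
shared-edge adjacency (positive-length Voronoi edges only; vertex contact
does not connect — this avoids chaining through degenerate contacts). A
morphological closure then reattaches unretained cells whose strict
majority of Voronoi neighbours already belongs to one cluster, iterated
to a fixed point, but only within an attachment radius of twice the
largest nearest-neighbour spacing inside the cluster core. The radius cap
matters: in sparse background, a lone background point a micrometre from
a dense cluster can have most of its Voronoi neighbours inside the
cluster and would otherwise be absorbed, shifting the centroid and
inflating the second-moment diameter catastrophically (a single point at
distance d adds d²/n to m₂).

Components with fewer than **M = 40 localizations** are discarded — the
assay's positivity floor, equivalent to ~3 detected marker proteins at
L = 14. Clusters whose *core* cells touch the ROI rectangle edge are
excluded from counting by default (truncation bias); the attached fringe
is deliberately ignored for this judgement because fringe cells stretch
into empty space regardless of truncation. Exact coordinate duplicates
are merged before tessellation (duplicate points break the triangulation)
and their multiplicity counts toward cluster sizes.

**Degenerate inputs.** Fewer than four spatially distinct localizations,
or an all-collinear cloud, yields an empty tessellation with a warning.
Near-cocircular point sets (e.g. a perfect grid) may triangulate with
either diagonal; both choices give identical Voronoi cells up to
zero-length edges, which the positive-length adjacency rule removes.

# Per-vesicle metrics

**Detected markers.** `markers = nLoc / L`, kept real-valued; display
rounding only. L defaults to 14 and is a config knob because the blinking
calibration is dye- and buffer-specific.

**Diameter.** For antibodies anchored uniformly on a sphere of radius R,
the projected squared radial distance has mean E[r²] = 2R²/3; isotropic
Gaussian localization noise adds 2σ². The estimator inverts this:

D̂ = 2 · sqrt(1.5 · max(0, m₂ − 2σ²)),

with m₂ the mean squared distance of member localizations from their
centroid, clipped to 0 when the precision correction exceeds the spread.
The estimator is exact for the simulator's forward model (the test suite
recovers an 80 nm shell to ±2 nm from 1e4 localizations and cohort mean
diameters to <5% bias at 500 vesicles); applied to real vesicles it
inherits the sphere assumption and ignores antibody/linker size (~10 nm,
folded into σ). σ comes from the per-localization `sigma` column when
present, else the ROI median, else the configured default (12 nm).
Because blinks of one antibody are correlated (~14 localizations per
anchor), the effective sample size of a cluster is its antibody count,
not its localization count — per-vesicle diameter noise is dominated by
the number of antibodies.

# Counting and contribution estimators

Per-ROI cluster counts are divided by the incubated raw-biofluid volume
(EV/µL); cohorts of ROIs are summarized by mean, median, SEM (sample
sd/√n) and CV (sample sd/mean). The identity n = (cv·mean/sem)² recovers
the replicate count from printed summaries (`impliedRoiCount()`).

Contribution fractions are **ratios of cohort mean EV/µL values**, not
means of per-ROI ratios — matching the arithmetic that derives the
published percentages from per-condition means (e.g. 0.8/517), and
avoiding the instability of per-ROI ratios when numerator counts are
near zero (CSF tracer captures average 0.4 EV/ROI). Background is the
identical ratio in the tracer-negative control animal, subtracted with
clipping at zero; raw and corrected fractions are both reported.
Uncertainty is a seeded nonparametric bootstrap over ROIs (2000
resamples, percentile 95% interval) — the source tables publish only
SEM/CV, so the interval is this package's addition.

The stain-based estimator inherits its positivity from clustering (a
vesicle counts only if its stain yields ≥ M localizations ≈ 3 detected
markers), so it undercounts tracer-positive vesicles with few tracer
copies; the capture-based estimator requires only a single tracer
molecule for capture and is therefore the less-biased headline figure.
Group comparisons of per-vesicle diameters or marker counts use a
natural-log transform (right-skewed quantities), Welch's t-test for two
groups and one-way ANOVA beyond that, excluding non-positive values with
a reported count.

# The forward simulator

`simConfig()` defaults define the simulated study conditions:

| parameter | default | rationale |
|---|---|---|
| diameter law | log-normal, median 80 nm, log-sd 0.3 | ~80 nm average diameter of captured vesicles; diameter CV in the 0.2–0.4 range |
| copies per species at 80 nm | 6.7 each for MmCD9/MmCD63/MmCD81; 20 for HsCD81 (tracer-positive only, zero-truncated Poisson) | with 70% labeling gives ~14–17 detected panel markers and ~14 detected tracer markers per vesicle, the detected-marker averages of the modeled assay |
| copy-number scaling | ∝ (diameter/80 nm)² | surface proteins scale with membrane area |
| labeling probability | 0.7 | realistic single-step antibody labeling efficiency |
| per-copy capture probability | 0.35 | overnight incubation on high-avidity coverslips: multi-copy vesicles captured nearly surely, single-copy ones at ~1/3 |
| blinks per antibody | geometric on {1, 2, …}, mean 14 | memoryless blinking, matching the L = 14 calibration mean |
| localization precision σ | 10 nm per axis | typical dSTORM precision for AF647 |
| background | uniform Poisson, 0.5 /µm² | sparse nonspecific binding |
| ROI | 50 × 50 µm, 20 ROIs | plasma imaging design (10 for CSF) |

Capture follows 1 − (1 − p)^k in the copy number k of the capture
target, plus an optional Poisson nonspecific term; stained antibody
anchors are uniform on the sphere, orthographically projected (vesicle
radius ≪ TIRF depth, so no z-dependence). Localizations falling outside
the ROI are discarded, as at a real detector edge. One master seed
drives derived streams per stage and per ROI, so outputs are
reproducible and ROIs order-independent.

What the simulator does **not** emulate: camera frames and PSF fitting
(it starts at localization tables), drift, multi-emitter artifacts,
epitope masking, antibody cross-reactivity, vesicle aggregation, and any
correlation between tracer load and mouse-marker content. Passing
recovery tests therefore validate the analysis chain under the stated
generative model — they do not certify absolute accuracy on real data,
where the blinking calibration and labeling efficiency must come from
calibration experiments.

A consequence worth knowing: with area-scaled copy numbers and a
log-normal tail, large (>150 nm) vesicles carry many antibodies, are
captured and detected with near certainty, and pull cohort mean
diameters above the population median; small dim vesicles fall below the
40-localization floor. Detected-cohort averages are therefore biased
relative to population truth in the simulator exactly as they are in the
physical assay. Ratio estimators cancel this bias to first order because
it applies to numerator and denominator cohorts alike; the residual bias
from capture-efficiency asymmetry (reference capture misses a few
low-copy vesicles that tracer capture would hold) is visible in the
worked examples and stays within the ±0.03 recovery tolerance at the
plasma design.

# Numerical choices

* Tessellation coordinates are rescaled to unit size; the super-triangle
  spans 1e3 × that scale — large enough that hull circumcircles of dense
  SMLM data never reach it, small enough for well-conditioned incircle
  determinants in double precision.
* Voronoi adjacency requires a shared edge of positive length (squared
  length > 1e-20 in normalized units), symmetrized by requiring the facet
  from both sides.
* Area conservation is asserted at 1e-6 relative tolerance; observed
  errors are at machine precision.
* Problem sizes in the acceptance checks were chosen as the smallest that
  exercise the published designs: 20 ROIs × ~200 EV/ROI (plasma) and
  10 × ~40 (CSF) for fraction recovery, 200 ROIs × 5 planted vesicles for
  the clustering oracle, 1e4 localizations for shell recovery.
* Bootstrap and simulation seeds derive from one integer via fixed
  Lehmer-style mixing, kept below 2³¹.

# Limitations

* The density threshold and closure rules are principled defaults, not a
  reimplementation of any particular legacy code path; absolute agreement
  with other Voronoi segmentation software is not guaranteed, and all
  validation is by parameter recovery.
* Diameters assume spherical vesicles and an accurate σ; comparisons to
  published diameters should be treated as range-level, since published
  estimator details (including any precision correction) are typically
  unstated.
* Contribution estimators assume capture conditions differ only in the
  capture antibody; systematic differences in coverslip chemistry or
  incubation volume must be normalized out beforehand (EV/µL handles
  volume).
* Single-animal cohorts: ROIs are technical replicates, so bootstrap
  intervals quantify imaging sampling error, not animal-to-animal
  variability.
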