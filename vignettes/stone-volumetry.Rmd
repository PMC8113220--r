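---
title: "Measuring renal stone burden on CT: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring renal stone burden on CT: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stonevol)
```

## The problem

Clinical decisions about renal stones — whether to treat with
extracorporeal shockwave lithotripsy (SWL), and whether treatment
succeeded — are conventionally based on one or two manually measured
stone diameters on CT. Diameters are a crude proxy for the quantity
that matters physically, the stone *volume*: small differences in a
measured axis translate into large volume differences, and after
treatment, a residual fragment's single axis length can badly
understate how much stone is actually left. `stonevol` implements a
semi-automated volumetric alternative and the analyses needed to
compare it against manual axis measurement: segmentation by Hounsfield
unit (HU) thresholding, voxel-count volumetry, the manual ellipsoid
estimators, a three-way treatment-outcome classification, and a
logistic-regression layer that asks which burden measure best predicts
a stone-free outcome.

## The volumetry method

A non-contrast CT of the kidneys, ureters and bladder (CT KUB) is read
into a `CTVolume`: a `(slice, row, col)` grid of HU values plus pixel
spacing, slice thickness and slice positions. Stones are
hyperattenuating (typically several hundred HU against ~30 HU soft
tissue), so a single global threshold separates candidate stone voxels
from tissue and urine:

* **Thresholding.** `thresholdMask(volume, huThreshold)` marks every
  voxel with HU ≥ threshold. The comparison is inclusive so boundary
  behaviour is deterministic. The default of 130 HU is the conventional
  calcification cut-off; the workflow treats the threshold as per-case
  tunable, mirroring semi-automated clinical tools.
* **Instance labelling.** `labelStones()` groups mask voxels into
  stones by 3D connected components (voxel adjacency graph, components
  via igraph). Default connectivity is the 26-neighbourhood: a stone
  crossing slices with a sub-voxel lateral shift must stay one object.
  Components under `minVoxels` (default 2) are discarded as noise
  speckle; survivors are labelled 1..n by decreasing voxel count, ties
  broken by the lexicographically smallest `(slice, row, col)` member.
  Labelling is fully 3D; a per-slice 2D variant stacked afterwards
  would give the same voxel counts but could split stones across
  slices, so the 3D form is used.
* **Morphometry.** For each stone, `measureStone()` reports the voxel
  count and the volume identity
  `volume = N · row_spacing · col_spacing · slice_thickness`, the
  largest axial slice (most stone pixels; ties to the lowest index),
  the in-plane bounding-box extents of that slice (whole pixels:
  `(max − min + 1) · spacing`, so a one-pixel stone has width one
  pixel), that slice's area, and the craniocaudal extent.
  `totalBurden()` sums volumes over stones, as a multi-stone treatment
  plan requires.

Deliberately absent: morphological opening/closing (it would change the
measured volume beyond what the threshold defines), Feret diameters
(the manual protocol measures along image axes, and automated and
manual axes must share a convention to be comparable), and texture or
HU-statistics features.

Two conventions were genuinely open and are fixed as follows. The
"major vertical axis" is the in-plane row-direction extent of the
largest slice — both manual axes are measured on the largest
cross-sectional slice, so the automated counterpart is in-plane — and
the craniocaudal extent is reported separately. The manual protocol's
third diameter (from the coronal view) overlaps directionally with the
axial axes; it is interpreted as the craniocaudal direction.

## Manual ellipsoid estimators

From three measured diameters, `axisTriple()` assigns `a` = largest,
`b` = smallest, `c` = middle, and `ellipsoidVolumes()` evaluates

* scalene: π/6 · a · b · c
* oblate: π/6 · a · a · c
* prolate: π/6 · a · b · b

Under the `a ≥ c ≥ b` assignment, oblate ≥ scalene ≥ prolate is an
algebraic identity (replace `b` by `a`, or `c` by `b`). The diameter
labels in the manual protocol ("equatorial", "polar", "third") do not
by themselves fix an ordering; this assignment is the one under which
the cohort-level median ordering of the three estimators observed in
practice holds for every individual stone, so it is adopted as the
convention.

```{r estimators}
ellipsoidVolumes(axisTriple(10, 6, 4))
```

## Outcome classification and reclassification

`classifyOutcome()` maps a case's residual fragments to one of three
categories: `completely_stone_free` (no fragments),
`stone_free_with_cirfs` (fragments present, every major axis ≤ the
CIRF threshold), `not_stone_free` (any axis above it). CIRF stands for
clinically insignificant residual fragment; the conventional threshold
is 4 mm, inclusive, applied per fragment.

`reclassificationReport()` runs the volume-vs-axis comparison: among
cases called not-stone-free, find the smallest total residual volume;
count CIRF-classed cases whose total residual volume *strictly* exceeds
it (their burden was underestimated by the axis rule), and count
not-stone-free cases whose every fragment axis is ≤ the threshold on
re-measurement (the axis rule would now call them stone-free with
CIRFs). Multi-fragment cases aggregate by total volume but use the
per-fragment maximum axis, matching how the size rule is defined.

```{r reclass}
fr <- exampleFragments()
reclassificationReport(fr[fr$group == "stone_free_with_cirfs", ],
                       fr[fr$group == "not_stone_free", ])
```

## Statistical layer

`pearsonR()` is the product-moment correlation used to compare manual
against automated measures. `fitLogistic()` fits the univariable model
`logit P(stone-free) = b0 + b1 x` by iteratively reweighted least
squares (convergence when the largest coefficient change falls below
1e-8, at most 100 iterations), and reports the per-unit odds ratio
Exp(B) with a 95% Wald interval and Wald p-value — the presentation
conventional in clinical statistics software — plus Cox–Snell
`1 − exp((2/n)(L0 − L1))` and Nagelkerke (max-rescaled) pseudo R².
Per-predictor univariable models are compared by `rankPredictors()`
with no multiple-testing correction, matching the descriptive use of
Nagelkerke R² as "variance explained". (Quasi-)complete separation —
outcome classes occupying non-overlapping predictor ranges — makes the
slope MLE diverge; it is detected from the data and the fit is flagged
`reliable = FALSE` rather than silently returned.

Which stone-free definition feeds the regression is configurable by
how the user codes the outcome column; the headline definition
(completely stone-free vs rest) is the default in the cohort
simulator.

## The phantom generator: what it emulates and what it does not

`phantomSpec()`/`renderPhantom()` build axial CT stacks containing
ellipsoidal stones of analytically known geometry: each voxel whose
centre falls inside a rotated ellipsoid takes the stone's HU mean,
others the background mean; Gaussian noise is added per voxel and the
field is then blurred (noise before blur mimics reconstruction
smoothing of detector noise). The manifest stores each stone's
analytic volume π/6 · d1 · d2 · d3 as ground truth. Default HU model:
background 30 ± 15 HU, stone 800 ± 100 HU, blur 0.4 mm — typical
renal-stone contrast, chosen as rendering fixtures rather than claims
about any scanner.

The inside test uses voxel centres, deliberately matching the
per-voxel behaviour of the thresholding being validated; a 3×
supersampling flag exists for convergence studies. The stone-in-grid
check uses the enclosing sphere (max semi-diameter), slightly
conservative for rotated ellipsoids.

The phantoms contain no anatomy, no projection/reconstruction physics,
no beam hardening, and no irregular stone shapes. Passing phantom
tests therefore demonstrates that segmentation and morphometry recover
known geometry under controlled contrast — the digitization behaviour
of the algorithms — not that any particular clinical threshold choice
is correct on real, artefact-laden scans.

**Digitization accuracy.** For diameters 4–20 mm at 0.5 mm isotropic
voxels the voxel-count volume lies within 5% of the analytic volume
(in practice well under 1%), and the error shrinks at 0.25 mm voxels.
One numerical subtlety: per-shape error oscillates at the ~0.1% level
with stone-centre/grid alignment — a stone centred exactly on voxel
boundaries is a degenerate alignment that can even make errors tie
across resolutions — so convergence is asserted on the mean absolute
error over a shape set, and test fixtures offset the stone centre by a
grid-incommensurate amount.

## The cohort simulator and its calibration

`simulateCohort()` draws per-case true stone volumes from a
log-normal, derives three axis lengths of a random ellipsoid with
exactly that volume (log-normal aspect ratios, sd 0.25 on the log
scale), applies multiplicative Gaussian measurement noise, and draws
the binary stone-free outcome from
`plogis(intercept + slope · volume)`. The defaults are calibrated to a
published 72-case SWL cohort: volume median 113 mm³ with IQR 62–276
(`meanlog = log 113`, `sdlog = 1.107` from the normal-quantile IQR
relation), odds ratio 0.994 per mm³ (`slope = log 0.994`), intercept
0.45 so the stone-free probability at the median volume is near the
observed 44% rate, and 5% measurement noise — a realistic
inter-observer error, as no measured value is published. These
defaults are the simulator's study conditions and are not tuned per
analysis.

Parameter-recovery behaviour under these conditions (n = 2000
replicate cohorts): estimates are unbiased and the Wald standard
errors match the empirical sampling SD, giving per-coefficient 95% CI
coverage at its nominal level. The test suite asserts coverage within
[90%, 99%] over 200 replicates; a smaller replicate count makes the
binomial check itself unacceptably noisy. Note that the volume
distribution's heavy right tail produces high-leverage cases, so the
*joint* event "both CIs cover" runs a few points below the product of
the marginals.

## Problem sizes and runtime choices

The shipped tests use phantom grids up to ~96³ voxels (20 mm stones at
0.25 mm voxels), 50-phantom invariant sweeps at 12³–15³, simulated
cohorts of n = 2000 with 200 replicates for coverage, and a
six-to-twelve-point toy dataset for the brute-force likelihood oracle
(nested grid refinement, independent of the IRLS path). These sizes
were chosen so the full suite exercises every claim in well under a
minute of compute per module while keeping Monte-Carlo error
negligible relative to the asserted tolerances.

## Known limitations

* Only single-frame, axial, untilted DICOM series are supported; no
  multi-frame/enhanced CT, oblique reformats or contrast-phase logic.
* Thresholding is global and intensity-only; touching stones separated
  by a watershed-like constriction are returned as one object.
* The ellipsoid estimators inherit the manual protocol's assumption
  that stones are ellipsoids; for irregular stones they are biased by
  construction, which is precisely the motivation for voxel-count
  volumetry.
* The cohort simulator is a statistical twin (distributions and an
  outcome model), not an imaging twin: it does not generate images,
  and its measurement-noise model is multiplicative Gaussian only.
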