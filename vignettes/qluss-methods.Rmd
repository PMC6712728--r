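---
title: "Methods: automatic B-line quantification and score validation"
author: "qluss authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic B-line quantification and score validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qluss)
```

## The measurement problem

B-lines are laser-like vertical hyperechoic reverberation artifacts that
arise at the pleural line and extend to the bottom of the ultrasound screen
without fading. Their extent along the pleura tracks extravascular lung
water (EVLW), the clinical gold standard for pulmonary edema measured by
transpulmonary thermo-dilution. Visual B-line scoring is hard exactly where
it matters: numerous or coalescent B-lines cannot be reliably counted, and
"more or less than half of the pleura involved" is a difficult visual
judgement. `qluss` implements a fully automatic per-frame measurement — the
percentage of image columns classified as B-line below the pleural line —
whose intra-patient mean over the 12 standard intercostal frames is the
quantitative score QLUSS, together with the four semi-quantitative
comparator scores and the statistics used to validate all five against
EVLW.

## The segmentation pipeline

`runPipeline()` composes six stages; every stage is exported and unit
tested on its own.

1. **Pleural-line localization** (`locatePleuralLine`). The pleural line is
   the dominant horizontal reflector in a linear-probe transverse scan, so
   it is located as the row of maximal mean intensity within the top 40% of
   the frame (`searchFraction = 0.4`). Ties break toward the shallowest
   row, anchoring a thick pleural band at its top. The region of interest
   is everything from `offset = 2` rows below that line to the bottom of
   the frame: B-lines reach the bottom of the screen, so no lower cut is
   imposed. A per-frame manual override is available through the manifest
   for atypical frames. Frames whose detected line leaves fewer than 8 rows
   are rejected as degenerate.
2. **Contrast stretch** (`adjustContrast`). A percentile-clip linear
   stretch maps the 1st percentile to 0 and the 99th to 255. Percentile
   clipping (rather than min–max) makes the stretch insensitive to a few
   saturated or dropout pixels. A zero-dynamic-range ROI passes through
   unchanged with the `constant_roi` flag; dividing by zero is impossible.
3. **Two-class clustering** (`kmeansBinarize`). Pixels are split into two
   intensity classes by 2-means. In one dimension the optimal 2-partition
   is an interval split, so the package enumerates all intensity cut
   points and takes the global within-cluster sum-of-squares minimum:
   exact, deterministic, no random initialization anywhere (ties break
   toward the lowest cut). The higher-centroid class is "white". The tests
   hold this equal to an independent exhaustive-threshold oracle on random
   images.
4. **Alternated sequential filter** (`asfFilter`). Openings followed by
   closings with vertical (axial) line elements of odd lengths 3, 5, 7, 9,
   11. The openings remove white objects axially shorter than the element —
   isolated specks and the 1-pixel-tall lateral bridges that spuriously
   merge neighboring B-lines — while the terminal closing (length 11) fills
   axial gaps of up to `asfMaxGap = 10` pixels inside a column. Border
   convention: erosion treats out-of-image pixels as white and dilation as
   black (the convention of mainstream morphology toolboxes), so neither
   opening nor closing erodes the image borders; the filter is idempotent.
   The schedule is configurable through `asfMaxGap`.
5. **Column scan** (`detectBlineColumns`). A column is flagged as B-line
   when at least 50% of the pixels in the uppermost 70% of the ROI depth
   are white (`whiteFractionThreshold = 0.5`, `depthFraction = 0.7`, both
   inclusive `>=`). The rule is read as a 50% white-pixel criterion inside
   a 70%-depth window anchored at the pleura, because B-lines arise at the
   pleura and may attenuate at depth; the alternative reading (50% over
   the full column combined with a 70% vertical-span requirement) is a
   defensible variant and both numbers are configuration parameters, so
   neither is hard-coded anywhere.
6. **Frame percentage** (`frameBlinePercent`): 100 × flagged/total columns,
   carried at full precision and rounded to 2 decimals only when
   serialized. `aggregateQLUSS()` averages the 12 frame percentages into
   the patient score, warning when any region is annotated tissue-like
   (the column scan is meaningless over consolidated lung, and the method
   is likewise not applicable to pleural effusion).

A constant ROI (no intensity structure at all below the pleura) cannot be
split by stages 2–3; it is classified wholesale by a mid-scale cut
(median > 127.5 means all columns white), so a uniformly dark field scores
0, a full-width coalescent band scores 100, and either result carries the
`constant_roi` flag.

Determinism is a design invariant: identical frame and configuration give
a bit-identical result, and every result records an MD5 digest of the
configuration that produced it.

## Semi-quantitative comparator scores

Computed by `scorePanel()` from one clinician annotation per region
(pattern, maximum B-line count with fused B-lines counted once, visual
percentage of the rib space filled by confluent B-lines, additional
discrete B-lines):

* **nLUSS** — total B-line count over the 12 regions.
* **%LUSS** — per region, confluent percentage / 10 plus discrete B-lines,
  white lung fixed at 10; summed.
* **cLUSS** — per-region aeration-loss grade 0–3 (0: A-lines or fewer than
  2 B-lines; 1: spaced B-lines; 2: coalescent, including white lung; 3:
  tissue-like), summed.
* **qLUSS** — as cLUSS but coalescence is graded 1 when occupying ≤ 50% of
  the space and 2 when > 50%, which is why qLUSS ≤ cLUSS always holds.

Two conventions had to be fixed where the published grade anchors leave a
gap. Exactly 2 B-lines falls between the stated grade-0 ("< 2 B-lines")
and grade-1 ("≥ 3 spaced B-lines") anchors; the package grades it 1
(aeration loss is present), isolated in one internal function so the
alternative is a one-line change. qLUSS grades for non-coalescent patterns
are not restated in the source description; they inherit the cLUSS grades,
which is consistent with qLUSS ≤ cLUSS across the whole packaged cohort.

## Validation statistics

All analyses run offline on the packaged 12-patient cohort table
(`lusTable1()`).

* **Regression** (`fitSLR`, `fitRobust`): OLS plus Huber
  (k = 1.345), LAD, S, MM (bisquare c = 3.44, 85% efficiency), LMS and
  LTS. LTS minimizes the sum of the h = ⌊(n+p+1)/2⌋ smallest squared
  residuals (h = 7 at n = 12) and is solved *exactly* by exhaustive
  enumeration of subsets for n ≤ 20 — the tests pin it to an independent
  `lm()`-over-subsets oracle and to order/seed invariance. LMS ("least
  mean squares" is read as Rousseeuw's least *median* of squares, the
  estimator conventionally abbreviated LMS in the robust-regression canon;
  the literal reading would duplicate OLS) is solved exactly through the
  elemental-pair property. For the trimmed estimators the primary
  R² is the *trimmed* R², 1 − SS_res(h)/SS_tot(h) on the h retained
  observations; the output also carries the all-points R² and a
  `r_squared_definition` string, because robust R² conventions differ
  between packages. On the packaged table the exhaustive LTS trimmed R²
  for QLUSS~EVLW is 0.96 (the acceptance script computes it); the
  originally reported robust R² of 0.86 is not reproduced by this or any
  other standard convention we evaluated (reweighted-LS refits with a
  2.5σ cut give 0.81, scale-ratio forms 0.91–0.96), and the original
  statistical supplement is not available to settle the definition — the
  discrepancy is reported rather than tuned away.
* **Correlation** (`spearmanCorrelation`): Spearman r as Pearson on
  midranks, two-sided p from the t approximation with n − 2 df (adequate
  at n = 12; an exact Monte-Carlo permutation p is available behind
  `pMethod = "permutation"`). Of the four published QLUSS correlations,
  three reproduce exactly from the packaged table (0.772, 0.561, 0.105);
  the %LUSS coefficient computes to 0.743 where 0.757 was reported — an
  internal inconsistency of the source table that propagates to the
  dependent-correlation p-values below.
* **Dependent overlapping correlations**
  (`compareDependentCorrelations`): Dunn & Clark's z with the
  Hittner–May–Silver modification (covariance evaluated at the
  backtransformed average of the two Fisher transforms). From the packaged
  table the two comparisons give p = 0.041 and p = 0.073 (reported: 0.037
  and 0.071; the %LUSS inconsistency accounts for the offset).
* **Agreement ICC** (`iccAgreement`): two-way, absolute-agreement,
  single-measure ICC from the closed-form mean-squares decomposition, 95%
  CI by the F-based method, strength labels at lower-inclusive cut-points
  0.30/0.50/0.70/0.90 (so the labels partition the whole range).
  Single-measure is the appropriate form when each rater contributes one
  score; the average-measure coefficient sits behind
  `averageMeasure = TRUE`. Note a statistical fact the simulation tests
  respect: with k raters the rater variance component is estimated with
  k − 1 degrees of freedom *however many subjects there are*, so with 2
  raters the ICC estimate concentrates on the component ratio of the
  rater effects actually drawn, not on the population ratio;
  `generateRaterTable()` therefore attaches both `theoretical_icc` and
  `realized_icc`, and recovery is tested against the realized ratio
  (within ±0.04 at 500 subjects).
* **Power** (`powerCorrelation`): two-sided test of zero correlation via
  the Fisher-z approximation with the small-sample bias term
  z_r = atanh(r) + r/(2(n−1)) and a t-based critical correlation
  r_c = √(t²/(t² + n − 2)). This exact formula is pinned because it
  reproduces both published design values (0.924 at r = 0.8 and 0.85 at
  r = 0.75, n = 12, α = 0.05) analytically.

## The phantom generator

`generatePhantomFrame()` emulates exactly the image structure the pipeline
exploits: a uniform dark background (default 20/255), a bright pleural
line (default rows 20–21 of a 128 × 60 frame), and rectangular vertical
bands of controlled center, width, intensity and penetration depth
(default: to the bottom of the frame, as B-lines do). Overlapping or
adjacent bands coalesce into a single ground-truth interval, exercising
the detector on merged B-lines; optional axial dropouts exercise the ASF
gap closure; speckle is multiplicative log-normal (a simple, standard
stand-in for ultrasound speckle), applied after the geometry so it never
alters the ground truth; an optional lateral Gaussian blur emulates finite
beam width. Frames are bit-reproducible from (spec, seed).

What the phantom does *not* emulate: scan-conversion geometry, spatially
correlated Rayleigh speckle, rib shadows, A-line reverberations, moving
cine loops, effusions and consolidations. Passing the phantom tests
therefore demonstrates the algorithm's correctness on its own model of the
data — bright axial bands over speckle — not clinical performance, which
the cohort statistics address separately.

Test and acceptance problem sizes are deliberate package choices: 50
random phantom specs per property (exact recovery noiseless; pooled
column-level F1 ≥ 0.90 at speckle σ = 0.15), 100 random 64 × 64 images for
the clustering oracle, 500 subjects for ICC recovery — all run in seconds
on one core while leaving the estimators no room to hide.

## Degenerate inputs, tie-breaks, rounding

* Row-mean ties in pleural detection: shallowest row wins.
* Clustering threshold ties: lowest cut point wins.
* Column rule and coalescence split: inclusive (≥ 50%, ≤ 50%).
* Constant ROI: flagged, classified by the mid-scale cut described above.
* Percentages and scores are carried at full precision; rounding to 2
  decimals happens only in serialized CSV/JSON output.
* All coordinates are 1-based, row-major, origin at the top-left (skin
  surface), the R convention.

## Known limitations

The measurement is defined on single still frames — one representative
frame per intercostal space — not on cine loops; frame selection remains
an operator decision. It is not valid in pleural effusion or
consolidation (flagged, not silently scored). The pleural-line detector
presumes a linear-probe transverse view in which the pleura is the
dominant horizontal reflector; the manifest override exists for the
frames where it is not.
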