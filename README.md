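# qluss — quantitative lung ultrasound B-line scoring

B-lines are vertical hyperechoic reverberation artifacts that arise at the
pleural line and extend to the bottom of the ultrasound screen; their
extent along the pleura tracks extravascular lung water (EVLW), the
thermo-dilution gold standard for pulmonary edema. Counting them by eye is
unreliable precisely when it matters most — when they are numerous or
coalescent. `qluss` is for intensivists and ultrasound researchers who
want an operator-independent measurement: it computes, fully
automatically, the percentage of the pleural line affected by B-lines on
each intercostal still frame, and averages it over the 12 standard
regions into the patient-level quantitative score **QLUSS**.

The per-frame measurement is a five-stage segmentation of the sub-pleural
region of interest *I* (rows below the detected pleural line):

1. percentile contrast stretch (1st–99th percentile → 0–255);
2. exact 1-D 2-means binarization: the partition of pixel intensities
   minimizing the within-cluster sum of squares (in 1-D an interval split,
   found deterministically by exhaustive cut-point search);
3. alternated sequential filter: openings then closings with vertical line
   structuring elements of lengths 3, 5, 7, 9, 11, closing axial gaps
   ≤ 10 px and severing lateral bridges;
4. column scan: column *j* is B-line iff
   (Σ white pixels in the top ⌈0.7·depth⌉ rows of column *j*) / ⌈0.7·depth⌉ ≥ 0.5;
5. frame score = 100 × (flagged columns)/(total columns);
   QLUSS = mean over the patient's 12 frames.

The package also implements the four semi-quantitative comparator scores
computed from clinician annotations (nLUSS, %LUSS, cLUSS, qLUSS), the
validation statistics (OLS and robust regression — Huber, LAD, S, MM, and
*exact* exhaustive LTS/LMS — tie-corrected Spearman correlation, the
Hittner–May–Silver test for dependent overlapping correlations, two-way
absolute-agreement ICC with strength labels, and correlation-test power),
a synthetic phantom generator with known column-level ground truth, and a
command-line interface. The 12-patient validation cohort table ships with
the package (`lusTable1()`).

## Worked example

```r
library(qluss)

## a speckled phantom with three B-line bands covering 20 of 60 columns
spec <- phantomSpec(
  bands = data.frame(center = c(14, 33, 50), width = c(6, 10, 4),
                     intensity = 200, depth_fraction = 1),
  speckleSigma = 0.12, seed = 42)
ph <- generatePhantomFrame(spec)
ph$truth
#> PhantomTruth: 33.33% of columns covered

runPipeline(ph$frame)
#> FrameResult: bline_percent=33.33  patient=NA region=NA

## validation statistics on the packaged cohort
t1 <- lusTable1()
fitSLR(t1$QLUSS, t1$EVLW)
#> OLS regression (n = 12)
#>   y = 6.8810 + 0.2857 x,  R^2 = 0.567,  p(slope) = 0.004709

fitRobust(t1$QLUSS, t1$EVLW, "lts")
#> LTS regression (n = 12)
#>   y = 7.7673 + 0.1721 x,  R^2 = 0.959
#>   trimmed fit, h = 7 retained of 12 (trimmed: 1 - SS_res(h)/SS_tot(h) on the h retained observations)

spearmanCorrelation(t1$QLUSS, t1$qLUSS)
#> Spearman rank correlation: r = 0.772, p = 0.003243 (n = 12, t approximation)

powerCorrelation(0.8, 12)
#> Power of the two-sided zero-correlation test: 0.924 (r = 0.8, n = 12, alpha = 0.05)

iccAgreement(generateRaterTable(500, c(4, 1, 1), seed = 1))
#> ICC (two-way, absolute agreement, single measure): 0.779  95% CI [0.734, 0.816]  agreement: strong
```

Reading the output: the phantom's three bands cover 20/60 = 33.33% of the
columns and the pipeline recovers that percentage through the speckle. On
the cohort table, QLUSS explains 57% of EVLW variance under OLS; the
exhaustive least-trimmed-squares fit (7 of 12 observations retained)
explains 96% of the variance of the retained set — the output states
which R² convention it reports, since robust R² definitions differ
between packages. QLUSS correlates with the semi-quantitative qLUSS at
r = 0.772 (p = 0.003), and the study design's power for detecting r = 0.8
at n = 12 is 0.924.

## Command-line interface

A thin wrapper ships at `inst/scripts/qluss`:

```sh
qluss simulate --spec spec.json --out frames/          # phantoms + truth.csv
qluss segment  --manifest frames.csv --out results.csv # per-frame percentages
qluss qluss    --manifest frames.csv --annotations ann.csv --out panel.csv
qluss scores   --annotations ann.csv --out scores.csv  # semi-quantitative
qluss stats    --table table1.csv --analysis slr --x QLUSS --y EVLW --out report.json
qluss simulate-raters --n 500 --var 4,1,1 --seed 7 --out raters.csv
```

Every command writes a provenance sidecar (package version, configuration
digest, seed) next to its output; identical inputs and seed give
byte-identical outputs.

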