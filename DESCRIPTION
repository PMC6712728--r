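Package: qluss
Title: Quantitative Lung Ultrasound B-Line Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Fully automatic quantification of B-line artifacts in lung
    ultrasound still frames. Implements a per-frame segmentation pipeline
    (pleural-line localization, percentile contrast stretch, exact
    one-dimensional 2-means binarization, alternated sequential morphological
    filtering with axial line elements, and a per-column white-fraction scan)
    that measures the percentage of the pleural line affected by B-lines
    (QLUSS), together with four semi-quantitative comparator scores computed
    from clinician annotations (nLUSS, %LUSS, cLUSS, qLUSS) and the
    statistical framework used to validate the scores against extravascular
    lung water: simple and robust linear regression (Huber, LMS, LTS, LAD, S,
    MM), tie-corrected Spearman correlation, comparison of dependent
    overlapping correlations, two-way absolute-agreement intraclass
    correlation, and correlation-test power. A synthetic phantom generator
    provides frames with known B-line ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: methods, stats, utils, tools, png, tiff, MASS, jsonlite
Suggests: testthat (>= 3.0.0), EBImage, withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'frames-io.R'
    'morphology.R'
    'segmentation.R'
    'scoring.R'
    'stats-regression.R'
    'stats-correlation.R'
    'stats-icc.R'
    'phantom.R'
    'table1.R'
    'cli.R'
    'qluss-package.R'
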