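cfg <- segmentationConfig()

test_that("contrast stretch maps clip percentiles to the full range", {
  # 90% of pixels at 50, 10% at 200: 1%/99% quantiles sit on the two values
  px <- matrix(c(rep(50L, 180L), rep(200L, 20L)), 20L, 10L)
  out <- adjustContrast(makeRoi(px), cfg)
  expect_true(all(pixels(out)[px == 50L] == 0L))
  expect_true(all(pixels(out)[px == 200L] == 255L))
})

test_that("contrast stretch is near-identity on full-range input", {
  set.seed(2)
  px <- matrix(sample(0:255, 400L, replace = TRUE), 20L, 20L)
  px[1L] <- 0L; px[2L] <- 255L
  out <- adjustContrast(makeRoi(px), cfg)
  expect_lte(max(abs(pixels(out) - px)), 8L)  # 1%/99% clip quantization
})

test_that("constant ROI passes through flagged, never divides by zero", {
  px <- matrix(77L, 12L, 9L)
  expect_warning(out <- adjustContrast(makeRoi(px), cfg), "constant")
  expect_identical(pixels(out), px)
  expect_true("constant_roi" %in% out@flags)
})

test_that("binarization separates well-separated modes exactly", {
  px <- matrix(c(rep(10L, 50L), rep(240L, 50L)), 10L, 10L)
  m <- kmeansBinarize(makeRoi(px), cfg)
  expect_identical(pixels(m), px == 240L)
  expect_equal(m@stage, "kmeans")
})

test_that("binarization finds the global within-cluster-SS optimum", {
  # {0, 100, 101, 255} equally frequent: WCSS is minimized by the split
  # {0, 100, 101} | {255} (6734 vs 16858 for {0,100}|{101,255})
  px <- matrix(rep(c(0L, 100L, 101L, 255L), each = 25L), 10L, 10L)
  m <- kmeansBinarize(makeRoi(px), cfg)
  expect_identical(pixels(m), px == 255L)
})

test_that("binarization equals the exhaustive-threshold oracle", {
  set.seed(7)
  for (i in 1:20) {
    vals <- sample(0:255, sample(2:6, 1L))
    px <- matrix(sample(vals, 15L * 12L, replace = TRUE), 15L, 12L)
    if (length(unique(as.vector(px))) < 2L) next
    thr <- thresholdOracle(as.vector(px))
    m <- kmeansBinarize(makeRoi(px), cfg)
    expect_identical(pixels(m), px > thr)
  }
})

test_that("single-valued ROI raises a degenerate-clustering error", {
  expect_error(kmeansBinarize(makeRoi(matrix(5L, 10L, 10L)), cfg),
               "degenerate-clustering")
})

test_that("ASF closes axial gaps up to 10 px and not beyond", {
  m <- matrix(FALSE, 40L, 9L); m[, 5L] <- TRUE; m[10:17, 5L] <- FALSE
  out <- pixels(asfFilter(makeMask(m), cfg))
  expect_true(all(out[, 5L]))            # 8-px gap closed, borders intact
  expect_false(any(out[, -5L]))
  m2 <- matrix(FALSE, 40L, 9L); m2[, 5L] <- TRUE; m2[10:20, 5L] <- FALSE
  expect_false(all(pixels(asfFilter(makeMask(m2), cfg))[, 5L]))
})

test_that("ASF removes specks and lateral bridges, keeping columns", {
  m <- matrix(FALSE, 40L, 9L); m[20L, 4L] <- TRUE
  expect_false(any(pixels(asfFilter(makeMask(m), cfg))))
  # two tall columns joined by a 1-px-tall bridge on a 15 x 9 grid
  b <- matrix(FALSE, 15L, 9L); b[, 3L] <- TRUE; b[, 7L] <- TRUE
  b[8L, 4:6] <- TRUE
  out <- pixels(asfFilter(makeMask(b), cfg))
  expect_false(any(out[, 4:6]))
  expect_true(all(out[, c(3L, 7L)]))
})

test_that("ASF is idempotent", {
  set.seed(9)
  for (i in 1:10) {
    m <- matrix(runif(40L * 25L) < runif(1, 0.2, 0.8), 40L, 25L)
    a1 <- pixels(asfFilter(makeMask(m), cfg))
    a2 <- pixels(asfFilter(makeMask(a1), cfg))
    expect_identical(a1, a2)
  }
})

test_that("ASF agrees with EBImage morphology away from borders", {
  set.seed(11)
  for (i in 1:5) {
    m <- matrix(FALSE, 60L, 30L)
    m[20:40, 8:22] <- matrix(runif(21L * 15L) < 0.5, 21L, 15L)
    ref <- EBImage::Image(m * 1)
    for (len in seq(3L, 11L, 2L)) {
      k <- EBImage::makeBrush(len, shape = "line", angle = 0)
      ref <- EBImage::dilate(EBImage::erode(ref, k), k)   # opening
      ref <- EBImage::erode(EBImage::dilate(ref, k), k)   # closing
    }
    mine <- pixels(asfFilter(makeMask(m), cfg))
    expect_identical(unname(mine), unname(ref@.Data > 0.5))
  }
})

test_that("column scan evaluates the uppermost depth window inclusively", {
  # 100-row ROI, window = 70 rows; 35 white rows = 0.5 -> flagged,
  # 34 -> not flagged
  m <- matrix(FALSE, 100L, 3L)
  m[1:35, 1L] <- TRUE
  m[1:34, 2L] <- TRUE
  m[71:100, 3L] <- TRUE                  # white only below the window
  det <- detectBlineColumns(makeMask(m, "asf"), cfg)
  expect_equal(det@whiteFraction, c(0.5, 34 / 70, 0))
  expect_identical(det@isBline, c(TRUE, FALSE, FALSE))
})

test_that("stage bookkeeping guards the pipeline order", {
  m <- matrix(TRUE, 20L, 5L)
  expect_error(asfFilter(makeMask(m, "asf"), cfg), "kmeans")
  expect_error(detectBlineColumns(makeMask(m, "kmeans"), cfg), "asf")
})

test_that("frame percentage is exactly 100 x flagged / total", {
  mk <- function(flags) new("ColumnDetection",
                            whiteFraction = as.numeric(flags),
                            isBline = flags, nColumns = length(flags))
  expect_equal(blinePercent(frameBlinePercent(mk(rep(FALSE, 200L)))), 0)
  expect_equal(blinePercent(frameBlinePercent(mk(rep(TRUE, 200L)))), 100)
  expect_equal(blinePercent(frameBlinePercent(
    mk(rep(c(TRUE, FALSE), c(80L, 120L))))), 40)
})

test_that("pipeline results are deterministic and carry a config digest", {
  sp <- phantomSpec(bands = data.frame(center = c(15, 40), width = c(6, 10),
                                       intensity = 200, depth_fraction = 1),
                    speckleSigma = 0.12, seed = 21L)
  f <- generatePhantomFrame(sp)$frame
  r1 <- runPipeline(f, cfg)
  r2 <- runPipeline(f, cfg)
  expect_identical(blinePercent(r1), blinePercent(r2))
  expect_match(r1@configDigest, "^[0-9a-f]{32}$")
  expect_identical(r1@configDigest, configDigest(cfg))
})

test_that("lowering the white-fraction threshold never lowers the score", {
  sp <- phantomSpec(bands = data.frame(center = c(12, 35, 50),
                                       width = c(5, 8, 4), intensity = 190,
                                       depth_fraction = c(1, 0.8, 0.6)),
                    speckleSigma = 0.15, seed = 3L)
  f <- generatePhantomFrame(sp)$frame
  thr <- seq(0.9, 0.1, by = -0.2)
  pct <- vapply(thr, function(t)
    blinePercent(runPipeline(f, segmentationConfig(
      whiteFractionThreshold = t))), numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("widening phantom bands never lowers the score", {
  widths <- c(4L, 8L, 14L, 20L)
  pct <- vapply(widths, function(w) {
    sp <- phantomSpec(bands = data.frame(center = 30, width = w,
                                         intensity = 200,
                                         depth_fraction = 1))
    blinePercent(runPipeline(generatePhantomFrame(sp)$frame, cfg))
  }, numeric(1))
  expect_true(all(diff(pct) >= 0))
})

test_that("debug mode exposes the four intermediate stages", {
  sp <- phantomSpec(bands = data.frame(center = 30, width = 12,
                                       intensity = 200, depth_fraction = 1))
  r <- runPipeline(generatePhantomFrame(sp)$frame, cfg,
                   keepIntermediates = TRUE)
  im <- attr(r, "intermediates")
  expect_named(im, c("roi", "kmeans", "asf", "detection"))
  expect_s4_class(im$kmeans, "BinaryMask")
  expect_equal(im$asf@stage, "asf")
})

test_that("degenerate uniform fields score 0 (dark) or 100 (bright)", {
  dark <- generatePhantomFrame(phantomSpec())$frame
  expect_equal(blinePercent(runPipeline(dark, cfg)), 0)
  bright <- generatePhantomFrame(phantomSpec(
    bands = data.frame(center = 31, width = 60, intensity = 200,
                       depth_fraction = 1)))$frame
  res <- runPipeline(bright, cfg)
  expect_equal(blinePercent(res), 100)
  expect_true("constant_roi" %in% res@flags)
})
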