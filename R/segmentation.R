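#' Percentile-clip contrast stretch
#'
#' Linearly rescales ROI intensities so that the `lowPercentile` value maps
#' to 0 and the `highPercentile` value to 255, clipping beyond; this
#' maximizes the usable dynamic range before binarization while being
#' insensitive to a few extreme pixels.
#'
#' @param roi a [SubPleuralROI-class].
#' @param config a [SegmentationConfig-class].
#' @return A [SubPleuralROI-class] with stretched intensities. A ROI with
#'   zero dynamic range is returned unchanged with the `"constant_roi"`
#'   flag set (never a divide-by-zero).
#' @export
adjustContrast <- function(roi, config = segmentationConfig()) {
  stopifnot(is(roi, "SubPleuralROI"), is(config, "SegmentationConfig"))
  px <- pixels(roi)
  qs <- stats::quantile(px, c(config@lowPercentile, config@highPercentile) / 100,
                        names = FALSE)
  lo <- qs[1L]; hi <- qs[2L]
  if (hi <= lo) {
    roi@flags <- unique(c(roi@flags, "constant_roi"))
    warning("constant ROI: contrast left unchanged")
    return(roi)
  }
  out <- round(255 * (px - lo) / (hi - lo))
  out[out < 0] <- 0
  out[out > 255] <- 255
  roi@pixels <- matrix(as.integer(out), nrow = nrow(px))
  roi
}

## exact 1-D 2-means: in one dimension the optimal 2-partition is an
## interval split, so minimizing within-cluster sum of squares over all
## intensity cut points is the global k-means optimum -- and deterministic.
.bestThreshold <- function(values) {
  lev <- sort(unique(values))
  if (length(lev) < 2L)
    stop("degenerate-clustering error: ROI has a single intensity value; ",
         "check the contrast-adjustment stage")
  cnt <- tabulate(match(values, lev), nbins = length(lev))
  cs <- cumsum(cnt * lev)
  cs2 <- cumsum(cnt * lev^2)
  cn <- cumsum(cnt)
  ntot <- cn[length(cn)]
  i <- seq_len(length(lev) - 1L)              # split after level i
  wssLow <- cs2[i] - cs[i]^2 / cn[i]
  nHigh <- ntot - cn[i]
  wssHigh <- (cs2[length(lev)] - cs2[i]) - (cs[length(lev)] - cs[i])^2 / nHigh
  j <- which.min(wssLow + wssHigh)            # ties: lowest threshold
  lev[j]                                      # white iff value > threshold
}

#' Exact two-class intensity clustering
#'
#' Partitions ROI pixels into two intensity classes by one-dimensional
#' 2-means. Because the data are one-dimensional and k = 2, the optimal
#' partition is an interval split, so the global within-cluster
#' sum-of-squares minimum is found exactly (and deterministically) by
#' enumerating all intensity cut points. The higher-centroid class is
#' "white".
#'
#' @param roi a [SubPleuralROI-class] (ideally contrast-adjusted).
#' @param config a [SegmentationConfig-class].
#' @return A [BinaryMask-class] with `stage = "kmeans"`.
#' @export
kmeansBinarize <- function(roi, config = segmentationConfig()) {
  stopifnot(is(roi, "SubPleuralROI"), is(config, "SegmentationConfig"))
  px <- pixels(roi)
  thr <- .bestThreshold(as.vector(px))
  new("BinaryMask", pixels = px > thr, stage = "kmeans")
}

#' Per-column B-line detection
#'
#' Scans the filtered mask along its columns. A column is flagged as B-line
#' when at least `whiteFractionThreshold` of the pixels in its uppermost
#' `depthFraction` of the ROI depth are white -- B-lines arise at the pleura
#' and must dominate the sub-pleural band, whereas they may attenuate at
#' depth.
#'
#' @param mask a [BinaryMask-class] from [asfFilter()].
#' @param config a [SegmentationConfig-class]; both thresholds are read
#'   from it.
#' @return A [ColumnDetection-class].
#' @export
detectBlineColumns <- function(mask, config = segmentationConfig()) {
  stopifnot(is(mask, "BinaryMask"), is(config, "SegmentationConfig"))
  if (mask@stage != "asf")
    stop("detectBlineColumns expects a mask from the asf stage, got '",
         mask@stage, "'")
  m <- pixels(mask)
  win <- as.integer(ceiling(config@depthFraction * nrow(m)))
  if (win < 1L)
    stop("configuration error: depth window computes to 0 rows")
  wf <- colSums(m[seq_len(win), , drop = FALSE]) / win
  new("ColumnDetection", whiteFraction = as.numeric(wf),
      isBline = wf >= config@whiteFractionThreshold,
      nColumns = ncol(m))
}

#' Per-frame B-line percentage
#'
#' @param det a [ColumnDetection-class].
#' @param patientId,regionId identifiers carried into the result.
#' @param configDigest configuration hash (see [configDigest()]).
#' @param flags quality flags to propagate.
#' @return A [FrameResult-class]; `blinePercent` is
#'   `100 * flagged / total` at full precision (rounding to 2 decimals
#'   happens only at serialization).
#' @export
frameBlinePercent <- function(det, patientId = NA_character_,
                              regionId = NA_character_,
                              configDigest = NA_character_,
                              flags = character()) {
  stopifnot(is(det, "ColumnDetection"))
  if (det@nColumns < 1L) stop("no columns to score")
  new("FrameResult",
      blinePercent = 100 * sum(det@isBline) / det@nColumns,
      patientId = patientId, regionId = regionId,
      configDigest = configDigest, flags = flags)
}

#' Digest of a segmentation configuration
#'
#' MD5 hash of the canonical serialization of all configuration fields,
#' recorded in every [FrameResult-class] for provenance.
#'
#' @param config a [SegmentationConfig-class].
#' @return Character scalar (32 hex digits).
#' @export
configDigest <- function(config) {
  stopifnot(is(config, "SegmentationConfig"))
  txt <- paste(
    format(c(config@lowPercentile, config@highPercentile,
             config@kmeansK, config@asfMaxGap,
             config@whiteFractionThreshold, config@depthFraction,
             config@randomSeed), digits = 15),
    collapse = "|")
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(txt, f)
  unname(tools::md5sum(f))
}

#' Run the full B-line segmentation pipeline on one frame
#'
#' Composition of [locatePleuralLine()], [adjustContrast()],
#' [kmeansBinarize()], [asfFilter()], [detectBlineColumns()] and
#' [frameBlinePercent()]. A ROI with zero dynamic range (no echogenic
#' structure below the pleura) yields 0% with the `"constant_roi"` flag
#' rather than an error.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param config a [SegmentationConfig-class].
#' @param pleuralRowOverride optional manual pleural row (1-based).
#' @param keepIntermediates if `TRUE`, attach the ROI, both masks and the
#'   column detection to the result's `intermediates` attribute (the four
#'   panels of the algorithm's illustration).
#' @return A [FrameResult-class].
#' @examples
#' ph <- generatePhantomFrame(phantomSpec(
#'   bands = data.frame(center = 30, width = 18, intensity = 200,
#'                      depth_fraction = 1),
#'   seed = 1))
#' res <- runPipeline(ph$frame)
#' blinePercent(res)           # 30: 18 of 60 columns are B-line
#' @export
runPipeline <- function(frame, config = segmentationConfig(),
                        pleuralRowOverride = NULL,
                        keepIntermediates = FALSE) {
  stopifnot(is(frame, "UltrasoundFrame"))
  wrap <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", stage, conditionMessage(e)), call. = FALSE))
  }
  roi <- wrap("locate_pleural_line",
              locatePleuralLine(frame, pleuralRowOverride = pleuralRowOverride))
  roi <- wrap("adjust_contrast",
              suppressWarnings(adjustContrast(roi, config)))
  if ("constant_roi" %in% roi@flags) {
    ## no intensity structure to segment: classify the whole ROI by a
    ## mid-scale cut, so a uniformly dark field (no B-lines) scores 0 and a
    ## uniformly bright one (full-width coalescence) scores 100, flagged
    white <- stats::median(pixels(roi)) > 127.5
    nc <- ncol(pixels(roi))
    det <- new("ColumnDetection",
               whiteFraction = rep(as.numeric(white), nc),
               isBline = rep(white, nc),
               nColumns = nc)
    res <- frameBlinePercent(det, patientId(frame), regionId(frame),
                             configDigest(config), flags = roi@flags)
    if (keepIntermediates)
      attr(res, "intermediates") <- list(roi = roi, kmeans = NULL,
                                         asf = NULL, detection = det)
    return(res)
  }
  km <- wrap("kmeans_binarize", kmeansBinarize(roi, config))
  fm <- wrap("asf_filter", asfFilter(km, config))
  det <- wrap("detect_bline_columns", detectBlineColumns(fm, config))
  res <- frameBlinePercent(det, patientId(frame), regionId(frame),
                           configDigest(config), flags = roi@flags)
  if (keepIntermediates)
    attr(res, "intermediates") <- list(roi = roi, kmeans = km, asf = fm,
                                       detection = det)
  res
}
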