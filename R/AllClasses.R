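#' The twelve standard intercostal examination regions
#'
#' Each hemithorax is divided into anterior, lateral and posterior zones
#' relative to the sternum and axillary lines, and each zone into an upper
#' and a lower half, giving twelve regions per patient.
#'
#' @return Character vector of the 12 region identifiers.
#' @examples
#' lusRegions()
#' @export
lusRegions <- function() {
  as.vector(outer(
    outer(c("left", "right"), c("anterior", "lateral", "posterior"),
          paste, sep = "_"),
    c("upper", "lower"), paste, sep = "_"))
}

.checkPixels8bit <- function(px) {
  if (!is.matrix(px) || !is.numeric(px))
    return("pixels must be a numeric matrix")
  if (anyNA(px)) return("pixels must not contain NA")
  if (any(px < 0 | px > 255)) return("intensities must lie in [0, 255]")
  if (any(px != round(px))) return("intensities must be integer-valued")
  NULL
}

#' Ultrasound still frame
#'
#' One grayscale intercostal-space still image (8-bit intensity scale) with
#' acquisition metadata. The skin surface is at row 1; depth increases with
#' the row index.
#'
#' @slot pixels integer-valued matrix, intensities in 0--255.
#' @slot patientId character scalar, `NA` when unknown.
#' @slot regionId one of [lusRegions()], or `NA` when unknown.
#' @slot sourcePath provenance string (file the frame was read from).
#' @export
setClass("UltrasoundFrame",
  representation(pixels = "matrix", patientId = "character",
                 regionId = "character", sourcePath = "character"),
  prototype(patientId = NA_character_, regionId = NA_character_,
            sourcePath = NA_character_))

setValidity("UltrasoundFrame", function(object) {
  msg <- .checkPixels8bit(object@pixels)
  if (!is.null(msg)) return(msg)
  if (nrow(object@pixels) < 32L || ncol(object@pixels) < 32L)
    return("frame must be at least 32 x 32 pixels")
  if (!is.na(object@regionId) && !object@regionId %in% lusRegions())
    return(sprintf("unknown regionId '%s'", object@regionId))
  TRUE
})

#' Sub-pleural region of interest
#'
#' The contiguous block of frame rows strictly below the detected pleural
#' line (plus a safety offset), in which B-lines are sought.
#'
#' @slot pixels integer-valued matrix (sub-matrix of the parent frame).
#' @slot pleuralRow 1-based row index of the pleural line in frame
#'   coordinates.
#' @slot offset number of rows skipped below the pleural line before the ROI
#'   starts.
#' @slot flags character vector of quality flags (e.g. `"constant_roi"` set
#'   by [adjustContrast()] on zero-dynamic-range input).
#' @export
setClass("SubPleuralROI",
  representation(pixels = "matrix", pleuralRow = "integer",
                 offset = "integer", flags = "character"),
  prototype(flags = character()))

setValidity("SubPleuralROI", function(object) {
  msg <- .checkPixels8bit(object@pixels)
  if (!is.null(msg)) return(msg)
  if (length(object@pleuralRow) != 1L || object@pleuralRow < 1L)
    return("pleuralRow must be a positive scalar")
  if (nrow(object@pixels) < 8L)
    return("ROI must retain at least 8 analyzable rows")
  TRUE
})

#' Segmentation configuration
#'
#' Tunable parameters of the B-line segmentation pipeline. Defaults follow
#' the published algorithm: 1--99 percentile contrast stretch, two pixel
#' classes, axial gap closure up to 10 px, and a column flagged as B-line
#' when at least 50% of the pixels in the uppermost 70% of the sub-pleural
#' depth are white.
#'
#' @slot lowPercentile,highPercentile contrast-stretch clip percentiles.
#' @slot kmeansK number of intensity classes (fixed at 2).
#' @slot asfMaxGap largest axial (vertical) gap, in pixels, the alternated
#'   sequential filter must close; the element schedule runs over odd
#'   lengths 3, 5, ..., `asfMaxGap + 1`.
#' @slot whiteFractionThreshold minimum white-pixel fraction for a B-line
#'   column.
#' @slot depthFraction fraction of the ROI depth (from the pleura down) over
#'   which the white fraction is evaluated.
#' @slot randomSeed integer seed for any stochastic fallback (the exact 1-D
#'   2-means step itself is deterministic).
#' @export
setClass("SegmentationConfig",
  representation(lowPercentile = "numeric", highPercentile = "numeric",
                 kmeansK = "integer", asfMaxGap = "integer",
                 whiteFractionThreshold = "numeric",
                 depthFraction = "numeric", randomSeed = "integer"))

setValidity("SegmentationConfig", function(object) {
  if (object@lowPercentile < 0 || object@highPercentile > 100 ||
      object@lowPercentile >= object@highPercentile)
    return("need 0 <= lowPercentile < highPercentile <= 100")
  if (object@kmeansK != 2L)
    return("kmeansK is fixed at 2")
  if (object@asfMaxGap < 1L)
    return("asfMaxGap must be >= 1")
  if (object@whiteFractionThreshold <= 0 || object@whiteFractionThreshold > 1)
    return("whiteFractionThreshold must be in (0, 1]")
  if (object@depthFraction <= 0 || object@depthFraction > 1)
    return("depthFraction must be in (0, 1]")
  TRUE
})

#' @describeIn SegmentationConfig-class Constructor with the published
#'   defaults.
#' @param lowPercentile,highPercentile,asfMaxGap,whiteFractionThreshold,depthFraction,randomSeed
#'   see the corresponding slots.
#' @return A validated `SegmentationConfig`.
#' @examples
#' segmentationConfig()
#' segmentationConfig(whiteFractionThreshold = 0.4)
#' @export
segmentationConfig <- function(lowPercentile = 1, highPercentile = 99,
                               asfMaxGap = 10L,
                               whiteFractionThreshold = 0.5,
                               depthFraction = 0.7,
                               randomSeed = 1L) {
  new("SegmentationConfig",
      lowPercentile = lowPercentile, highPercentile = highPercentile,
      kmeansK = 2L, asfMaxGap = as.integer(asfMaxGap),
      whiteFractionThreshold = whiteFractionThreshold,
      depthFraction = depthFraction, randomSeed = as.integer(randomSeed))
}

#' Binary pixel mask
#'
#' Boolean matrix the same shape as its source ROI, produced either by the
#' 2-means binarization (`stage = "kmeans"`) or by the alternated sequential
#' filter (`stage = "asf"`).
#'
#' @slot pixels logical matrix; `TRUE` is the white (hyperechoic) class.
#' @slot stage producing stage, `"kmeans"` or `"asf"`.
#' @export
setClass("BinaryMask",
  representation(pixels = "matrix", stage = "character"))

setValidity("BinaryMask", function(object) {
  if (!is.logical(object@pixels) || anyNA(object@pixels))
    return("mask pixels must be logical and NA-free")
  if (!object@stage %in% c("kmeans", "asf"))
    return("stage must be 'kmeans' or 'asf'")
  TRUE
})

#' Per-column B-line decision
#'
#' @slot whiteFraction per-column proportion of white pixels within the
#'   configured depth window.
#' @slot isBline per-column logical decision.
#' @slot nColumns ROI width.
#' @export
setClass("ColumnDetection",
  representation(whiteFraction = "numeric", isBline = "logical",
                 nColumns = "integer"))

setValidity("ColumnDetection", function(object) {
  if (length(object@whiteFraction) != object@nColumns ||
      length(object@isBline) != object@nColumns)
    return("whiteFraction and isBline must have length nColumns")
  if (any(object@whiteFraction < 0 | object@whiteFraction > 1))
    return("whiteFraction must lie in [0, 1]")
  TRUE
})

#' Per-frame segmentation result
#'
#' @slot blinePercent percentage in \[0, 100\] of ROI columns flagged as
#'   B-line, carried at full precision.
#' @slot patientId,regionId identifiers (possibly `NA`).
#' @slot configDigest hash of the [SegmentationConfig-class] used.
#' @slot flags quality flags propagated from the pipeline (e.g.
#'   `"constant_roi"`).
#' @export
setClass("FrameResult",
  representation(blinePercent = "numeric", patientId = "character",
                 regionId = "character", configDigest = "character",
                 flags = "character"),
  prototype(patientId = NA_character_, regionId = NA_character_,
            flags = character()))

setValidity("FrameResult", function(object) {
  if (object@blinePercent < 0 || object@blinePercent > 100)
    return("blinePercent must lie in [0, 100]")
  TRUE
})

#' Synthetic phantom specification
#'
#' Describes an ultrasound-like phantom: a bright horizontal pleural line
#' with vertical hyperechoic bands (B-lines) of controlled position, width
#' and penetration depth over a dark background, optionally corrupted by
#' multiplicative log-normal speckle.
#'
#' @slot height,width frame size in pixels.
#' @slot pleuralRow 1-based row at which the pleural line is drawn.
#' @slot pleuralThickness rows occupied by the pleural line.
#' @slot bands data.frame with columns `center`, `width`, `intensity`,
#'   `depth_fraction` (one row per B-line band; overlapping bands coalesce).
#' @slot backgroundIntensity,speckleSigma background gray level and
#'   multiplicative speckle scale (standard deviation of log-intensity).
#' @slot gapRowStart,gapHeight optional axial dropout carved out of every
#'   band (0 = none).
#' @slot lateralBlurSigma optional lateral Gaussian beam-width blur in
#'   pixels (0 = off).
#' @slot seed integer RNG seed; identical spec implies identical frame.
#' @export
setClass("PhantomSpec",
  representation(height = "integer", width = "integer",
                 pleuralRow = "integer", pleuralThickness = "integer",
                 bands = "data.frame", backgroundIntensity = "numeric",
                 speckleSigma = "numeric", gapRowStart = "integer",
                 gapHeight = "integer", lateralBlurSigma = "numeric",
                 seed = "integer"))

setValidity("PhantomSpec", function(object) {
  b <- object@bands
  need <- c("center", "width", "intensity", "depth_fraction")
  if (!all(need %in% names(b)))
    return(paste("bands needs columns", paste(need, collapse = ", ")))
  if (nrow(b) > 0) {
    lo <- b$center - floor(b$width / 2)
    hi <- lo + b$width - 1
    if (any(lo < 1 | hi > object@width))
      return("bands must lie fully inside the frame")
    if (any(b$intensity <= object@backgroundIntensity))
      return("band intensity must exceed backgroundIntensity")
    if (any(b$depth_fraction <= 0 | b$depth_fraction > 1))
      return("band depth_fraction must be in (0, 1]")
  }
  if (object@speckleSigma < 0) return("speckleSigma must be >= 0")
  if (object@pleuralRow < 1 ||
      object@pleuralRow + object@pleuralThickness + 8 > object@height)
    return("pleural line too deep: fewer than 8 sub-pleural rows remain")
  TRUE
})

#' Ground truth attached to a phantom frame
#'
#' @slot columnMask logical per frame column; `TRUE` where a band covers the
#'   column.
#' @slot trueBlinePercent 100 x covered columns / width.
#' @export
setClass("PhantomTruth",
  representation(columnMask = "logical", trueBlinePercent = "numeric"))

setValidity("PhantomTruth", function(object) {
  p <- 100 * sum(object@columnMask) / length(object@columnMask)
  if (abs(p - object@trueBlinePercent) > 1e-9)
    return("trueBlinePercent inconsistent with columnMask")
  TRUE
})

## ---- accessors ----

#' @rdname pixels
#' @export
setMethod("pixels", "UltrasoundFrame", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "SubPleuralROI", function(x) x@pixels)
#' @rdname pixels
#' @export
setMethod("pixels", "BinaryMask", function(x) x@pixels)

#' @rdname pixels
#' @export
setMethod("frameWidth", "UltrasoundFrame", function(x) ncol(x@pixels))
#' @rdname pixels
#' @export
setMethod("frameHeight", "UltrasoundFrame", function(x) nrow(x@pixels))

#' @rdname patientId
#' @export
setMethod("patientId", "UltrasoundFrame", function(x) x@patientId)
#' @rdname patientId
#' @export
setMethod("patientId", "FrameResult", function(x) x@patientId)
#' @rdname patientId
#' @export
setMethod("regionId", "UltrasoundFrame", function(x) x@regionId)
#' @rdname patientId
#' @export
setMethod("regionId", "FrameResult", function(x) x@regionId)

#' @rdname pleuralRow
#' @export
setMethod("pleuralRow", "SubPleuralROI", function(x) x@pleuralRow)

#' @rdname blinePercent
#' @export
setMethod("blinePercent", "FrameResult", function(x) x@blinePercent)

## ---- show methods ----

setMethod("show", "UltrasoundFrame", function(object) {
  cat(sprintf("UltrasoundFrame %d x %d  patient=%s region=%s\n",
              nrow(object@pixels), ncol(object@pixels),
              object@patientId, object@regionId))
  cat(sprintf("  intensity range [%d, %d]\n",
              min(object@pixels), max(object@pixels)))
})

setMethod("show", "SubPleuralROI", function(object) {
  cat(sprintf("SubPleuralROI %d x %d  pleuralRow=%d offset=%d%s\n",
              nrow(object@pixels), ncol(object@pixels), object@pleuralRow,
              object@offset,
              if (length(object@flags))
                paste0("  [", paste(object@flags, collapse = ","), "]")
              else ""))
})

setMethod("show", "SegmentationConfig", function(object) {
  cat(sprintf(paste0(
    "SegmentationConfig: stretch %g-%g%%, k=2, asfMaxGap=%d,\n",
    "  whiteFraction>=%.2f over top %.0f%% of ROI depth\n"),
    object@lowPercentile, object@highPercentile, object@asfMaxGap,
    object@whiteFractionThreshold, 100 * object@depthFraction))
})

setMethod("show", "BinaryMask", function(object) {
  cat(sprintf("BinaryMask %d x %d  stage=%s  white=%.1f%%\n",
              nrow(object@pixels), ncol(object@pixels), object@stage,
              100 * mean(object@pixels)))
})

setMethod("show", "ColumnDetection", function(object) {
  cat(sprintf("ColumnDetection: %d/%d columns flagged as B-line\n",
              sum(object@isBline), object@nColumns))
})

setMethod("show", "FrameResult", function(object) {
  cat(sprintf("FrameResult: bline_percent=%.2f  patient=%s region=%s\n",
              object@blinePercent, object@patientId, object@regionId))
})

setMethod("show", "PhantomSpec", function(object) {
  cat(sprintf(
    "PhantomSpec %d x %d  pleuralRow=%d  %d band(s)  speckle=%.2f seed=%d\n",
    object@height, object@width, object@pleuralRow, nrow(object@bands),
    object@speckleSigma, object@seed))
})

setMethod("show", "PhantomTruth", function(object) {
  cat(sprintf("PhantomTruth: %.2f%% of columns covered\n",
              object@trueBlinePercent))
})
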