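#' Pixel matrix of an image-like object
#'
#' @param x an [UltrasoundFrame-class], [SubPleuralROI-class] or
#'   [BinaryMask-class] object.
#' @return For frames and ROIs an integer matrix with values in 0--255; for
#'   masks a logical matrix.
#' @export
setGeneric("pixels", function(x) standardGeneric("pixels"))

#' @rdname pixels
#' @export
setGeneric("frameWidth", function(x) standardGeneric("frameWidth"))

#' @rdname pixels
#' @export
setGeneric("frameHeight", function(x) standardGeneric("frameHeight"))

#' Patient and region identifiers
#'
#' @param x an object carrying acquisition metadata.
#' @return A character scalar (possibly `NA`).
#' @export
setGeneric("patientId", function(x) standardGeneric("patientId"))

#' @rdname patientId
#' @export
setGeneric("regionId", function(x) standardGeneric("regionId"))

#' Row of the detected pleural line
#'
#' @param x a [SubPleuralROI-class].
#' @return 1-based row index of the pleural line in frame coordinates.
#' @export
setGeneric("pleuralRow", function(x) standardGeneric("pleuralRow"))

#' Per-frame B-line percentage
#'
#' @param x a [FrameResult-class].
#' @return Numeric scalar in \[0, 100\], full precision.
#' @export
setGeneric("blinePercent", function(x) standardGeneric("blinePercent"))
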