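#' Read an ultrasound frame from PNG or TIFF
#'
#' Decodes an 8-bit grayscale image (the canonical storage format). RGB
#' images are collapsed to luminance by the ITU-R 601 transform
#' (0.299 R + 0.587 G + 0.114 B); higher bit depths are rescaled linearly
#' to 0--255. An alpha channel, if present, is ignored.
#'
#' @param path PNG (`.png`) or TIFF (`.tif`, `.tiff`) file.
#' @param patientId,regionId optional metadata attached to the frame.
#' @return An [UltrasoundFrame-class].
#' @seealso [readManifest()] for batch reading with metadata sidecar.
#' @export
readFrame <- function(path, patientId = NA_character_,
                      regionId = NA_character_) {
  if (!file.exists(path))
    stop("input error: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path, all = TRUE),
    stop("unsupported-format error: cannot read '.", ext,
         "' files; supply PNG or TIFF stills"))
  if (is.list(img)) {                      # multi-frame TIFF container
    if (length(img) > 1L)
      stop("unsupported-format error: multi-frame cine container; ",
           "export individual still frames and retry")
    img <- img[[1L]]
  }
  if (length(dim(img)) == 3L) {
    nc <- dim(img)[3L]
    if (nc >= 3L) {
      img <- 0.299 * img[, , 1L] + 0.587 * img[, , 2L] + 0.114 * img[, , 3L]
    } else {
      img <- img[, , 1L]                   # gray (+alpha)
    }
  }
  if (length(img) == 0L)
    stop("input error: empty image: ", path)
  ## readPNG/readTIFF normalize to [0,1] whatever the bit depth, so a single
  ## multiplication realizes the linear rescale to the 8-bit range.
  px <- matrix(as.integer(round(img * 255)), nrow = nrow(img))
  new("UltrasoundFrame", pixels = px, patientId = as.character(patientId),
      regionId = as.character(regionId), sourcePath = path)
}

#' Write a frame as 8-bit grayscale PNG
#'
#' Round-trips losslessly with [readFrame()] for 8-bit input.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
writeFrame <- function(frame, path) {
  stopifnot(is(frame, "UltrasoundFrame"))
  png::writePNG(pixels(frame) / 255, target = path)
  invisible(path)
}

#' Read a frame manifest
#'
#' The manifest is a CSV with columns `patient_id`, `region_id`, `path` and
#' optionally `pleural_row_override` (blank for automatic pleural-line
#' detection). Relative paths are resolved against the manifest's directory.
#'
#' @param path manifest CSV.
#' @return A data.frame with one row per frame.
#' @export
readManifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("patient_id", "region_id", "path")
  if (!all(need %in% names(m)))
    stop("input error: manifest must have columns ",
         paste(need, collapse = ", "))
  if (!"pleural_row_override" %in% names(m))
    m$pleural_row_override <- NA_integer_
  m$pleural_row_override <- suppressWarnings(
    as.integer(m$pleural_row_override))
  rel <- !grepl("^(/|[A-Za-z]:)", m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  m
}

#' Locate the pleural line and extract the sub-pleural ROI
#'
#' The pleural line is the dominant horizontal reflector in linear-probe
#' transverse scans, so it is located as the row with maximal mean intensity
#' within the top `searchFraction` of the frame (ties broken toward the
#' shallowest row, anchoring a thick pleural band at its top). The ROI is
#' the block of rows starting `offset` rows below the detected line and
#' running to the bottom of the frame.
#'
#' @param frame an [UltrasoundFrame-class].
#' @param searchFraction fraction of the frame depth searched, in (0, 1].
#' @param offset rows skipped below the pleural line before the ROI starts.
#' @param pleuralRowOverride manual 1-based pleural row; bypasses detection
#'   (used for atypical frames via the manifest).
#' @return A [SubPleuralROI-class].
#' @examples
#' f <- generatePhantomFrame(phantomSpec(seed = 1))$frame
#' locatePleuralLine(f)
#' @export
locatePleuralLine <- function(frame, searchFraction = 0.4, offset = 2L,
                              pleuralRowOverride = NULL) {
  stopifnot(is(frame, "UltrasoundFrame"))
  if (searchFraction <= 0 || searchFraction > 1)
    stop("searchFraction must be in (0, 1]")
  offset <- as.integer(offset)
  if (offset < 0L) stop("offset must be >= 0")
  px <- pixels(frame)
  h <- nrow(px)
  if (is.null(pleuralRowOverride) || is.na(pleuralRowOverride)) {
    nsearch <- max(1L, as.integer(ceiling(searchFraction * h)))
    prow <- which.max(rowMeans(px[seq_len(nsearch), , drop = FALSE]))
  } else {
    prow <- as.integer(pleuralRowOverride)
    if (prow < 1L || prow > h) stop("pleural row override outside frame")
  }
  start <- prow + offset
  if (h - start + 1L < 8L)
    stop("degenerate-ROI error: pleural line at row ", prow,
         " leaves fewer than 8 analyzable rows")
  new("SubPleuralROI", pixels = px[start:h, , drop = FALSE],
      pleuralRow = as.integer(prow), offset = offset)
}
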