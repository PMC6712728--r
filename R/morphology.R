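## Binary morphology with vertical (axial) line structuring elements.
##
## A centered vertical line element of odd length L = 2k + 1 decomposes all
## four operations into independent per-column 1-D window computations, so
## everything here is vectorized over the whole mask via padded cumulative
## sums. Border convention: erosion treats pixels outside the image as
## white, dilation treats them as black (the convention of mainstream
## image-morphology toolboxes), so neither opening nor closing erodes
## image borders.

## windowed white count per pixel: number of TRUE within rows [i-k, i+k]
## clipped to the image, plus the number of out-of-image rows when `padWhite`
.windowCount <- function(m, k, padWhite) {
  h <- nrow(m)
  i <- seq_len(h)
  S <- apply(m, 2L, cumsum)                 # S[j, ] = whites in rows 1..j
  if (!is.matrix(S)) S <- matrix(S, nrow = h)
  P <- rbind(0L, S)                         # P[j + 1, ] = S[j], S[0] = 0
  cnt <- P[pmin(i + k, h) + 1L, , drop = FALSE] -
         P[pmax(i - k - 1L, 0L) + 1L, , drop = FALSE]
  if (padWhite) {
    outside <- pmax(k - (i - 1L), 0L) + pmax(k - (h - i), 0L)
    cnt <- cnt + outside
  }
  cnt
}

.erodeVert <- function(m, len) {
  k <- (len - 1L) %/% 2L
  if (k == 0L) return(m)
  .windowCount(m, k, padWhite = TRUE) == len
}

.dilateVert <- function(m, len) {
  k <- (len - 1L) %/% 2L
  if (k == 0L) return(m)
  .windowCount(m, k, padWhite = FALSE) > 0L
}

.openVert <- function(m, len) .dilateVert(.erodeVert(m, len), len)
.closeVert <- function(m, len) .erodeVert(.dilateVert(m, len), len)

#' Alternated sequential filter with axial line elements
#'
#' Applies morphological opening followed by closing with vertical line
#' structuring elements of increasing odd length (3, 5, ...,
#' `asfMaxGap + 1`). The openings remove white objects shorter (axially)
#' than the element -- isolated specks and the 1-pixel-tall horizontal
#' bridges that spuriously connect adjacent B-lines -- while the closings
#' fill axial gaps inside a column; the terminal closing spans
#' `asfMaxGap + 1` pixels and therefore bridges gaps of up to `asfMaxGap`
#' pixels.
#'
#' @param mask a [BinaryMask-class] produced by [kmeansBinarize()].
#' @param config a [SegmentationConfig-class]; `asfMaxGap` sets the
#'   schedule.
#' @return A [BinaryMask-class] with `stage = "asf"`.
#' @examples
#' roi <- new("SubPleuralROI",
#'   pixels = matrix(c(rep(200L, 40), rep(10L, 60)), 20, 5),
#'   pleuralRow = 1L, offset = 0L)
#' m <- kmeansBinarize(roi, segmentationConfig())
#' asfFilter(m, segmentationConfig())
#' @export
asfFilter <- function(mask, config = segmentationConfig()) {
  stopifnot(is(mask, "BinaryMask"), is(config, "SegmentationConfig"))
  if (mask@stage != "kmeans")
    stop("asfFilter expects a mask from the kmeans stage, got '",
         mask@stage, "'")
  m <- pixels(mask)
  for (len in seq(3L, config@asfMaxGap + 1L, by = 2L)) {
    m <- .openVert(m, len)
    m <- .closeVert(m, len)
  }
  new("BinaryMask", pixels = m, stage = "asf")
}
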