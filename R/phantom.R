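#' Construct a phantom specification
#'
#' Convenience constructor for [PhantomSpec-class] with realistic defaults:
#' a 128 x 60 frame, pleural line at row 20, dark (20/255) background, and
#' B-line bands extending from the pleura to the bottom of the frame
#' without fading, as B-lines do.
#'
#' @param height,width frame size in pixels.
#' @param pleuralRow 1-based row of the pleural line.
#' @param pleuralThickness rows occupied by the line.
#' @param bands data.frame with columns `center`, `width`, `intensity`,
#'   `depth_fraction`; zero rows for a B-line-free phantom.
#' @param backgroundIntensity background gray level (0--255).
#' @param speckleSigma multiplicative log-normal speckle scale (0 = none).
#' @param gapRowStart,gapHeight optional axial dropout carved out of every
#'   band (0 = none); used to exercise gap closure.
#' @param lateralBlurSigma optional lateral Gaussian beam-width blur
#'   (pixels, 0 = off).
#' @param seed RNG seed: identical spec gives a bit-identical frame.
#' @return A validated [PhantomSpec-class].
#' @export
phantomSpec <- function(height = 128L, width = 60L, pleuralRow = 20L,
                        pleuralThickness = 2L,
                        bands = data.frame(center = numeric(),
                                           width = numeric(),
                                           intensity = numeric(),
                                           depth_fraction = numeric()),
                        backgroundIntensity = 20, speckleSigma = 0,
                        gapRowStart = 0L, gapHeight = 0L,
                        lateralBlurSigma = 0, seed = 1L) {
  new("PhantomSpec", height = as.integer(height), width = as.integer(width),
      pleuralRow = as.integer(pleuralRow),
      pleuralThickness = as.integer(pleuralThickness),
      bands = bands, backgroundIntensity = backgroundIntensity,
      speckleSigma = speckleSigma, gapRowStart = as.integer(gapRowStart),
      gapHeight = as.integer(gapHeight),
      lateralBlurSigma = lateralBlurSigma, seed = as.integer(seed))
}

#' Generate a synthetic ultrasound-like frame with known ground truth
#'
#' Draws a uniform background, a bright horizontal pleural line, and
#' vertical hyperechoic bands emulating B-lines (each running from the
#' pleural line down to `depth_fraction` of the frame), optionally carves
#' an axial dropout out of the bands, applies optional lateral Gaussian
#' blur, and finally multiplies by log-normal speckle, clipping to
#' \[0, 255\]. Overlapping bands coalesce: the ground-truth column mask is
#' the union of band columns, so adjacent bands with zero spacing form one
#' contiguous truth interval. Speckle never alters the truth.
#'
#' @param spec a [PhantomSpec-class].
#' @return A list with elements `frame` ([UltrasoundFrame-class]) and
#'   `truth` ([PhantomTruth-class]).
#' @examples
#' ph <- generatePhantomFrame(phantomSpec(
#'   bands = data.frame(center = c(15, 40), width = c(6, 10),
#'                      intensity = 200, depth_fraction = 1),
#'   speckleSigma = 0.1, seed = 7))
#' ph$truth
#' @export
generatePhantomFrame <- function(spec) {
  stopifnot(is(spec, "PhantomSpec"))
  h <- spec@height; w <- spec@width
  img <- matrix(spec@backgroundIntensity, h, w)
  colMask <- logical(w)
  b <- spec@bands
  if (nrow(b) > 0) {
    for (i in seq_len(nrow(b))) {
      lo <- b$center[i] - floor(b$width[i] / 2)
      cols <- seq(lo, length.out = b$width[i])
      rows <- seq(spec@pleuralRow,
                  max(spec@pleuralRow, floor(b$depth_fraction[i] * h)))
      img[rows, cols] <- pmax(img[rows, cols], b$intensity[i])
      colMask[cols] <- TRUE
    }
    if (spec@gapHeight > 0L) {
      gap <- seq(spec@gapRowStart,
                 length.out = spec@gapHeight)
      gap <- gap[gap >= 1 & gap <= h]
      img[gap, colMask] <- spec@backgroundIntensity
    }
  }
  prow <- seq(spec@pleuralRow, length.out = spec@pleuralThickness)
  img[prow, ] <- 255
  if (spec@lateralBlurSigma > 0) {
    half <- ceiling(3 * spec@lateralBlurSigma)
    kern <- stats::dnorm(-half:half, sd = spec@lateralBlurSigma)
    kern <- kern / sum(kern)
    pad <- img[, c(rep(1L, half), seq_len(w), rep(w, half)), drop = FALSE]
    img <- t(apply(pad, 1L, function(r)
      stats::convolve(r, rev(kern), type = "filter")))
  }
  if (spec@speckleSigma > 0) {
    set.seed(spec@seed)
    img <- img * exp(matrix(stats::rnorm(h * w, 0, spec@speckleSigma), h, w))
  }
  img <- pmin(pmax(round(img), 0), 255)
  frame <- new("UltrasoundFrame",
               pixels = matrix(as.integer(img), h, w),
               sourcePath = "phantom")
  truth <- new("PhantomTruth", columnMask = colMask,
               trueBlinePercent = 100 * sum(colMask) / w)
  list(frame = frame, truth = truth)
}

#' Simulate a subjects-by-raters score table
#'
#' Additive two-way model `score(i, j) = mu + subject_i + rater_j + eps_ij`
#' with independent normal components, for exercising the agreement ICC:
#' its theoretical two-way agreement ICC is
#' `var_subject / (var_subject + var_rater + var_error)` and is attached as
#' the `theoretical_icc` attribute.
#'
#' @param nSubjects number of subjects (>= 5).
#' @param varComponents length-3 numeric: subject, rater and error
#'   variances (all >= 0).
#' @param nRaters number of raters.
#' @param mu grand mean.
#' @param seed RNG seed.
#' @return Numeric matrix `nSubjects x nRaters` with attributes
#'   `theoretical_icc` (the population component ratio) and `realized_icc`
#'   (the same ratio computed from the sample variances of the components
#'   actually drawn). With few raters the rater variance is estimated from
#'   only `nRaters - 1` degrees of freedom however many subjects there
#'   are, so the agreement ICC estimate concentrates around the realized
#'   ratio, not the population one.
#' @export
generateRaterTable <- function(nSubjects, varComponents, nRaters = 2L,
                               mu = 20, seed = 1L) {
  stopifnot(length(varComponents) == 3L, all(varComponents >= 0),
            nSubjects >= 5L, nRaters >= 2L)
  set.seed(seed)
  subj <- stats::rnorm(nSubjects, 0, sqrt(varComponents[1L]))
  rat <- stats::rnorm(nRaters, 0, sqrt(varComponents[2L]))
  eps <- matrix(stats::rnorm(nSubjects * nRaters, 0,
                             sqrt(varComponents[3L])),
                nSubjects, nRaters)
  m <- mu + outer(subj, rep(1, nRaters)) + outer(rep(1, nSubjects), rat) + eps
  dimnames(m) <- list(NULL, paste0("rater", seq_len(nRaters)))
  tot <- sum(varComponents)
  attr(m, "theoretical_icc") <- if (tot == 0) 1 else varComponents[1L] / tot
  rtot <- stats::var(subj) + stats::var(rat) + stats::var(as.vector(eps))
  attr(m, "realized_icc") <- if (rtot == 0) 1 else stats::var(subj) / rtot
  m
}
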