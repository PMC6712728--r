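#' Strength label for an intraclass correlation
#'
#' Maps an ICC point estimate to the conventional agreement labels with
#' lower-inclusive cut-points at 0.30, 0.50, 0.70 and 0.90 (so the labels
#' partition the whole range with no gaps).
#'
#' @param icc numeric scalar.
#' @return One of `"poor"`, `"fair"`, `"moderate"`, `"strong"`,
#'   `"almost_perfect"`.
#' @export
iccStrengthLabel <- function(icc) {
  stopifnot(is.numeric(icc), length(icc) == 1L, !is.na(icc))
  if (icc < 0.30) "poor"
  else if (icc < 0.50) "fair"
  else if (icc < 0.70) "moderate"
  else if (icc < 0.90) "strong"
  else "almost_perfect"
}

#' Two-way absolute-agreement intraclass correlation
#'
#' Single-measure ICC from the two-way random-effects model with absolute
#' agreement -- systematic rater offsets count against agreement, unlike
#' the consistency form. Mean squares come from the standard two-way
#' decomposition (subjects, raters, error); the 95% confidence interval
#' uses the F-based method of the two-way agreement model. The
#' average-measure coefficient is available behind `averageMeasure = TRUE`.
#'
#' @param table numeric matrix or data.frame, subjects x raters, complete
#'   (no missing cells; no imputation is attempted), >= 5 subjects and
#'   >= 2 raters.
#' @param alpha confidence level is `1 - alpha`.
#' @param averageMeasure if `TRUE` return the average-measure ICC.
#' @return A list of class `"lusICC"` with `icc`, `ci_low`, `ci_high`,
#'   `model`, and `strength_label` from [iccStrengthLabel()].
#' @examples
#' rt <- generateRaterTable(50, c(4, 1, 1), seed = 1)
#' iccAgreement(rt)
#' @export
iccAgreement <- function(table, alpha = 0.05, averageMeasure = FALSE) {
  m <- as.matrix(table)
  if (anyNA(m))
    stop("incomplete-design error: missing cell(s); no imputation is done")
  n <- nrow(m); k <- ncol(m)
  if (n < 5L) stop("need at least 5 subjects")
  if (k < 2L) stop("need at least 2 raters")
  grand <- mean(m)
  rm_ <- rowMeans(m); cm <- colMeans(m)
  SSR <- k * sum((rm_ - grand)^2)            # subjects
  SSC <- n * sum((cm - grand)^2)             # raters
  SST <- sum((m - grand)^2)
  SSE <- SST - SSR - SSC
  MSR <- SSR / (n - 1)
  MSC <- SSC / (k - 1)
  MSE <- SSE / ((n - 1) * (k - 1))
  if (MSR + (k - 1) * MSE + k / n * (MSC - MSE) == 0) {
    icc <- 0
  } else {
    icc <- if (averageMeasure)
      (MSR - MSE) / (MSR + (MSC - MSE) / n)
    else
      (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  }
  if (MSE == 0 && MSC == 0) {                # identical raters
    ci <- c(icc, icc)
  } else {
    a <- k * icc / (n * (1 - icc))
    b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
    if (!is.finite(a) || !is.finite(b)) {
      ci <- c(icc, icc)
    } else {
      v <- (a * MSC + b * MSE)^2 /
        ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
      FL <- stats::qf(1 - alpha / 2, n - 1, v)
      FU <- stats::qf(1 - alpha / 2, v, n - 1)
      lower <- n * (MSR - FL * MSE) /
        (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
      upper <- n * (FU * MSR - MSE) /
        (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
      if (averageMeasure) {
        lower <- lower * k / (1 + (k - 1) * lower)
        upper <- upper * k / (1 + (k - 1) * upper)
      }
      ci <- c(lower, upper)
    }
  }
  structure(list(icc = icc, ci_low = ci[1L], ci_high = ci[2L],
                 model = sprintf("two-way, absolute agreement, %s measure",
                                 if (averageMeasure) "average" else "single"),
                 n_subjects = n, n_raters = k,
                 strength_label = iccStrengthLabel(icc)),
            class = "lusICC")
}

#' @export
print.lusICC <- function(x, ...) {
  cat(sprintf("ICC (%s): %.3f  95%% CI [%.3f, %.3f]  agreement: %s\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$strength_label))
  invisible(x)
}
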