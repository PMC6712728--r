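#' Spearman rank correlation with midrank tie correction
#'
#' Computes r as the Pearson correlation of the midrank vectors (the
#' tie-corrected definition) and a two-sided p-value from the t
#' approximation with n - 2 degrees of freedom. An exact Monte-Carlo
#' permutation p-value is available behind `pMethod = "permutation"`.
#'
#' @param x,y paired observations, n >= 4.
#' @param pMethod `"t"` (default) or `"permutation"`.
#' @param nPerm,seed permutation count and seed when
#'   `pMethod = "permutation"`.
#' @return A list of class `"lusCorrelation"` with `r`, `p_value`, `n` and
#'   `tie_corrected` (always `TRUE`: midranks are used).
#' @examples
#' t1 <- lusTable1()
#' spearmanCorrelation(t1$QLUSS, t1$qLUSS)$r   # 0.772
#' @export
spearmanCorrelation <- function(x, y, pMethod = c("t", "permutation"),
                                nPerm = 10000L, seed = 1L) {
  pMethod <- match.arg(pMethod)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 4L) stop("need n >= 4 pairs")
  if (anyNA(x) || anyNA(y)) stop("x and y must be NA-free")
  if (length(unique(x)) < 2L || length(unique(y)) < 2L)
    stop("undefined-correlation error: constant vector")
  rx <- rank(x); ry <- rank(y)
  r <- stats::cor(rx, ry)
  if (pMethod == "t") {
    tstat <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  } else {
    set.seed(seed)
    ref <- replicate(nPerm, stats::cor(rx, sample(ry)))
    p <- (1 + sum(abs(ref) >= abs(r) - 1e-12)) / (nPerm + 1)
  }
  structure(list(r = r, p_value = p, n = n, tie_corrected = TRUE,
                 p_method = pMethod),
            class = "lusCorrelation")
}

#' @export
print.lusCorrelation <- function(x, ...) {
  cat(sprintf("Spearman rank correlation: r = %.3f, p = %.4g (n = %d, %s)\n",
              x$r, x$p_value, x$n,
              if (x$p_method == "t") "t approximation" else "permutation"))
  invisible(x)
}

#' Compare two dependent overlapping correlations
#'
#' Tests whether two correlations sharing a variable (r12 = cor(1,2) and
#' r13 = cor(1,3)) differ, by Hittner, May and Silver's modification of
#' Dunn and Clark's z: both correlations are Fisher-z transformed and their
#' covariance is evaluated at the backtransformed average of the two
#' transforms.
#'
#' @param r12,r13 the correlations being compared (share variable 1).
#' @param r23 correlation between variables 2 and 3.
#' @param n sample size (>= 4).
#' @return A list of class `"lusCorComparison"` with `z_statistic` and the
#'   two-sided normal `p_value`.
#' @examples
#' compareDependentCorrelations(0.772, 0.105, -0.083, 12)
#' @export
compareDependentCorrelations <- function(r12, r13, r23, n) {
  if (n < 4L) stop("parameter error: need n >= 4")
  if (any(abs(c(r12, r13, r23)) > 1))
    stop("parameter error: correlations must lie in [-1, 1]")
  if (any(abs(c(r12, r13)) == 1))
    stop("transform-overflow error: |r| = 1 cannot be Fisher-transformed")
  z12 <- atanh(r12); z13 <- atanh(r13)
  rbar <- tanh((z12 + z13) / 2)              # backtransformed average
  cv <- (r23 * (1 - 2 * rbar^2) -
           0.5 * rbar^2 * (1 - 2 * rbar^2 - r23^2)) / (1 - rbar^2)^2
  z <- (z12 - z13) * sqrt(n - 3) / sqrt(2 - 2 * cv)
  structure(list(r12 = r12, r13 = r13, r23 = r23, n = n,
                 z_statistic = z, p_value = 2 * stats::pnorm(-abs(z))),
            class = "lusCorComparison")
}

#' @export
print.lusCorComparison <- function(x, ...) {
  cat(sprintf(
    "Dependent-correlation comparison (Hittner-May-Silver z):\n  r12 = %.3f vs r13 = %.3f (r23 = %.3f, n = %d): z = %.3f, p = %.4g\n",
    x$r12, x$r13, x$r23, x$n, x$z_statistic, x$p_value))
  invisible(x)
}

#' Power of the two-sided test of zero correlation
#'
#' Fisher-z approximation with the small-sample bias term: the hypothesized
#' correlation maps to `z_r = atanh(r) + r / (2(n - 1))`; the critical
#' correlation comes from the t quantile at n - 2 df,
#' `r_c = sqrt(t^2 / (t^2 + n - 2))`; power is
#' `Phi((z_r - atanh(r_c)) * sqrt(n - 3))`.
#'
#' @param r hypothesized correlation, 0 < r < 1.
#' @param n sample size (>= 4).
#' @param alpha two-sided significance level.
#' @return A list of class `"lusPower"` with the `power` and its inputs.
#' @examples
#' powerCorrelation(0.8, 12)$power    # 0.924
#' @export
powerCorrelation <- function(r, n, alpha = 0.05) {
  if (r <= 0 || r >= 1) stop("parameter error: need 0 < r < 1")
  if (n < 4L) stop("parameter error: need n >= 4")
  if (alpha <= 0 || alpha >= 1) stop("parameter error: alpha in (0, 1)")
  zr <- atanh(r) + r / (2 * (n - 1))
  tq <- stats::qt(1 - alpha / 2, n - 2)
  rc <- sqrt(tq^2 / (tq^2 + n - 2))
  pw <- stats::pnorm((zr - atanh(rc)) * sqrt(n - 3))
  structure(list(r = r, n = n, alpha = alpha, power = pw),
            class = "lusPower")
}

#' @export
print.lusPower <- function(x, ...) {
  cat(sprintf(
    "Power of the two-sided zero-correlation test: %.3f (r = %g, n = %d, alpha = %g)\n",
    x$power, x$r, x$n, x$alpha))
  invisible(x)
}
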