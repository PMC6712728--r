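test_that("OLS fit recovers exact lines and matches the lm oracle", {
  x <- c(1, 2, 3, 4, 5, 6)
  f <- suppressWarnings(fitSLR(x, 2 * x + 1))  # lm flags the perfect fit
  expect_equal(f$r_squared, 1)
  expect_equal(f$slope, 2)
  expect_equal(f$intercept, 1)
  set.seed(3)
  y <- 0.5 * x + rnorm(6)
  f2 <- fitSLR(x, y)
  sm <- summary(lm(y ~ x))
  expect_equal(f2$r_squared, sm$r.squared)
  expect_equal(f2$p_value, sm$coefficients[2, 4])
  expect_error(fitSLR(rep(1, 6), y), "singular-design")
})

test_that("all robust estimators agree with OLS on outlier-free lines", {
  x <- c(0, 1, 2, 3, 4, 5, 6, 7, 8, 9)
  y <- 3 + 0.8 * x
  for (est in c("huber", "lms", "lts", "lad", "s", "mm")) {
    f <- fitRobust(x, y, est)
    expect_equal(f$slope, 0.8, tolerance = 1e-6)
    expect_equal(f$intercept, 3, tolerance = 1e-6)
  }
})

test_that("high-breakdown fits ignore a gross outlier that drags OLS", {
  x <- 1:12
  y <- as.numeric(x)
  y[1] <- 60                             # gross outlier
  for (est in c("lts", "lms", "lad")) {
    f <- fitRobust(x, y, est)
    expect_equal(f$slope, 1, tolerance = 1e-9)
  }
  expect_gt(abs(fitSLR(x, y)$slope - 1), 0.2)
})

test_that("exhaustive LTS is invariant to order and seed, and optimal", {
  t1 <- lusTable1()
  x <- t1$QLUSS; y <- t1$EVLW
  f <- fitRobust(x, y, "lts", seed = 1L)
  perm <- c(5, 2, 12, 7, 1, 9, 3, 11, 4, 8, 6, 10)
  fp <- fitRobust(x[perm], y[perm], "lts", seed = 99L)
  expect_equal(fp$slope, f$slope)
  expect_equal(fp$intercept, f$intercept)
  expect_equal(fp$r_squared, f$r_squared)
  expect_equal(f$subset_size, 7L)        # floor((12 + 2 + 1)/2)
  # optimality: criterion no worse than MASS::lqs's stochastic search
  lq <- MASS::lqs(y ~ x, method = "lts")
  critOf <- function(a, b) sum(sort((y - a - b * x)^2)[1:7])
  expect_lte(critOf(f$intercept, f$slope),
             critOf(coef(lq)[1], coef(lq)[2]) + 1e-9)
})

test_that("trimmed R-squared is computed on the retained observations", {
  t1 <- lusTable1()
  f <- fitRobust(t1$QLUSS, t1$EVLW, "lts")
  keep <- f$retained
  ols <- lm(t1$EVLW[keep] ~ t1$QLUSS[keep])
  expect_equal(f$r_squared, summary(ols)$r.squared)
  expect_match(f$r_squared_definition, "retained")
  expect_true(!is.null(f$r_squared_all))
})

test_that("Spearman r uses midranks and the t-approximate p-value", {
  t1 <- lusTable1()
  s <- spearmanCorrelation(t1$QLUSS, t1$qLUSS)
  ct <- cor.test(t1$QLUSS, t1$qLUSS, method = "spearman", exact = FALSE)
  expect_equal(s$r, unname(ct$estimate))
  expect_equal(spearmanCorrelation(t1$QLUSS, t1$QLUSS)$r, 1)
  # tied data against an independent midrank oracle
  set.seed(10)
  for (i in 1:10) {
    x <- sample(1:5, 12L, replace = TRUE)
    y <- sample(1:4, 12L, replace = TRUE)
    if (length(unique(x)) < 2L || length(unique(y)) < 2L) next
    expect_equal(spearmanCorrelation(x, y)$r,
                 cor(midrankOracle(x), midrankOracle(y)))
  }
  expect_error(spearmanCorrelation(rep(2, 12), 1:12),
               "undefined-correlation")
})

test_that("permutation p-value agrees with the t approximation broadly", {
  set.seed(4)
  x <- rnorm(12); y <- x + rnorm(12, 0, 0.8)
  pt_ <- spearmanCorrelation(x, y)$p_value
  pp <- spearmanCorrelation(x, y, pMethod = "permutation",
                            nPerm = 4000L, seed = 2L)$p_value
  expect_lt(abs(pt_ - pp), 0.05)
})

test_that("dependent-correlation z is antisymmetric and null at equality", {
  eq <- compareDependentCorrelations(0.6, 0.6, 0.3, 20)
  expect_equal(eq$z_statistic, 0)
  expect_equal(eq$p_value, 1)
  a <- compareDependentCorrelations(0.7, 0.2, 0.3, 15)
  b <- compareDependentCorrelations(0.2, 0.7, 0.3, 15)
  expect_equal(a$z_statistic, -b$z_statistic)
  expect_equal(a$p_value, b$p_value)
  # more data, same correlations: stronger evidence
  expect_lt(compareDependentCorrelations(0.7, 0.2, 0.3, 60)$p_value,
            a$p_value)
  expect_error(compareDependentCorrelations(1, 0.5, 0.3, 12),
               "transform-overflow")
})

test_that("correlation-test power is monotone in n and r", {
  pw <- function(r, n) powerCorrelation(r, n)$power
  ns <- c(8, 10, 12, 16, 24, 40)
  expect_true(all(diff(vapply(ns, function(n) pw(0.6, n), 1)) > 0))
  rs <- c(0.3, 0.5, 0.7, 0.9)
  expect_true(all(diff(vapply(rs, function(r) pw(r, 12), 1)) > 0))
  expect_error(powerCorrelation(1.2, 12), "parameter error")
})

test_that("ICC mean squares match the aov decomposition", {
  rt <- generateRaterTable(40L, c(4, 1, 1), nRaters = 3L, seed = 6L)
  r <- iccAgreement(rt)
  d <- data.frame(score = as.vector(rt),
                  subj = factor(rep(seq_len(nrow(rt)), ncol(rt))),
                  rater = factor(rep(seq_len(ncol(rt)), each = nrow(rt))))
  ms <- anova(aov(score ~ subj + rater, data = d))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  n <- nrow(rt); k <- ncol(rt)
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(r$icc, icc_oracle)
  expect_true(r$ci_low <= r$icc && r$icc <= r$ci_high)
})

test_that("agreement ICC penalizes a systematic rater offset", {
  set.seed(2)
  base <- rnorm(30, 10, 2)
  m <- cbind(base, base + 3)
  r <- iccAgreement(m)
  expect_lt(r$icc, 1)
  # consistency-type ICC of the same data is exactly 1
  n <- nrow(m); k <- ncol(m)
  grand <- mean(m)
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  mse <- (sum((m - grand)^2) - k * sum((rowMeans(m) - grand)^2) -
            n * sum((colMeans(m) - grand)^2)) / ((n - 1) * (k - 1))
  expect_equal((msr - mse) / (msr + (k - 1) * mse), 1)
})

test_that("identical raters give ICC 1 labelled almost_perfect", {
  m <- cbind(1:10, 1:10)
  r <- iccAgreement(m)
  expect_equal(r$icc, 1)
  expect_equal(r$strength_label, "almost_perfect")
  expect_equal(c(r$ci_low, r$ci_high), c(1, 1))
})

test_that("strength labels partition the range, lower bound inclusive", {
  expect_equal(iccStrengthLabel(0.299), "poor")
  expect_equal(iccStrengthLabel(0.30), "fair")
  expect_equal(iccStrengthLabel(0.499), "fair")
  expect_equal(iccStrengthLabel(0.50), "moderate")
  expect_equal(iccStrengthLabel(0.70), "strong")
  expect_equal(iccStrengthLabel(0.899), "strong")
  expect_equal(iccStrengthLabel(0.90), "almost_perfect")
  expect_equal(iccStrengthLabel(-0.4), "poor")
})

test_that("simulated two-way tables recover their realized ICC", {
  rt <- generateRaterTable(200L, c(4, 1, 1), seed = 1L)
  r <- iccAgreement(rt)
  expect_lt(abs(r$icc - attr(rt, "realized_icc")), 0.05)
  expect_equal(attr(rt, "theoretical_icc"), 4 / 6)
  # no subject signal: ICC near zero
  rt0 <- generateRaterTable(500L, c(0, 1, 1), seed = 2L)
  expect_lt(abs(iccAgreement(rt0)$icc), 0.1)
  # perfect subject signal: identical raters
  rt1 <- generateRaterTable(50L, c(1, 0, 0), seed = 3L)
  expect_equal(iccAgreement(rt1)$icc, 1)
})

test_that("incomplete rater designs are rejected, not imputed", {
  m <- cbind(1:10, c(1:9, NA))
  expect_error(iccAgreement(m), "incomplete-design")
})
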