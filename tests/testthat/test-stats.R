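test_that("quality gate applies the inclusive signal-strength and artifact rules", {
  scan <- as_scan(matrix(1, 50, 50), pitch = 10, signal_strength = 7)
  expect_true(quality_gate(scan, artifact_fraction = 0.10)$pass)
  low <- as_scan(matrix(1, 50, 50), pitch = 10, signal_strength = 6)
  g <- quality_gate(low)
  expect_false(g$pass); expect_match(g$reason, "signal strength")
  g2 <- quality_gate(scan, artifact_fraction = 0.11)
  expect_false(g2$pass); expect_match(g2$reason, "artifact fraction")
  broken <- scan; broken$signal_strength <- NA_integer_
  expect_error(quality_gate(broken), "missing")
})

test_that("Wilcoxon exact branch matches brute-force enumeration", {
  res <- wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))
  expect_equal(res$W, 15)
  expect_equal(res$p, 0.0625)
  expect_equal(res$method, "exact")
  # independent enumeration oracle for arbitrary tied/untied data
  set.seed(31)
  for (rep in 1:10) {
    d <- round(stats::rnorm(8), 1); d <- d[d != 0]
    n <- length(d); r <- rank(abs(d)); W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    p_oracle <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
    expect_equal(wilcoxon_signed_rank(d, rep(0, n))$p, p_oracle)
  }
  # agreement with the reference implementation on untied data
  set.seed(32)
  for (rep in 1:10) {
    x <- stats::rnorm(9); y <- stats::rnorm(9)
    expect_equal(wilcoxon_signed_rank(x, y)$p,
                 stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("Wilcoxon respects sign symmetry and degenerate input", {
  x <- c(1.2, 3.1, 0.4, 2.2, 5.0, 1.1); y <- x + c(1, -2, 0.5, 1.5, -0.3, 2)
  a <- wilcoxon_signed_rank(x, y)
  b <- wilcoxon_signed_rank(y, x)
  expect_equal(a$p, b$p)
  expect_error(wilcoxon_signed_rank(x, x), "degenerate")
})

test_that("normal approximation agrees with exact enumeration near the cutover", {
  set.seed(33)
  for (rep in 1:15) {
    # n = 13 uses the approximate branch; enumerate 2^13 sign patterns as
    # the independent exact oracle
    x <- stats::rnorm(13); y <- stats::rnorm(13)
    res <- wilcoxon_signed_rank(x, y)
    expect_equal(res$method, "normal approximation")
    d <- x - y; r <- rank(abs(d)); W <- sum(r[d > 0])
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 13)))
    Wall <- as.vector(signs %*% r)
    p_exact <- min(1, 2 * min(mean(Wall <= W), mean(Wall >= W)))
    expect_lt(abs(res$p - p_exact), 0.01)
  }
})

test_that("Wilcoxon type-I error is calibrated at the nominal level", {
  set.seed(34)
  rej <- 0
  for (r in 1:1000) {
    x <- stats::rnorm(20); y <- stats::rnorm(20)
    if (wilcoxon_signed_rank(x, y)$p < 0.05) rej <- rej + 1
  }
  expect_gte(rej / 1000, 0.02)
  expect_lte(rej / 1000, 0.08)
})

test_that("ICC(A,1) matches an independent ANOVA mean-squares oracle", {
  set.seed(41)
  x <- matrix(stats::rnorm(8 * 3, mean = rep(stats::rnorm(8, 0, 2), 3)), 8, 3)
  res <- icc_absolute_agreement(x)
  long <- data.frame(y = as.vector(x),
                     subj = factor(rep(1:8, 3)),
                     rater = factor(rep(1:3, each = 8)))
  ms <- stats::anova(stats::lm(y ~ subj + rater, data = long))[["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]; n <- 8; k <- 3
  icc_oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-12)
  expect_lte(res$ci_low, res$icc)
  expect_gte(res$ci_high, res$icc)
})

test_that("ICC degenerate and simulated recovery cases", {
  # identical repeats per subject, subjects differ -> ICC = 1
  x <- matrix(rep(c(1, 2, 3, 4, 5, 9), 3), 6, 3)
  expect_equal(icc_absolute_agreement(x)$icc, 1.0)
  expect_error(icc_absolute_agreement(matrix(2, 6, 3)), "no variance")
  expect_error(icc_absolute_agreement(matrix(1:8, 4, 2)), "at least 5")
  # variance-components recovery: subject SD 3, error SD 1 -> ICC 0.9
  set.seed(42)
  subj <- stats::rnorm(200, 0, 3)
  xs <- matrix(subj, 200, 3) + matrix(stats::rnorm(600), 200, 3)
  r <- icc_absolute_agreement(xs)
  expect_gte(r$icc, 0.85); expect_lte(r$icc, 0.95)
  # null: independent values -> ICC near 0
  xn <- matrix(stats::rnorm(600), 200, 3)
  expect_lt(abs(icc_absolute_agreement(xn)$icc), 0.1)
})

test_that("ICC is invariant to shifts and scaling of the measurements", {
  set.seed(43)
  x <- matrix(stats::rnorm(7 * 3, rep(stats::rnorm(7, 0, 2), 3)), 7, 3)
  base <- icc_absolute_agreement(x)$icc
  expect_equal(icc_absolute_agreement(x + 100)$icc, base, tolerance = 1e-10)
  expect_equal(icc_absolute_agreement(x * 3.5)$icc, base, tolerance = 1e-10)
})
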