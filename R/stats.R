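#' Acquisition quality gate
#'
#' A scan fails quality control when its signal strength is below 7 or when
#' artifacts (motion, defocus, blur) affect more than 10% of the image. The
#' boundaries are inclusive on the passing side: signal strength exactly 7
#' and artifact fraction exactly 0.10 both pass.
#'
#' @param scan An `enface_angiogram` carrying `signal_strength` metadata.
#' @param artifact_fraction Fraction of the image affected by artifacts.
#' @return List with `pass` (logical) and `reason` (`NA` when passing).
#' @export
quality_gate <- function(scan, artifact_fraction = 0) {
  stopifnot(inherits(scan, "enface_angiogram"))
  if (is.null(scan$signal_strength) || is.na(scan$signal_strength))
    stop_domain("missing signal_strength metadata")
  if (scan$signal_strength < 7)
    return(list(pass = FALSE, reason = "signal strength"))
  if (artifact_fraction > 0.10)
    return(list(pass = FALSE, reason = "artifact fraction"))
  list(pass = TRUE, reason = NA_character_)
}

#' Wilcoxon signed-rank test for paired samples
#'
#' Zero differences are dropped (classic Wilcoxon convention); absolute
#' differences are ranked with average ranks for ties and `W` is the sum of
#' ranks of the positive differences. For `n <= 12` the two-sided p-value is
#' computed by exact enumeration of all `2^n` sign assignments (valid under
#' ties as well); for larger `n` a normal approximation with tie correction
#' and continuity correction is used.
#'
#' @param a First members of the pairs, or a two-column matrix of pairs.
#' @param b Second members (differences are `a - b`); omit when `a` is a
#'   matrix.
#' @return List with `W`, `p` (two-sided), `n` (non-zero pairs), `method`.
#' @examples
#' wilcoxon_signed_rank(c(2, 3, 4, 5, 6), c(1, 1, 1, 1, 1))  # p = 0.0625
#' @export
wilcoxon_signed_rank <- function(a, b = NULL) {
  if (is.null(b)) {
    stopifnot(is.matrix(a) || is.data.frame(a), ncol(a) == 2)
    b <- a[, 2]; a <- a[, 1]
  }
  if (length(a) != length(b)) stop_domain("paired vectors differ in length")
  d <- a - b
  d <- d[is.finite(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_domain("degenerate: no nonzero pairs")
  r <- rank(abs(d))
  W <- sum(r[d > 0])
  if (n <= 12) {
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Wall <- as.vector(signs %*% r)
    p <- 2 * min(mean(Wall <= W), mean(Wall >= W))
    p <- min(p, 1)
    method <- "exact"
  } else {
    # moments of W = sum r_i B_i, B_i ~ Bernoulli(1/2): tie-robust variance
    # sum(r^2)/4 and fourth cumulant -sum(r^4)/8; an Edgeworth kurtosis term
    # plus continuity correction keeps the tail areas close to exact
    mu <- sum(r) / 2
    sig2 <- sum(r^2) / 4
    k4 <- -sum(r^4) / 8
    wlo <- min(W, 2 * mu - W)
    z <- (wlo + 0.5 - mu) / sqrt(sig2)
    Fz <- stats::pnorm(z) -
      stats::dnorm(z) * (k4 / (24 * sig2^2)) * (z^3 - 3 * z)
    # floor at the exact two-sided p of the most extreme statistic, 2/2^n
    p <- min(1, max(2^(1 - n), 2 * Fz))
    method <- "normal approximation"
  }
  list(W = W, p = p, n = n, method = method)
}

#' Intraclass correlation, two-way model, absolute agreement, single measure
#'
#' ICC(A,1) from the two-way mean squares:
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)` for `n` subjects
#' by `k` repeated measurements, with the McGraw-Wong F-based 95% confidence
#' interval. This is the repeatability index for single acquisitions when
#' each eye is scanned `k` times.
#'
#' @param x Numeric matrix, `n` subjects (rows) by `k` repeats (columns), no
#'   missing cells, `n >= 5`, `k >= 2`.
#' @param conf_level Confidence level (default 0.95).
#' @return List of class `icc_result`: `icc`, `ci_low`, `ci_high`, `model`,
#'   `n`, `k`.
#' @export
icc_absolute_agreement <- function(x, conf_level = 0.95) {
  x <- as.matrix(x)
  n <- nrow(x); k <- ncol(x)
  if (n < 5) stop_domain("need at least 5 subjects")
  if (k < 2) stop_domain("need at least 2 repeats")
  if (any(!is.finite(x))) stop_domain("missing or non-finite cells")
  gm <- mean(x)
  if (sum((x - gm)^2) == 0) stop_domain("no variance")
  rm_ <- rowMeans(x); cm <- colMeans(x)
  SSR <- k * sum((rm_ - gm)^2)
  SSC <- n * sum((cm - gm)^2)
  SSE <- sum((x - outer(rm_, rep(1, k)) - outer(rep(1, n), cm) + gm)^2)
  MSR <- SSR / (n - 1); MSC <- SSC / (k - 1); MSE <- SSE / ((n - 1) * (k - 1))
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
  alpha <- 1 - conf_level
  a <- k * icc / (n * (1 - icc)); b <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  den <- (a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1))
  v <- if (!is.finite(den) || den <= 0) Inf else (a * MSC + b * MSE)^2 / den
  FL <- stats::qf(1 - alpha / 2, n - 1, v)
  FU <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  upper <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  structure(list(icc = icc, ci_low = min(lower, icc), ci_high = max(upper, icc),
                 model = "ICC(A,1) two-way mixed, absolute agreement, single measure",
                 n = n, k = k),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s\n  ICC = %.3f (95%% CI %.3f-%.3f), n = %d, k = %d\n",
              x$model, x$icc, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}
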