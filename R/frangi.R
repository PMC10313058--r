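#' Parameters of the Frangi vesselness filter
#'
#' @param scales Gaussian scales (sigma) in pixels at which the Hessian is
#'   computed; the response is the maximum over scales.
#' @param beta Blobness weight (suppresses blob-like structures).
#' @param c Structureness weight; `"auto"` (default) sets it per scale to
#'   half the maximum Hessian Frobenius norm, which makes the response
#'   invariant to a positive rescaling of the image.
#' @param bright_on_dark Enhance bright tubular structures on a dark
#'   background (the OCTA situation).
#' @return Object of class `frangi_params`.
#' @export
frangi_params <- function(scales = c(1, 1.5, 2, 3), beta = 0.5, c = "auto",
                          bright_on_dark = TRUE) {
  if (!length(scales) || any(scales <= 0)) stop_domain("scales must be positive")
  if (beta <= 0) stop_domain("beta must be positive")
  if (!identical(c, "auto") && (!is.numeric(c) || c <= 0))
    stop_domain("c must be positive or \"auto\"")
  structure(list(scales = scales, beta = beta, c = c,
                 bright_on_dark = isTRUE(bright_on_dark)),
            class = "frangi_params")
}

# 1-D Gaussian (or derivative) kernel, sum-normalized for order 0.
gauss_kernel_1d <- function(sigma, order = 0) {
  r <- max(2L, ceiling(4 * sigma))
  x <- (-r):r
  g <- exp(-x^2 / (2 * sigma^2))
  g <- g / sum(g)
  switch(as.character(order),
         "0" = g,
         "1" = -x / sigma^2 * g,
         "2" = {
           k <- (x^2 - sigma^2) / sigma^4 * g
           k - sum(k) / length(k)  # zero-sum despite truncation
         })
}

# Convolve with a separable Gaussian-derivative kernel (replicate borders).
gauss_deriv <- function(img, sigma, order_x, order_y) {
  kx <- gauss_kernel_1d(sigma, order_x)
  ky <- gauss_kernel_1d(sigma, order_y)
  k <- outer(ky, kx)  # rows = y
  EBImage::filter2(img, k, boundary = "replicate")
}

#' Frangi vesselness map
#'
#' Multi-scale Hessian tubularity measure. At each scale the Hessian is
#' computed with scale-normalized (`sigma^2`) Gaussian derivatives and its
#' eigenvalues ordered `|l1| <= |l2|`. For bright vessels the response is
#' zero where `l2 > 0`, otherwise
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))` with blobness
#' `Rb = l1 / l2` and structureness `S = sqrt(l1^2 + l2^2)`. The map is the
#' maximum over scales, with values in `[0, 1]`.
#'
#' @param scan An `enface_angiogram` or plain numeric matrix.
#' @param params A [frangi_params()].
#' @return Matrix of vesselness values in `[0, 1]`, same size as the input.
#' @export
frangi_vesselness <- function(scan, params = frangi_params()) {
  img <- if (inherits(scan, "enface_angiogram")) scan$pixels else as.matrix(scan)
  if (!length(img)) stop_domain("empty image")
  img <- matrix(as.numeric(img), nrow(img), ncol(img))
  out <- matrix(0, nrow(img), ncol(img))
  for (s in params$scales) {
    Hxx <- s^2 * gauss_deriv(img, s, 2, 0)
    Hyy <- s^2 * gauss_deriv(img, s, 0, 2)
    Hxy <- s^2 * gauss_deriv(img, s, 1, 1)
    tr2 <- (Hxx + Hyy) / 2
    disc <- sqrt(pmax(((Hxx - Hyy) / 2)^2 + Hxy^2, 0))
    ea <- tr2 + disc; eb <- tr2 - disc
    swap <- abs(ea) > abs(eb)
    l1 <- ifelse(swap, eb, ea)  # smaller magnitude
    l2 <- ifelse(swap, ea, eb)  # larger magnitude
    S2 <- l1^2 + l2^2
    m <- sqrt(max(S2))
    # a Hessian that is zero up to convolution roundoff (constant or flat
    # image) carries no structure at this scale
    if (m <= 1e-8 * max(max(abs(img)), .Machine$double.xmin)) next
    cc <- if (identical(params$c, "auto")) m / 2 else params$c
    # eigenvalues within floating noise of zero count as zero so that, e.g.,
    # adding a constant to the image cannot flip responses in flat regions
    tol <- 1e-10 * max(abs(l2))
    Rb2 <- ifelse(abs(l2) > tol, (l1 / l2)^2, 0)
    v <- exp(-Rb2 / (2 * params$beta^2)) * (1 - exp(-S2 / (2 * cc^2)))
    sign_bad <- if (params$bright_on_dark) l2 >= -tol else l2 <= tol
    v[sign_bad] <- 0
    out <- pmax(out, v)
  }
  out
}
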