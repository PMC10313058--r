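#' Estimate the translation between two scans by phase correlation
#'
#' Computes the normalized cross-power spectrum of the two images and locates
#' its inverse-FFT peak, then refines the peak to 0.1-pixel resolution with a
#' local upsampled discrete Fourier transform (matrix-multiply evaluation
#' around the integer peak). Returns the shift that maps the reference onto
#' the moving image: if `moving` equals `reference` displaced by `(+5, -3)`
#' pixels, the estimate is `(5, -3)`.
#'
#' @param reference,moving `enface_angiogram`s (or matrices) of identical
#'   shape and pitch.
#' @param upsample Subpixel refinement factor (default 10, i.e. 0.1 px).
#' @return Object of class `transform2d`: `dx`, `dy` (px, x = columns,
#'   y = rows), `peak` (phase-correlation peak height in `[0, 1]`),
#'   `reference_id`.
#' @export
estimate_translation <- function(reference, moving, upsample = 10) {
  ref <- if (inherits(reference, "enface_angiogram")) reference$pixels else as.matrix(reference)
  mov <- if (inherits(moving, "enface_angiogram")) moving$pixels else as.matrix(moving)
  if (!identical(dim(ref), dim(mov))) stop_domain("images must have the same shape")
  if (inherits(reference, "enface_angiogram") && inherits(moving, "enface_angiogram") &&
      !isTRUE(all.equal(reference$pitch, moving$pitch)))
    stop_domain("images must share the same pitch")
  n <- nrow(ref); m <- ncol(ref)
  F1 <- stats::fft(ref); F2 <- stats::fft(mov)
  R <- Conj(F1) * F2
  mag <- Mod(R)
  R <- R / pmax(mag, max(mag) * 1e-12)
  r <- Re(stats::fft(R, inverse = TRUE)) / (n * m)
  peak <- max(r)
  if (peak < 0.2) stop_domain("registration failed: correlation peak ", signif(peak, 3))
  idx <- arrayInd(which.max(r), dim(r))
  dy0 <- idx[1] - 1; dx0 <- idx[2] - 1
  if (dy0 > n / 2) dy0 <- dy0 - n
  if (dx0 > m / 2) dx0 <- dx0 - m
  # upsampled DFT in a +-1 px window around the integer peak
  if (upsample > 1) {
    step <- 1 / upsample
    uy <- seq(dy0 - 1, dy0 + 1, by = step)
    ux <- seq(dx0 - 1, dx0 + 1, by = step)
    ky <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1)) # FFT frequencies
    kx <- c(0:floor((m - 1) / 2), -(ceiling((m - 1) / 2):1))
    Ey <- exp(2i * pi * outer(uy, ky) / n)   # length(uy) x n
    Ex <- exp(2i * pi * outer(kx, ux) / m)   # m x length(ux)
    ru <- Re(Ey %*% R %*% Ex) / (n * m)
    hit <- arrayInd(which.max(ru), dim(ru))
    dy0 <- uy[hit[1]]; dx0 <- ux[hit[2]]
  }
  structure(list(dx = dx0, dy = dy0, peak = peak,
                 reference_id = if (inherits(reference, "enface_angiogram"))
                   reference$eye_id else NA_character_),
            class = "transform2d")
}

# Resample img displaced by (dx, dy): out(x) = img(x + dx, y + dy), bilinear,
# replicate borders. Used to align a moving image back onto its reference.
translate_bilinear <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  rows <- matrix(seq_len(nr), nr, nc) + dy
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc) + dx
  matrix(bilinear_at(img, as.vector(rows), as.vector(cols)), nr, nc)
}

#' Register repeated scans to a reference and average them
#'
#' Each non-reference scan is registered by phase correlation and resampled
#' (bilinear) onto the reference grid; the pixel-wise mean is returned with
#' the reference's metadata. Members whose registration fails are dropped
#' with a warning; fewer than two usable scans is an error.
#'
#' @param scans List of `enface_angiogram`s with identical geometry.
#' @param reference_index Which scan defines the reference grid (default 1).
#' @return An averaged `enface_angiogram` with a `provenance` attribute
#'   listing member repeat indices and estimated transforms.
#' @export
average_scans <- function(scans, reference_index = 1) {
  if (length(scans) < 2) stop_domain("need at least 2 scans")
  ref <- scans[[reference_index]]
  acc <- list(ref$pixels)
  transforms <- list(list(member = ref$repeat_index, dx = 0, dy = 0))
  for (i in seq_along(scans)) {
    if (i == reference_index) next
    tr <- tryCatch(estimate_translation(ref, scans[[i]]), error = function(e) NULL)
    if (is.null(tr)) {
      warning("dropping scan ", i, ": registration failed")
      next
    }
    acc[[length(acc) + 1]] <- translate_bilinear(scans[[i]]$pixels, tr$dx, tr$dy)
    transforms[[length(transforms) + 1]] <-
      list(member = scans[[i]]$repeat_index, dx = tr$dx, dy = tr$dy)
  }
  if (length(acc) < 2) stop_domain("fewer than 2 scans registered successfully")
  out <- ref
  out$pixels <- Reduce(`+`, acc) / length(acc)
  attr(out, "provenance") <- transforms
  out
}

#' Crop a scan to a smaller field of view
#'
#' Extracts the central window (optionally offset by a registration
#' transform) of side `round(1000 * target_fov / pitch)` pixels; the pitch is
#' unchanged and the fovea center is remapped into the window.
#'
#' @param scan An `enface_angiogram`.
#' @param target_fov Target field of view, mm (at most the scan's).
#' @param alignment Optional `transform2d` whose `(dx, dy)` offsets the
#'   window, e.g. from registering the large-vessel pattern of a paired scan.
#' @return The cropped `enface_angiogram`.
#' @export
crop_to_match <- function(scan, target_fov, alignment = NULL) {
  stopifnot(inherits(scan, "enface_angiogram"))
  if (target_fov > scan$fov + 1e-9) stop_domain("target_fov exceeds the scan FOV")
  n <- nrow(scan$pixels)
  n_out <- round(1000 * target_fov / scan$pitch)
  dx <- if (is.null(alignment)) 0 else alignment$dx
  dy <- if (is.null(alignment)) 0 else alignment$dy
  c0 <- round((n - n_out) / 2 + dx) + 1
  r0 <- round((n - n_out) / 2 + dy) + 1
  if (r0 < 1 || c0 < 1 || r0 + n_out - 1 > n || c0 + n_out - 1 > n)
    stop_domain("crop window exceeds image bounds")
  out <- scan
  out$pixels <- scan$pixels[r0:(r0 + n_out - 1), c0:(c0 + n_out - 1), drop = FALSE]
  out$fov <- target_fov
  out$fovea_center <- c(scan$fovea_center[1] - (c0 - 1), scan$fovea_center[2] - (r0 - 1))
  out
}
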