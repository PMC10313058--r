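#' Rasterize a vessel network into a high-resolution flow image
#'
#' Renders every vessel edge as a capsule (segment dilated by its radius)
#' onto a fine square raster covering the network's field of view: pixels
#' covered by a vessel get intensity 1, background 0. This is the optics-free
#' flow image that the point-spread function and grid sampling act on.
#'
#' @param net A [generate_network()] result.
#' @param raster_pitch Raster pixel size in micrometres; must be at most
#'   2 um so the finest point-spread function is oversampled.
#' @param fov Rendered field of view, mm (default: the network's).
#' @return An object of class `flow_raster`: list with `pixels` (matrix,
#'   rows = y), `pitch` (um) and `fov` (mm).
#' @export
rasterize_network <- function(net, raster_pitch = 2, fov = net$spec$fov) {
  stopifnot(inherits(net, "vessel_network"))
  if (raster_pitch > 2) stop_domain("raster_pitch must be <= 2 um to oversample the PSF")
  h <- fov / 2
  occ <- raster_occupancy(net, raster_pitch, c(-h, h), c(-h, h))
  structure(list(pixels = occ * 1, pitch = raster_pitch, fov = fov),
            class = "flow_raster")
}

# Reflect-pad a matrix by m rows/cols on every side.
pad_reflect <- function(x, m) {
  nr <- nrow(x); nc <- ncol(x)
  m <- min(m, nr - 1, nc - 1)
  ri <- c(rev(seq_len(m) + 1), seq_len(nr), nr - seq_len(m))
  ci <- c(rev(seq_len(m) + 1), seq_len(nc), nc - seq_len(m))
  x[ri, ci, drop = FALSE]
}

#' Blur a flow image with the acquisition point-spread function
#'
#' Convolves with a normalized 2-D Gaussian whose 1/e^2 intensity diameter
#' equals `spot_diameter * defocus_widen`; for a Gaussian intensity PSF this
#' means `sigma = diameter / 4`. Borders are handled by mirror reflection so
#' that total intensity is conserved and the periphery is not darkened.
#'
#' @param raster A `flow_raster` (or plain matrix plus `pitch`).
#' @param spot_diameter Beam 1/e^2 diameter at the retina, micrometres.
#' @param defocus_widen PSF widening factor (>= 1) emulating defocus.
#' @param pitch Pixel pitch in um; taken from `raster` when it is a
#'   `flow_raster`.
#' @return Same type as the input, blurred.
#' @export
apply_psf <- function(raster, spot_diameter, defocus_widen = 1, pitch = NULL) {
  if (spot_diameter <= 0) stop_domain("spot_diameter must be positive")
  if (defocus_widen < 1) stop_domain("defocus_widen must be >= 1")
  is_raster <- inherits(raster, "flow_raster")
  px <- if (is_raster) raster$pixels else raster
  pitch <- if (is_raster) raster$pitch else pitch
  if (is.null(pitch)) stop_domain("pitch required for a plain matrix")
  sigma <- spot_diameter * defocus_widen / 4 / pitch
  m <- ceiling(4 * sigma) + 1
  padded <- pad_reflect(px, m)
  blurred <- EBImage::gblur(padded, sigma = sigma)
  out <- blurred[(m + 1):(m + nrow(px)), (m + 1):(m + ncol(px)), drop = FALSE]
  if (is_raster) { raster$pixels <- out; raster } else out
}

# Exact box-mean downsampling via a bilinearly interpolated integral image.
# Boxes may have fractional edges (pitch need not divide the raster pitch).
box_mean_grid <- function(px, raster_pitch, out_pitch, out_fov, in_fov) {
  n_out <- round(1000 * out_fov / out_pitch)
  p_in <- raster_pitch / 1000; p_out <- out_pitch / 1000
  if (out_fov > in_fov + 1e-9) stop_domain("sampled FOV exceeds the rendered FOV")
  # integral image S with zero-padded first row/col: S[i+1, j+1] = sum px[1..i, 1..j]
  S <- matrix(0, nrow(px) + 1, ncol(px) + 1)
  S[-1, -1] <- apply(apply(px, 2, cumsum), 1, cumsum) |> t()
  # integral up to physical coordinate x (from the raster origin) in pixels
  off <- (in_fov - out_fov) / 2
  edges <- off / p_in + (0:n_out) * (p_out / p_in)  # in raster-pixel units
  pos <- edges + 1  # index into S (1 = zero edge)
  Iat <- function(rr, cc) bilinear_at(S, rr, cc)
  out <- matrix(0, n_out, n_out)
  r0 <- pos[1:n_out]; r1 <- pos[2:(n_out + 1)]
  for (j in seq_len(n_out)) {
    c0 <- pos[j]; c1 <- pos[j + 1]
    box <- Iat(r1, rep(c1, n_out)) - Iat(r0, rep(c1, n_out)) -
      Iat(r1, rep(c0, n_out)) + Iat(r0, rep(c0, n_out))
    out[, j] <- pmax(box, 0) / ((r1 - r0) * (c1 - c0))
  }
  out
}

#' Sample a blurred flow image onto the acquisition grid
#'
#' Area-averaged downsampling (emulating detector integration over each
#' sampling cell) onto an `n x n` grid with `n = round(1000 * fov / pitch)`,
#' centered on the raster center. The fovea center of the output is the grid
#' center.
#'
#' @param raster A `flow_raster`, typically after [apply_psf()].
#' @param pitch Sampling pitch, micrometres.
#' @param fov Sampled field of view, mm; must fit inside the rendered one.
#' @param slab Slab label.
#' @param signal_strength Device-style signal strength score, 0-10.
#' @param eye_id,repeat_index,config_name Acquisition identifiers.
#' @return An object of class `enface_angiogram`.
#' @export
sample_grid <- function(raster, pitch, fov, slab = "whole_retina",
                        signal_strength = 10L, eye_id = "eye1",
                        repeat_index = 1L, config_name = "custom") {
  stopifnot(inherits(raster, "flow_raster"))
  out <- box_mean_grid(raster$pixels, raster$pitch, pitch, fov, raster$fov)
  n <- nrow(out)
  enface_angiogram(out, pitch = pitch, fov = fov,
                   fovea_center = c((n + 1) / 2, (n + 1) / 2),
                   slab = slab, signal_strength = signal_strength,
                   eye_id = eye_id, repeat_index = repeat_index,
                   config_name = config_name)
}

#' Construct an en-face angiogram object
#'
#' @param pixels Square matrix of non-negative intensities (rows = y).
#' @param pitch Pixel pitch, micrometres.
#' @param fov Field of view, mm; `round(1000 * fov / pitch)` must equal the
#'   matrix side.
#' @param fovea_center Fovea position in pixel coordinates (x, y), 1-based
#'   pixel centers, fractional allowed.
#' @param slab Slab label ("SCP", "DCC" or "whole_retina").
#' @param signal_strength Integer 0-10 quality score.
#' @param eye_id,repeat_index,config_name Identifiers.
#' @return Object of class `enface_angiogram`.
#' @export
enface_angiogram <- function(pixels, pitch, fov,
                             fovea_center = NULL,
                             slab = "whole_retina", signal_strength = 10L,
                             eye_id = "eye1", repeat_index = 1L,
                             config_name = "custom") {
  pixels <- as.matrix(pixels)
  n <- round(1000 * fov / pitch)
  if (nrow(pixels) != ncol(pixels))
    stop_domain("angiogram must be square, got ", nrow(pixels), " x ", ncol(pixels))
  if (abs(nrow(pixels) - n) > 1)
    stop_domain("image side ", nrow(pixels), " inconsistent with fov ", fov,
                " mm at pitch ", pitch, " um (expected ", n, ")")
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop_domain("intensities must be finite and non-negative")
  structure(list(
    pixels = pixels, pitch = pitch, fov = fov,
    fovea_center = fovea_center %||% c((nrow(pixels) + 1) / 2, (nrow(pixels) + 1) / 2),
    slab = slab, signal_strength = as.integer(signal_strength),
    eye_id = eye_id, repeat_index = as.integer(repeat_index),
    config_name = config_name
  ), class = "enface_angiogram")
}

#' @export
print.enface_angiogram <- function(x, ...) {
  cat(sprintf(
    "<enface_angiogram> %s %s rep%d: %dx%d px, %.3g um pitch, %.3g mm FOV, slab %s, SS %d\n",
    x$eye_id, x$config_name, x$repeat_index, nrow(x$pixels), ncol(x$pixels),
    x$pitch, x$fov, x$slab, x$signal_strength))
  invisible(x)
}

#' Acquisition noise specification
#'
#' OCT envelope statistics: multiplicative speckle on the flow signal plus a
#' Rayleigh-distributed background floor, with optional motion-artifact row
#' shifts and a defocus widening of the point-spread function.
#'
#' @param background_scale Rayleigh scale of the background floor, intensity
#'   units (mean background is `background_scale * sqrt(pi / 2)`).
#' @param speckle_cv Multiplicative coefficient of variation on the signal.
#' @param motion_rows Optional list of `c(row, shift_px)` pairs; each listed
#'   row (and not others) is shifted horizontally by the given pixel count.
#' @param defocus_widen PSF widening factor (>= 1).
#' @return Object of class `noise_spec`.
#' @export
noise_spec <- function(background_scale = 0.05, speckle_cv = 0.25,
                       motion_rows = NULL, defocus_widen = 1) {
  if (background_scale < 0) stop_domain("background_scale must be >= 0")
  if (speckle_cv < 0) stop_domain("speckle_cv must be >= 0")
  if (defocus_widen < 1) stop_domain("defocus_widen must be >= 1")
  structure(list(background_scale = background_scale, speckle_cv = speckle_cv,
                 motion_rows = motion_rows, defocus_widen = defocus_widen),
            class = "noise_spec")
}

#' Add acquisition noise to an angiogram
#'
#' Each pixel becomes `signal * (1 + speckle_cv * g) + Rayleigh(background)`
#' with `g` standard normal, clipped at zero; motion rows are then applied as
#' horizontal block shifts. Deterministic given the seed; the global RNG
#' state is left untouched.
#'
#' @param scan An `enface_angiogram`.
#' @param noise A [noise_spec()].
#' @param seed Integer seed.
#' @return A noisy `enface_angiogram`.
#' @export
add_noise <- function(scan, noise = noise_spec(), seed = 1) {
  stopifnot(inherits(scan, "enface_angiogram"), inherits(noise, "noise_spec"))
  with_seed(seed, {
    px <- scan$pixels
    n <- length(px)
    if (noise$speckle_cv > 0)
      px <- px * (1 + noise$speckle_cv * stats::rnorm(n))
    if (noise$background_scale > 0)
      px <- px + noise$background_scale * sqrt(-2 * log(stats::runif(n)))
    px <- matrix(pmax(px, 0), nrow(scan$pixels), ncol(scan$pixels))
    for (mr in noise$motion_rows) {
      r <- mr[1]; s <- mr[2]
      if (r >= 1 && r <= nrow(px) && s != 0) {
        row <- px[r, ]
        out <- numeric(length(row))
        src <- seq_along(row) - s
        ok <- src >= 1 & src <= length(row)
        out[ok] <- row[src[ok]]
        px[r, ] <- out
      }
    }
    scan$pixels <- px
    scan
  })
}

#' Render an angiogram from a network under one optical configuration
#'
#' Full forward model: rasterize, blur by the configuration's retinal spot
#' (times any defocus widening), sample onto the acquisition grid, then add
#' noise. When rendering the beam-expander configuration from a 3 mm network
#' the central 2.25 mm window is sampled, as in a fovea-centered acquisition.
#'
#' @param net A `vessel_network`.
#' @param cfg An [optical_config()].
#' @param noise A [noise_spec()]; use `background_scale = 0, speckle_cv = 0`
#'   for a noiseless render.
#' @param seed Integer seed for the noise draw.
#' @param eye_id,repeat_index Identifiers.
#' @param raster_pitch Working raster pitch, um.
#' @param raster Optional precomputed *blurred* `flow_raster` (used by
#'   [render_repeats()] to share the signal path across repeats).
#' @return An `enface_angiogram`.
#' @export
render_scan <- function(net, cfg, noise = noise_spec(), seed = 1,
                        eye_id = "eye1", repeat_index = 1L,
                        raster_pitch = 2, raster = NULL) {
  stopifnot(inherits(cfg, "optical_config"))
  if (is.null(raster)) {
    raster <- rasterize_network(net, raster_pitch)
    raster <- apply_psf(raster, cfg$spot_diameter_retina, noise$defocus_widen)
  }
  scan <- sample_grid(raster, cfg$pitch, cfg$fov, slab = net$spec$slab,
                      eye_id = eye_id, repeat_index = repeat_index,
                      config_name = cfg$name)
  add_noise(scan, noise, seed)
}

#' Render repeated acquisitions with independent noise
#'
#' The signal path (rasterization, blur, sampling) is computed once; each
#' repeat receives an independent noise draw with a seed derived from the
#' master seed.
#'
#' @inheritParams render_scan
#' @param n_repeats Number of repeats (>= 1).
#' @return List of `enface_angiogram`s.
#' @export
render_repeats <- function(net, cfg, noise = noise_spec(), n_repeats = 3,
                           seed = 1, eye_id = "eye1", raster_pitch = 2,
                           raster = NULL) {
  if (n_repeats < 1) stop_domain("n_repeats must be >= 1")
  if (is.null(raster)) {
    raster <- rasterize_network(net, raster_pitch)
    raster <- apply_psf(raster, cfg$spot_diameter_retina, noise$defocus_widen)
  }
  lapply(seq_len(n_repeats), function(r) {
    render_scan(net, cfg, noise, seed = derive_seed(seed, r),
                eye_id = eye_id, repeat_index = r, raster = raster)
  })
}
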