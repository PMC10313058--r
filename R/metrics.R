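#' Estimate the acquisition noise floor from structure-free areas
#'
#' Structure-free *areas* are identified on a spatially smoothed vesselness
#' map (Gaussian, sigma 2 px): pixels whose smoothed vesselness falls at or
#' below its `structure_quantile` quantile. The noise level is the mean raw
#' intensity over that set. Smoothing matters: selecting on per-pixel
#' vesselness would preferentially pick locally dark pixels and bias the
#' level low, whereas regional selection leaves the intensities within a
#' structure-free region unbiased. If the set is empty the mean of the
#' lowest intensity decile is used instead (with a message).
#'
#' @param scan An `enface_angiogram` or matrix of intensities.
#' @param vesselness Matrix from [frangi_vesselness()], same size.
#' @param structure_quantile Fraction in (0, 1); default 0.25.
#' @return Noise level in intensity units.
#' @export
estimate_noise_floor <- function(scan, vesselness, structure_quantile = 0.25) {
  img <- if (inherits(scan, "enface_angiogram")) scan$pixels else as.matrix(scan)
  if (structure_quantile <= 0 || structure_quantile >= 1)
    stop_domain("structure_quantile must be in (0, 1)")
  vs <- EBImage::gblur(vesselness, sigma = 2)
  thr <- stats::quantile(vs, structure_quantile, names = FALSE)
  sel <- vs <= thr
  if (!any(sel)) {
    message("structure-free set empty; falling back to lowest intensity decile")
    sel <- img <= stats::quantile(img, 0.1, names = FALSE)
  }
  mean(img[sel])
}

#' Binarize an enhanced angiogram into a perfusion mask
#'
#' Thresholds the vesselness-weighted intensity (`vesselness * intensity`)
#' at `k * noise_level`, then removes connected components smaller than
#' `min_object_px` (8-connectivity) and fills holes smaller than
#' `max_hole_px` (4-connectivity) — the usual cleanup of features unlikely
#' to be vascular.
#'
#' @param scan An `enface_angiogram` or intensity matrix.
#' @param vesselness Matrix from [frangi_vesselness()].
#' @param noise_level Noise floor from [estimate_noise_floor()].
#' @param k Threshold multiplier on the noise level (> 0).
#' @param min_object_px Minimum connected-component size kept, pixels.
#' @param max_hole_px Maximum hole size filled, pixels.
#' @return Object of class `perfusion_mask`: logical `pixels`, `pitch`, and
#'   a `provenance` list (threshold, noise level, cleanup parameters).
#' @export
binarize_perfusion <- function(scan, vesselness, noise_level, k = 0.2,
                               min_object_px = 10, max_hole_px = 10) {
  if (k <= 0) stop_domain("k must be positive")
  img <- if (inherits(scan, "enface_angiogram")) scan$pixels else as.matrix(scan)
  pitch <- if (inherits(scan, "enface_angiogram")) scan$pitch else NA_real_
  thr <- k * noise_level
  mask <- (vesselness * img) > thr
  if (min_object_px > 1 && any(mask)) {
    lab <- label_components(mask, 8)
    sz <- component_sizes(lab)
    keep <- which(sz >= min_object_px)
    mask <- matrix(lab %in% keep, nrow(mask), ncol(mask))
  }
  if (max_hole_px > 0 && any(mask)) {
    labb <- label_components(!mask, 4)
    border_labs <- unique(c(labb[1, ], labb[nrow(labb), ], labb[, 1], labb[, ncol(labb)]))
    sz <- component_sizes(labb)
    fill <- setdiff(which(sz > 0 & sz <= max_hole_px), border_labs)
    if (length(fill)) mask[labb %in% fill] <- TRUE
  }
  if (all(mask) || !any(mask))
    warning("degenerate perfusion mask (all ", if (all(mask)) "foreground" else "background", ")")
  structure(list(pixels = mask, pitch = pitch,
                 provenance = list(threshold = thr, noise_level = noise_level,
                                   k = k, min_object_px = min_object_px,
                                   max_hole_px = max_hole_px)),
            class = "perfusion_mask")
}

# Guo-Hall thinning pass; returns the thinned logical matrix.
guo_hall_thin <- function(m) {
  m <- m * 1
  repeat {
    changed <- FALSE
    for (sub in 0:1) {
      P2 <- shift_mat(m, 1, 0); P6 <- shift_mat(m, -1, 0)   # N, S (row-1 = north)
      P4 <- shift_mat(m, 0, -1); P8 <- shift_mat(m, 0, 1)   # E, W
      P3 <- shift_mat(m, 1, -1); P5 <- shift_mat(m, -1, -1) # NE, SE
      P7 <- shift_mat(m, -1, 1); P9 <- shift_mat(m, 1, 1)   # SW, NW
      C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
        (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
      N1 <- (P9 | P2) + (P3 | P4) + (P5 | P6) + (P7 | P8)
      N2 <- (P2 | P3) + (P4 | P5) + (P6 | P7) + (P8 | P9)
      N <- pmin(N1, N2)
      O <- if (sub == 0) ((P2 | P3 | !P5) & P4) else ((P6 | P7 | !P9) & P8)
      del <- m == 1 & C == 1 & N >= 2 & N <= 3 & O == 0
      if (any(del)) { m[del] <- 0; changed <- TRUE }
    }
    if (!changed) break
  }
  m == 1
}

# Count of 8-neighbours of each foreground pixel.
neighbour_count <- function(m) {
  m <- m * 1
  shift_mat(m, 1, 0) + shift_mat(m, -1, 0) + shift_mat(m, 0, 1) + shift_mat(m, 0, -1) +
    shift_mat(m, 1, 1) + shift_mat(m, 1, -1) + shift_mat(m, -1, 1) + shift_mat(m, -1, -1)
}

# TRUE where deleting the pixel keeps local 8-connectivity (crossing number 1).
is_simple_px <- function(m) {
  m <- m * 1
  P2 <- shift_mat(m, 1, 0); P6 <- shift_mat(m, -1, 0)
  P4 <- shift_mat(m, 0, -1); P8 <- shift_mat(m, 0, 1)
  P3 <- shift_mat(m, 1, -1); P5 <- shift_mat(m, -1, -1)
  P7 <- shift_mat(m, -1, 1); P9 <- shift_mat(m, 1, 1)
  C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) +
    (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
  C == 1
}

#' Skeletonize a perfusion mask to one-pixel-wide centerlines
#'
#' Topology-preserving Guo-Hall thinning (an iterative erosion that never
#' breaks or merges components), followed by a conservative cleanup that
#' removes simple pixels from any remaining 2x2 foreground block. The result
#' is a subset of the input with the same number of connected components and
#' no 2x2 foreground block.
#'
#' @param mask A `perfusion_mask` or logical matrix.
#' @return Object of class `skeleton_mask` (logical `pixels`, `pitch`).
#' @export
skeletonize_mask <- function(mask) {
  px <- if (inherits(mask, "perfusion_mask")) mask$pixels else as.matrix(mask) > 0
  pitch <- if (inherits(mask, "perfusion_mask")) mask$pitch else NA_real_
  sk <- guo_hall_thin(px)
  # dissolve residual 2x2 blocks without changing topology
  for (iter in 1:8) {
    blk <- sk & shift_mat(sk, 1, 0) & shift_mat(sk, 0, 1) & shift_mat(sk, 1, 1)
    if (!any(blk)) break
    in_block <- blk | shift_mat(blk, 1, 0) | shift_mat(blk, 0, 1) | shift_mat(blk, 1, 1)
    cand <- which(in_block & is_simple_px(sk) & neighbour_count(sk) > 1)
    if (!length(cand)) break
    for (i in cand) {
      sk[i] <- FALSE
      if (!(is_simple_px_at(sk, i))) sk[i] <- TRUE else next
    }
  }
  structure(list(pixels = sk, pitch = pitch), class = "skeleton_mask")
}

# Check, after tentatively clearing index i, that its neighbourhood kept
# crossing number 1 around the removed site (i.e. removal was simple).
is_simple_px_at <- function(m, i) {
  nr <- nrow(m)
  r <- ((i - 1) %% nr) + 1
  cc <- ((i - 1) %/% nr) + 1
  if (r <= 1 || cc <= 1 || r >= nr || cc >= ncol(m)) return(TRUE)
  at <- function(dr, dc) m[r + dr, cc + dc]
  P2 <- at(-1, 0); P3 <- at(-1, 1); P4 <- at(0, 1); P5 <- at(1, 1)
  P6 <- at(1, 0); P7 <- at(1, -1); P8 <- at(0, -1); P9 <- at(-1, -1)
  C <- (!P2 & (P3 | P4)) + (!P4 & (P5 | P6)) + (!P6 & (P7 | P8)) + (!P8 & (P9 | P2))
  n8 <- P2 + P3 + P4 + P5 + P6 + P7 + P8 + P9
  C == 1 && n8 > 1
}

#' Annulus region of interest on an angiogram grid
#'
#' Pixel membership: a pixel belongs to the annulus iff the physical distance
#' from its center to the fovea center satisfies
#' `inner_d/2 <= d < outer_d/2`.
#'
#' @param scan An `enface_angiogram` (provides pitch, size, fovea center).
#' @param inner_d Inner diameter, mm (default 1).
#' @param outer_d Outer diameter, mm (default 2); the annulus must fit in
#'   the field of view.
#' @return Object of class `annulus_roi` (logical `pixels`, `center`,
#'   `inner_d`, `outer_d`, `pitch`).
#' @export
annulus_roi <- function(scan, inner_d = 1, outer_d = 2) {
  stopifnot(inherits(scan, "enface_angiogram"))
  if (outer_d < inner_d || inner_d < 0) stop_domain("need outer_d >= inner_d >= 0")
  if (outer_d > scan$fov + 1e-9)
    stop_domain("annulus (", outer_d, " mm) exceeds the field of view (", scan$fov, " mm)")
  n <- nrow(scan$pixels)
  fx <- scan$fovea_center[1]; fy <- scan$fovea_center[2]
  p <- scan$pitch / 1000
  dx <- (seq_len(n) - fx) * p
  dy <- (seq_len(n) - fy) * p
  d <- sqrt(outer(dy^2, dx^2, "+"))
  structure(list(pixels = d >= inner_d / 2 & d < outer_d / 2,
                 center = scan$fovea_center, inner_d = inner_d,
                 outer_d = outer_d, pitch = scan$pitch),
            class = "annulus_roi")
}

#' Perfusion density within a region of interest
#'
#' Fraction of region pixels flagged as perfused; the conventional "area of
#' detected flow per unit area", reported as a fraction in `[0, 1]`.
#'
#' @param mask A `perfusion_mask`.
#' @param roi An [annulus_roi()] of the same shape.
#' @return Fraction in `[0, 1]`.
#' @export
perfusion_density <- function(mask, roi) {
  m <- if (inherits(mask, "perfusion_mask")) mask$pixels else as.matrix(mask) > 0
  r <- roi$pixels
  if (!identical(dim(m), dim(r))) stop_domain("mask and roi shapes differ")
  if (!any(r)) stop_domain("empty roi")
  sum(m & r) / sum(r)
}

#' Vessel (length) density within a region of interest
#'
#' Skeleton length divided by region area, in 1/mm. Length is measured over
#' 8-neighbour links between skeleton pixels: each orthogonal link counts
#' `pitch`, each diagonal link `pitch * sqrt(2)`, every link once, and a link
#' contributes half its length per endpoint that lies inside the region.
#'
#' @param skel A `skeleton_mask`.
#' @param roi An [annulus_roi()] of the same shape.
#' @return Vessel density in 1/mm.
#' @export
vessel_density <- function(skel, roi) {
  s <- if (inherits(skel, "skeleton_mask")) skel$pixels else as.matrix(skel) > 0
  r <- roi$pixels
  if (!identical(dim(s), dim(r))) stop_domain("skeleton and roi shapes differ")
  if (!any(r)) stop_domain("empty roi")
  p_mm <- roi$pitch / 1000
  length_mm <- 0
  dirs <- list(list(0, 1, 1), list(1, 0, 1), list(1, 1, sqrt(2)), list(1, -1, sqrt(2)))
  rin <- r * 1
  for (d in dirs) {
    s2 <- shift_mat(s * 1, -d[[1]], -d[[2]])   # neighbour at (+dr, +dc)
    link <- s & s2 == 1
    w <- (rin + shift_mat(rin, -d[[1]], -d[[2]])) / 2
    length_mm <- length_mm + sum(w[link]) * d[[3]] * p_mm
  }
  area_mm2 <- sum(r) * p_mm^2
  length_mm / area_mm2
}

#' Quantify one angiogram: perfusion density, vessel density, FAZ metrics
#'
#' Runs the full measurement chain (vesselness, noise floor, binarization,
#' skeletonization, annulus densities, FAZ segmentation and morphometry) on
#' one scan.
#'
#' @param scan An `enface_angiogram`.
#' @param params A [frangi_params()].
#' @param k,min_object_px,max_hole_px Binarization settings, see
#'   [binarize_perfusion()].
#' @param inner_d,outer_d Annulus diameters in mm.
#' @param faz Logical; also segment and measure the FAZ.
#' @return A list: `pd`, `vd`, `threshold`, `noise_level`, `faz_area`,
#'   `faz_perimeter`, `faz_circularity` (the FAZ entries are `NA` when
#'   segmentation fails or `faz = FALSE`), plus the intermediate `mask` and
#'   `skeleton`.
#' @export
quantify_scan <- function(scan, params = frangi_params(), k = 0.2,
                          min_object_px = 10, max_hole_px = 10,
                          inner_d = 1, outer_d = 2, faz = TRUE) {
  v <- frangi_vesselness(scan, params)
  nl <- estimate_noise_floor(scan, v)
  mask <- binarize_perfusion(scan, v, nl, k = k, min_object_px = min_object_px,
                             max_hole_px = max_hole_px)
  skel <- skeletonize_mask(mask)
  roi <- annulus_roi(scan, inner_d, outer_d)
  pd <- perfusion_density(mask, roi)
  vd <- vessel_density(skel, roi)
  fz <- list(area = NA_real_, perimeter = NA_real_, circularity = NA_real_)
  if (faz) {
    fz_try <- tryCatch({
      region <- detect_faz(mask, scan$fovea_center)
      faz_metrics(region, scan$pitch)
    }, error = function(e) NULL)
    if (!is.null(fz_try)) fz <- fz_try
  }
  list(pd = pd, vd = vd, threshold = mask$provenance$threshold,
       noise_level = nl, faz_area = fz$area, faz_perimeter = fz$perimeter,
       faz_circularity = fz$circularity, mask = mask, skeleton = skel)
}
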