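#' Segment the foveal avascular zone from a perfusion mask
#'
#' The perfusion mask is morphologically closed with a disk of physical
#' radius `close_radius_um` (converted to pixels by the pitch, so both
#' acquisition modes use the same physical scale) to seal small capillary
#' gaps, then the background component containing the fovea center is
#' extracted by flood fill (4-connectivity). If the fovea-center pixel is
#' perfused, the nearest background pixel within a 5-pixel neighbourhood is
#' used as the seed. A component touching the image border means the FAZ is
#' not enclosed by vasculature and segmentation fails with an error, the
#' situation a reading-center would report as a segmentation failure.
#'
#' @param mask A `perfusion_mask`.
#' @param fovea_center Fovea position in pixel coordinates (x, y); default
#'   is the image center.
#' @param close_radius_um Closing-disk radius, micrometres (default 40, about one intercapillary distance, so gaps left by missed capillaries do not leak the flood fill).
#' @return Object of class `faz_region`: logical `pixels` (holes filled),
#'   `pitch`.
#' @export
detect_faz <- function(mask, fovea_center = NULL, close_radius_um = 40) {
  stopifnot(inherits(mask, "perfusion_mask"))
  px <- mask$pixels
  n <- nrow(px)
  fc <- fovea_center %||% c((n + 1) / 2, (ncol(px) + 1) / 2)
  cx <- round(fc[1]); cy <- round(fc[2])
  if (cx < 1 || cy < 1 || cx > ncol(px) || cy > n)
    stop_domain("fovea center outside the image")
  r_px <- max(1, round(close_radius_um / mask$pitch))
  brush <- EBImage::makeBrush(2 * r_px + 1, shape = "disc")
  closed <- EBImage::closing(px * 1, brush) > 0.5
  bg <- !closed
  if (!bg[cy, cx]) {
    win_r <- pmax(1, cy - 5):pmin(n, cy + 5)
    win_c <- pmax(1, cx - 5):pmin(ncol(px), cx + 5)
    cand <- which(bg[win_r, win_c, drop = FALSE], arr.ind = TRUE)
    if (!nrow(cand)) stop_domain("no background near the fovea center")
    d2 <- (win_r[cand[, 1]] - fc[2])^2 + (win_c[cand[, 2]] - fc[1])^2
    sel <- which.min(d2)
    cy <- win_r[cand[sel, 1]]; cx <- win_c[cand[sel, 2]]
  }
  lab <- label_components(bg, 4)
  id <- lab[cy, cx]
  region <- lab == id
  if (any(region[1, ]) || any(region[n, ]) || any(region[, 1]) || any(region[, ncol(px)]))
    stop_domain("FAZ unbounded: background reaches the image border")
  region <- EBImage::fillHull(region * 1) > 0.5
  structure(list(pixels = region, pitch = mask$pitch), class = "faz_region")
}

# Crofton 4-direction perimeter estimate, in pixels. Counts boundary
# crossings along rows, columns and both diagonals of a zero-padded image:
# P = (pi/8) * (Ch + Cv + (Cd1 + Cd2) / sqrt(2)).
crofton_perimeter_px <- function(region) {
  m <- matrix(0, nrow(region) + 2, ncol(region) + 2)
  m[2:(nrow(region) + 1), 2:(ncol(region) + 1)] <- region * 1
  ch <- sum(abs(m[, -1] - m[, -ncol(m)]))                     # along rows
  cv <- sum(abs(m[-1, ] - m[-nrow(m), ]))                     # along columns
  cd1 <- sum(abs(m[-1, -1] - m[-nrow(m), -ncol(m)]))          # \ diagonals
  cd2 <- sum(abs(m[-1, -ncol(m)] - m[-nrow(m), -1]))          # / diagonals
  (pi / 8) * (ch + cv + (cd1 + cd2) / sqrt(2))
}

#' Morphometry of a segmented foveal avascular zone
#'
#' Area is the pixel count times the pixel area; perimeter uses the Crofton
#' 4-direction estimate (boundary-pixel counting would overestimate the
#' perimeter of smooth shapes by up to a factor 8/pi and bias circularity
#' low); circularity is `4 * pi * area / perimeter^2`, 1 for a perfect
#' circle.
#'
#' @param region A `faz_region` (or logical matrix; then `pitch` must be
#'   given).
#' @param pitch Pixel pitch, micrometres.
#' @return List of class `faz_metrics`: `area` (mm^2), `perimeter` (mm),
#'   `circularity`, `region`.
#' @export
faz_metrics <- function(region, pitch = NULL) {
  px <- if (inherits(region, "faz_region")) region$pixels else as.matrix(region) > 0
  pitch <- if (inherits(region, "faz_region")) region$pitch else pitch
  if (is.null(pitch) || !is.finite(pitch)) stop_domain("pitch required")
  if (!any(px)) stop_domain("empty FAZ region")
  p_mm <- pitch / 1000
  area <- sum(px) * p_mm^2
  per <- crofton_perimeter_px(px) * p_mm
  structure(list(area = area, perimeter = per,
                 circularity = 4 * pi * area / per^2, region = px),
            class = "faz_metrics")
}

#' @export
print.faz_metrics <- function(x, ...) {
  cat(sprintf("<faz_metrics> area %.4f mm^2, perimeter %.3f mm, circularity %.3f\n",
              x$area, x$perimeter, x$circularity))
  invisible(x)
}
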