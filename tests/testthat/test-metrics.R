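test_that("noise floor: Rayleigh mean, noiseless zero, shift equivariance", {
  zero <- as_scan(matrix(0, 300, 300), pitch = 10)
  s <- 0.06
  noisy <- add_noise(zero, noise_spec(background_scale = s, speckle_cv = 0), seed = 5)
  v <- frangi_vesselness(noisy)
  nl <- estimate_noise_floor(noisy, v)
  # tracks the closed-form Rayleigh mean s*sqrt(pi/2); picking the quietest
  # regions of i.i.d. noise biases the level slightly low (< 15%)
  expect_lt(abs(nl - s * sqrt(pi / 2)) / (s * sqrt(pi / 2)), 0.15)
  expect_lte(nl, s * sqrt(pi / 2))

  n <- 101
  ridge <- matrix(rep(exp(-((seq_len(n) - 51)^2) / 8), n), n, n)
  scanr <- as_scan(ridge, pitch = 10)
  vr <- frangi_vesselness(scanr)
  expect_equal(estimate_noise_floor(scanr, vr), 0, tolerance = 1e-6)
  # adding a constant b raises the level by b (the Hessian is unchanged)
  scanb <- as_scan(ridge + 0.37, pitch = 10)
  expect_equal(estimate_noise_floor(scanb, frangi_vesselness(scanb)),
               0.37, tolerance = 1e-5)
  expect_error(estimate_noise_floor(scanr, vr, 0), "in \\(0, 1\\)")
})

test_that("binarization thresholds, small-object removal and hole filling", {
  n <- 60
  img <- matrix(0, n, n); img[20:22, 10:50] <- 1   # a bar
  img[40, 40] <- 1                                 # isolated speck
  v <- matrix(1, n, n)
  m0 <- suppressWarnings(binarize_perfusion(img, v, noise_level = 0, k = 2,
                                            min_object_px = 1, max_hole_px = 0))
  expect_equal(sum(m0$pixels), sum(img > 0))  # zero noise level keeps all positives
  m1 <- binarize_perfusion(img, v, noise_level = 0.1, k = 1,
                           min_object_px = 5, max_hole_px = 0)
  expect_false(m1$pixels[40, 40])             # speck removed
  expect_true(all(m1$pixels[20:22, 10:50]))
  # hole filling: a ring with a small interior hole
  ring <- disk_mask(41, 12) & !disk_mask(41, 3)
  m2 <- binarize_perfusion(ring * 1, matrix(1, 41, 41), noise_level = 0.1,
                           k = 1, min_object_px = 1, max_hole_px = 40)
  expect_true(all(m2$pixels[disk_mask(41, 3)]))
  expect_equal(m2$provenance$threshold, 0.1)
})

test_that("detection overlaps ground truth on the default eye at BE resolution", {
  net <- default_eye()
  cfg <- be_config()
  mask <- be_quant()$mask$pixels
  h <- cfg$fov / 2
  occ_raw <- octaquant:::raster_occupancy(net, cfg$pitch, c(-h, h), c(-h, h))
  dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))
  # against the anatomical (thin) truth the overlap is resolution-limited
  expect_gt(dice(mask, occ_raw), 0.4)
  # against the optics-matched truth the detection should overlap well: a
  # thin vessel blurred by the PSF has an apparent 1/e2 radius of about
  # spot/2, so truth radii are widened in quadrature with that
  net_eff <- net
  net_eff$edges$radius_um <- sqrt(net$edges$radius_um^2 +
                                    (cfg$spot_diameter_retina / 2)^2)
  occ_eff <- octaquant:::raster_occupancy(net_eff, cfg$pitch, c(-h, h), c(-h, h))
  expect_gt(dice(mask, occ_eff), 0.8)
})

test_that("skeletonization thins to 1 px, preserves topology, handles edge cases", {
  # 10-px-wide bar: single centerline; thinning erodes about half the bar
  # width from each free end
  m <- matrix(FALSE, 40, 80); m[16:25, 11:70] <- TRUE
  sk <- skeletonize_mask(m)$pixels
  expect_true(all(!sk | m))
  expect_equal(length(unique(which(sk, arr.ind = TRUE)[, 1])), 1)  # one row
  expect_equal(sum(sk), 60 - 10 + 1, tolerance = 2.5 / 51)
  # full disk degenerates to (nearly) a point
  expect_lte(sum(skeletonize_mask(disk_mask(61, 20))$pixels), 5)
  # empty mask
  expect_equal(sum(skeletonize_mask(matrix(FALSE, 20, 20))$pixels), 0)
})

test_that("skeleton invariants hold on random morphologies", {
  set.seed(13)
  for (i in 1:12) {
    m <- matrix(stats::runif(60 * 60) < 0.42, 60, 60)
    m <- EBImage::closing(m * 1, EBImage::makeBrush(3, "disc")) > 0.5
    sk <- skeletonize_mask(m)$pixels
    expect_true(all(!sk | m))                                  # subset
    expect_equal(max(octaquant:::label_components(sk, 8)),     # components kept
                 max(octaquant:::label_components(m, 8)))
    blk <- sk & octaquant:::shift_mat(sk, 1, 0) &
      octaquant:::shift_mat(sk, 0, 1) & octaquant:::shift_mat(sk, 1, 1)
    expect_false(any(blk))                                     # 1 px wide
  }
})

test_that("annulus ROI has the analytic area and correct degenerate forms", {
  scan <- as_scan(matrix(0, 300, 300), pitch = 10, fov = 3)
  roi <- annulus_roi(scan, 1, 2)
  expect_equal(sum(roi$pixels) * (0.01)^2, pi * (1^2 - 0.5^2), tolerance = 0.01)
  full <- annulus_roi(scan, 0, 2)
  expect_equal(sum(full$pixels) * (0.01)^2, pi * 1^2, tolerance = 0.01)
  expect_equal(sum(annulus_roi(scan, 1, 1)$pixels), 0)
  expect_error(annulus_roi(scan, 1, 4), "exceeds")
})

test_that("perfusion density counts fractions exactly", {
  scan <- as_scan(matrix(0, 200, 200), pitch = 10, fov = 2)
  roi <- annulus_roi(scan, 0, 1.6)
  all_fg <- structure(list(pixels = matrix(TRUE, 200, 200), pitch = 10),
                      class = "perfusion_mask")
  expect_equal(perfusion_density(all_fg, roi), 1.0)
  none <- structure(list(pixels = matrix(FALSE, 200, 200), pitch = 10),
                    class = "perfusion_mask")
  expect_equal(perfusion_density(none, roi), 0.0)
  left <- structure(list(pixels = cbind(matrix(TRUE, 200, 100),
                                        matrix(FALSE, 200, 100)), pitch = 10),
                    class = "perfusion_mask")
  # symmetric ROI: exactly half up to the one-pixel boundary ring
  expect_equal(perfusion_density(left, roi), 0.5, tolerance = 0.01)
  # dilation monotonicity
  mask <- be_quant()$mask
  dil <- mask
  dil$pixels <- EBImage::dilate(mask$pixels * 1, EBImage::makeBrush(3, "disc")) > 0.5
  roi2 <- annulus_roi(be_scan(), 1, 2)
  expect_gte(perfusion_density(dil, roi2), perfusion_density(mask, roi2))
})

test_that("vessel density matches line-length oracles", {
  # horizontal 1 mm line spanning a 1 mm x 1 mm ROI at 10 um pitch
  sk <- matrix(FALSE, 120, 120); sk[60, 11:110] <- TRUE
  roi <- list(pixels = matrix(FALSE, 120, 120), pitch = 10)
  roi$pixels[11:110, 11:110] <- TRUE
  skel <- structure(list(pixels = sk, pitch = 10), class = "skeleton_mask")
  expect_equal(vessel_density(skel, roi), 1.0, tolerance = 0.02)

  # diagonal line: polyline-length oracle, sqrt(2) per step
  skd <- matrix(FALSE, 120, 120)
  for (i in 11:110) skd[i, i] <- TRUE
  skel_d <- structure(list(pixels = skd, pitch = 10), class = "skeleton_mask")
  oracle <- 99 * sqrt(2) * 0.01 / (100 * 100 * 0.01^2)
  expect_equal(vessel_density(skel_d, roi), oracle, tolerance = 0.02 * oracle)
  expect_error(vessel_density(skel, list(pixels = matrix(FALSE, 120, 120),
                                         pitch = 10)), "empty roi")
})

test_that("densities are invariant to positive intensity rescaling", {
  q1 <- be_quant()
  scaled <- be_scan()
  scaled$pixels <- scaled$pixels * 4.2
  q2 <- quantify_scan(scaled)
  expect_equal(q2$pd, q1$pd, tolerance = 1e-10)
  expect_equal(q2$vd, q1$vd, tolerance = 1e-10)
  expect_gte(q1$pd, 0); expect_lte(q1$pd, 1); expect_gte(q1$vd, 0)
})
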