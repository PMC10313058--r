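test_that("rasterization draws capsules of the right width and is additive", {
  net0 <- manual_network(data.frame(x1 = 1, y1 = 1, x2 = 1.2, y2 = 1,
                                    radius_um = 3)[0, ], fov = 1)
  expect_true(all(rasterize_network(net0, 1)$pixels == 0))

  one <- manual_network(data.frame(x1 = -0.3, y1 = 0, x2 = 0.3, y2 = 0,
                                   radius_um = 5), fov = 1)
  r1 <- rasterize_network(one, 1)
  # cross-section width at mid-length: 10 um diameter at 1 um raster
  mid_col <- round(ncol(r1$pixels) / 2)
  expect_equal(sum(r1$pixels[, mid_col]), 10, tolerance = 0.1)

  two <- manual_network(data.frame(x1 = c(-0.3, -0.3), y1 = c(-0.2, 0.2),
                                   x2 = c(0.3, 0.3), y2 = c(-0.2, 0.2),
                                   radius_um = 5), fov = 1)
  r2 <- rasterize_network(two, 1)
  expect_equal(sum(r2$pixels), 2 * sum(r1$pixels))
  expect_error(rasterize_network(one, 3), "oversample")
})

test_that("PSF blur has the nominal 1/e2 diameter and conserves intensity", {
  n <- 201
  delta <- matrix(0, n, n); delta[101, 101] <- 1
  fr <- structure(list(pixels = delta, pitch = 1, fov = n / 1000),
                  class = "flow_raster")
  out <- apply_psf(fr, spot_diameter = 20)$pixels   # sigma = 5 px
  expect_equal(sum(out), 1, tolerance = 1e-3)
  prof <- out[101, ]
  # 1/e2 intensity radius of the kernel is 2 sigma = 10 px
  target <- max(prof) * exp(-2)
  right <- which(prof[101:n] < target)[1] - 1  # first crossing
  # linear interpolation between the straddling samples
  x1 <- right - 1; x2 <- right
  y1 <- prof[101 + x1]; y2 <- prof[101 + x2]
  r_e2 <- x1 + (y1 - target) / (y1 - y2)
  expect_equal(r_e2, 10, tolerance = 0.05 * 10)

  # uniform image is a fixed point (reflective borders, normalized kernel)
  uni <- structure(list(pixels = matrix(3, 120, 120), pitch = 1, fov = 0.12),
                   class = "flow_raster")
  blur <- apply_psf(uni, 15)$pixels
  expect_equal(max(abs(blur - 3)) / 3, 0, tolerance = 1e-3)

  # total intensity conserved on structured content
  set.seed(1)
  img <- structure(list(pixels = matrix(runif(150^2), 150, 150), pitch = 1,
                        fov = 0.15), class = "flow_raster")
  expect_equal(sum(apply_psf(img, 12)$pixels), sum(img$pixels), tolerance = 1e-3)
})

test_that("grid sampling produces the two 300x300 scan patterns", {
  fr <- structure(list(pixels = matrix(1.7, 1500, 1500), pitch = 2, fov = 3),
                  class = "flow_raster")
  s1 <- sample_grid(fr, pitch = 10, fov = 3)
  expect_equal(dim(s1$pixels), c(300, 300))
  s2 <- sample_grid(fr, pitch = 7.5, fov = 2.25)
  expect_equal(dim(s2$pixels), c(300, 300))
  # constant input -> constant output (integral-image roundoff ~1e-11)
  expect_equal(range(s1$pixels), c(1.7, 1.7), tolerance = 1e-9)
  expect_equal(range(s2$pixels), c(1.7, 1.7), tolerance = 1e-9)
  expect_error(sample_grid(fr, pitch = 10, fov = 4), "exceeds")
})

test_that("angiogram geometry invariants are enforced", {
  expect_error(enface_angiogram(matrix(0, 225, 225), pitch = 10, fov = 3),
               "inconsistent")
  expect_error(enface_angiogram(matrix(-1, 100, 100), pitch = 10, fov = 1),
               "non-negative")
  expect_error(enface_angiogram(matrix(0, 100, 90), pitch = 10, fov = 1),
               "square")
})

test_that("noise model: identity, Rayleigh mean, determinism, motion rows", {
  z <- as_scan(matrix(0.8, 200, 200), pitch = 10)
  clean <- add_noise(z, noise_spec(background_scale = 0, speckle_cv = 0), seed = 1)
  expect_identical(clean$pixels, z$pixels)

  zero <- as_scan(matrix(0, 300, 300), pitch = 10)
  s <- 0.07
  noisy <- add_noise(zero, noise_spec(background_scale = s, speckle_cv = 0), seed = 3)
  # Rayleigh mean s sqrt(pi/2), SE = s sqrt((4 - pi)/2) / 300
  se <- s * sqrt((4 - pi) / 2) / 300
  expect_lt(abs(mean(noisy$pixels) - s * sqrt(pi / 2)), 3 * se)

  n1 <- add_noise(z, noise_spec(), seed = 11)
  n2 <- add_noise(z, noise_spec(), seed = 11)
  n3 <- add_noise(z, noise_spec(), seed = 12)
  expect_identical(n1$pixels, n2$pixels)
  expect_false(identical(n1$pixels, n3$pixels))

  shifted <- add_noise(z, noise_spec(background_scale = 0, speckle_cv = 0,
                                     motion_rows = list(c(5, 3))), seed = 1)
  expect_equal(shifted$pixels[5, 4:200], z$pixels[5, 1:197])
  expect_equal(shifted$pixels[5, 1:3], rep(0, 3))
  expect_identical(shifted$pixels[6, ], z$pixels[6, ])
})

test_that("repeated renders share the signal path with independent noise", {
  net <- manual_network(data.frame(x1 = c(-0.8, 0), y1 = c(0, -0.8),
                                   x2 = c(0.8, 0), y2 = c(0, 0.8),
                                   radius_um = 8), fov = 2.25)
  cfg <- be_config()
  reps <- render_repeats(net, cfg, noise_spec(), n_repeats = 3, seed = 5)
  expect_length(reps, 3)
  expect_equal(vapply(reps, function(s) s$repeat_index, 1L), 1:3)
  expect_false(identical(reps[[1]]$pixels, reps[[2]]$pixels))
  expect_false(identical(reps[[2]]$pixels, reps[[3]]$pixels))
  expect_equal(reps[[1]]$pitch, reps[[2]]$pitch)
  expect_equal(reps[[1]]$fov, reps[[3]]$fov)

  quiet <- render_repeats(net, cfg, noise_spec(background_scale = 0, speckle_cv = 0),
                          n_repeats = 3, seed = 5)
  expect_identical(quiet[[1]]$pixels, quiet[[2]]$pixels)
  expect_identical(quiet[[1]]$pixels, quiet[[3]]$pixels)
})
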