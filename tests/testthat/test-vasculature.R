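test_that("network generation is deterministic and validated", {
  sp <- vasculature_spec(fov = 1.5, faz_area_target = 0.1,
                         capillary_point_density = 150, n_radial_vessels = 4)
  a <- generate_network(sp, seed = 3)
  b <- generate_network(sp, seed = 3)
  expect_identical(a$nodes, b$nodes)
  expect_identical(a$edges, b$edges)
  expect_identical(a$faz_polygon, b$faz_polygon)
  d <- generate_network(sp, seed = 4)
  expect_false(identical(a$edges, d$edges))
  # infeasible: FAZ does not fit the FOV
  expect_error(vasculature_spec(fov = 0.4, faz_area_target = 0.18), "infeasible")
})

test_that("degenerate spec yields an empty network with only a FAZ polygon", {
  sp <- vasculature_spec(capillary_point_density = 0, n_radial_vessels = 0)
  net <- generate_network(sp, seed = 1)
  expect_equal(nrow(net$edges), 0)
  expect_false(is.null(net$faz_polygon))
})

test_that("generated FAZ polygon is simple with area near target", {
  net <- default_eye()
  area <- octaquant:::shoelace_area(net$faz_polygon)
  expect_gte(area, 0.162)
  expect_lte(area, 0.198)
  expect_true(octaquant:::polygon_is_simple(net$faz_polygon))
})

test_that("ground truth: straight-edge length and capsule area oracles", {
  seg <- data.frame(x1 = -0.5, y1 = 0, x2 = 0.5, y2 = 0, radius_um = 5,
                    class = "capillary")
  net <- manual_network(seg, fov = 3)
  gt <- network_ground_truth(net, annulus_region(0, 2.5))
  expect_equal(gt$true_vessel_length, 1.0, tolerance = 1e-6)
  # analytic capsule area 2 r L + pi r^2; 1 um raster error ~ per-pixel
  expect_equal(gt$true_perfused_area, 2 * 0.005 * 1 + pi * 0.005^2,
               tolerance = 0.02)
})

test_that("ground truth: regular-polygon FAZ matches circle closed forms", {
  th <- seq(0, 2 * pi, length.out = 361)[-361]
  poly <- 0.24 * cbind(cos(th), sin(th))
  net <- manual_network(data.frame(x1 = 1, y1 = 1, x2 = 1.2, y2 = 1,
                                   radius_um = 3, class = "capillary"),
                        fov = 3, faz_polygon = poly)
  gt <- network_ground_truth(net, annulus_region(0, 2))
  expect_equal(gt$true_faz_area, pi * 0.24^2, tolerance = 1e-4)
  expect_equal(gt$true_faz_perimeter, 2 * pi * 0.24, tolerance = 1e-4)
  expect_equal(gt$true_faz_area, 0.181, tolerance = 2e-3)
  expect_equal(gt$true_faz_perimeter, 1.508, tolerance = 1e-3)
})

test_that("ground-truth length is additive over disjoint ROIs", {
  net <- default_eye()
  inner <- network_ground_truth(net, annulus_region(0, 1))$true_vessel_length
  ring <- network_ground_truth(net, annulus_region(1, 2))$true_vessel_length
  whole <- network_ground_truth(net, annulus_region(0, 2))$true_vessel_length
  expect_equal(inner + ring, whole, tolerance = 1e-6)
})

test_that("periarteriolar capillary removal strictly decreases vessel length", {
  sp0 <- vasculature_spec(capillary_free_halfwidth = 0)
  sp1 <- vasculature_spec(capillary_free_halfwidth = 50)
  n0 <- generate_network(sp0, seed = 5)
  n1 <- generate_network(sp1, seed = 5)
  len <- function(net) {
    e <- net$edges
    sum(sqrt((net$nodes[e$from, 1] - net$nodes[e$to, 1])^2 +
               (net$nodes[e$from, 2] - net$nodes[e$to, 2])^2))
  }
  expect_lt(len(n1), len(n0))
})

test_that("roi validation: outside-FOV and empty regions are rejected", {
  net <- default_eye()
  expect_error(network_ground_truth(net, annulus_region(1, 4)), "beyond")
  expect_error(annulus_region(1, 1), "outer_d > inner_d")
})

test_that("network JSON serialization round-trips", {
  net <- generate_network(vasculature_spec(fov = 1.5, faz_area_target = 0.08,
                                           capillary_point_density = 100,
                                           n_radial_vessels = 2), seed = 9)
  path <- withr::local_tempfile(fileext = ".json")
  write_network(net, path)
  back <- read_network(path)
  expect_equal(back$nodes, net$nodes, tolerance = 1e-12)
  expect_equal(back$edges$from, net$edges$from)
  expect_equal(back$edges$radius_um, net$edges$radius_um, tolerance = 1e-12)
  expect_equal(back$faz_polygon, net$faz_polygon, tolerance = 1e-12)
})
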