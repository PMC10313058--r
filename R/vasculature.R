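#' Specification of a synthetic parafoveal vascular network
#'
#' Parameters controlling the ground-truth network generator: a capillary
#' mesh surrounding a foveal avascular zone (FAZ), radial arterioles and
#' venules, periarteriolar capillary-free zones, and (for the deep capillary
#' complex) vortex-like capillary arrangements.
#'
#' Coordinates are continuous millimetres with the origin at the fovea
#' center, x rightward and y downward (image convention).
#'
#' @param fov Square field of view side, mm.
#' @param faz_area_target Target FAZ area, mm^2 (default 0.18, a typical
#'   healthy-eye value).
#' @param n_radial_vessels Number of radial arterioles+venules (alternating).
#' @param capillary_point_density Capillary node density, points/mm^2.
#' @param capillary_radius Range (min, max) of capillary radii, micrometres.
#' @param arteriole_radius Arteriole radius, micrometres (venules 25% larger).
#' @param capillary_free_halfwidth Half-width of the periarteriolar
#'   capillary-free zone, micrometres.
#' @param vortex_centers Number of capillary vortex centers (0 disables;
#'   used for the deep capillary complex).
#' @param slab Slab label: "SCP", "DCC" or "whole_retina".
#' @return An object of class `vasculature_spec`.
#' @export
vasculature_spec <- function(fov = 3, faz_area_target = 0.18,
                             n_radial_vessels = 8,
                             capillary_point_density = 380,
                             capillary_radius = c(2.5, 4),
                             arteriole_radius = 10,
                             capillary_free_halfwidth = 50,
                             vortex_centers = 0,
                             slab = c("SCP", "DCC", "whole_retina")) {
  slab <- match.arg(slab)
  if (fov <= 0) stop_domain("fov must be positive")
  if (faz_area_target < 0) stop_domain("faz_area_target must be non-negative")
  if (faz_area_target > 0 && fov <= 2 * sqrt(faz_area_target / pi))
    stop_domain("FAZ larger than the field of view is infeasible")
  if (capillary_point_density < 0) stop_domain("capillary_point_density must be >= 0")
  if (length(capillary_radius) != 2 || any(capillary_radius <= 0))
    stop_domain("capillary_radius must be a positive (min, max) pair")
  if (arteriole_radius <= 0) stop_domain("arteriole_radius must be positive")
  structure(list(
    fov = fov, faz_area_target = faz_area_target,
    n_radial_vessels = as.integer(n_radial_vessels),
    capillary_point_density = capillary_point_density,
    capillary_radius = capillary_radius,
    arteriole_radius = arteriole_radius,
    capillary_free_halfwidth = capillary_free_halfwidth,
    vortex_centers = as.integer(vortex_centers),
    slab = slab
  ), class = "vasculature_spec")
}

# Irregular star-shaped FAZ polygon around the origin, scaled so the
# shoelace area equals the target exactly.
make_faz_polygon <- function(area_target, n_vertices = 96) {
  theta <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  rho <- rep(1, n_vertices)
  for (k in 2:5) {
    a <- stats::rnorm(1, 0, 0.10 / k)
    phi <- stats::runif(1, 0, 2 * pi)
    rho <- rho + a * cos(k * theta + phi)
  }
  rho <- pmax(rho, 0.35)
  poly1 <- cbind(rho * cos(theta), rho * sin(theta))
  scale <- sqrt(area_target / shoelace_area(poly1))
  poly1 * scale
}

# Bridson Poisson-disc sampling over [-h, h]^2, excluding the FAZ interior.
poisson_disc <- function(h, r_min, faz_poly, k = 20) {
  cell <- r_min / sqrt(2)
  ng <- ceiling(2 * h / cell)
  grid <- matrix(0L, ng, ng)
  px <- numeric(0); py <- numeric(0)
  cell_of <- function(x) pmin(pmax(floor((x + h) / cell) + 1, 1), ng)
  ok_point <- function(x, y) {
    ci <- cell_of(x); cj <- cell_of(y)
    for (di in -2:2) for (dj in -2:2) {
      ii <- ci + di; jj <- cj + dj
      if (ii < 1 || jj < 1 || ii > ng || jj > ng) next
      id <- grid[ii, jj]
      if (id > 0L && (px[id] - x)^2 + (py[id] - y)^2 < r_min^2) return(FALSE)
    }
    TRUE
  }
  outside_faz <- function(x, y) {
    if (is.null(faz_poly)) TRUE else !in_polygon(x, y, faz_poly)
  }
  # initial point
  repeat {
    x0 <- stats::runif(1, -h, h); y0 <- stats::runif(1, -h, h)
    if (outside_faz(x0, y0)) break
  }
  px <- x0; py <- y0
  grid[cell_of(x0), cell_of(y0)] <- 1L
  active <- 1L
  while (length(active)) {
    ai <- active[length(active)]
    placed <- FALSE
    ang <- stats::runif(k, 0, 2 * pi)
    rad <- stats::runif(k, r_min, 2 * r_min)
    cx <- px[ai] + rad * cos(ang); cy <- py[ai] + rad * sin(ang)
    keep <- cx > -h & cx < h & cy > -h & cy < h
    keep[keep] <- outside_faz(cx[keep], cy[keep])
    for (m in which(keep)) {
      if (ok_point(cx[m], cy[m])) {
        px <- c(px, cx[m]); py <- c(py, cy[m])
        id <- length(px)
        grid[cell_of(cx[m]), cell_of(cy[m])] <- id
        active <- c(active, id)
        placed <- TRUE
        break
      }
    }
    if (!placed) active <- active[-length(active)]
  }
  cbind(px, py, deparse.level = 0)
}

# Distance from points (px, py) to segment (x1,y1)-(x2,y2), vectorized in points.
dist_point_segment <- function(px, py, x1, y1, x2, y2) {
  dx <- x2 - x1; dy <- y2 - y1
  L2 <- dx^2 + dy^2
  if (L2 == 0) return(sqrt((px - x1)^2 + (py - y1)^2))
  t <- pmin(pmax(((px - x1) * dx + (py - y1) * dy) / L2, 0), 1)
  sqrt((px - x1 - t * dx)^2 + (py - y1 - t * dy)^2)
}

#' Generate a ground-truth vascular network
#'
#' Builds a capillary mesh by Poisson-disc sampling outside the FAZ followed
#' by a Delaunay neighbour graph pruned to about three edges per node, adds
#' alternating radial arterioles and venules running from the field edge to
#' the FAZ ring, removes capillaries inside the periarteriolar capillary-free
#' zone, and (optionally) swirls capillaries around vortex centers as seen in
#' the deep capillary complex. The result is deterministic given
#' `(spec, seed)`.
#'
#' @param spec A [vasculature_spec()].
#' @param seed Integer seed controlling all randomness of the generator.
#' @return An object of class `vessel_network` with fields `nodes` (n x 2
#'   matrix, mm), `edges` (data.frame `from`, `to`, `radius_um`, `class`),
#'   `faz_polygon` (m x 2 matrix, mm), `spec`, `seed`.
#' @export
generate_network <- function(spec, seed = 1) {
  stopifnot(inherits(spec, "vasculature_spec"))
  with_seed(seed, {
    h <- spec$fov / 2
    faz <- if (spec$faz_area_target > 0) make_faz_polygon(spec$faz_area_target) else NULL
    faz_rad <- if (is.null(faz)) 0 else max(sqrt(faz[, 1]^2 + faz[, 2]^2))

    nodes <- matrix(numeric(0), 0, 2)
    edges <- data.frame(from = integer(0), to = integer(0),
                        radius_um = numeric(0), class = character(0),
                        stringsAsFactors = FALSE)

    if (spec$capillary_point_density > 0) {
      r_min <- sqrt(0.7 / spec$capillary_point_density)
      pts <- poisson_disc(h, r_min, faz)
      if (nrow(pts) >= 3) {
        dl <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
        eg <- dl$delsgs
        len <- sqrt((eg$x1 - eg$x2)^2 + (eg$y1 - eg$y2)^2)
        mx <- (eg$x1 + eg$x2) / 2; my <- (eg$y1 + eg$y2) / 2
        keep <- len <= 2.4 * r_min
        if (!is.null(faz)) keep <- keep & !in_polygon(mx, my, faz)
        eg <- eg[keep, , drop = FALSE]; len <- len[keep]
        # prune: keep an edge only while it ranks among the 3 shortest at
        # both endpoints (ties broken by edge angle for determinism), which
        # caps the degree at 3 and gives the open capillary-mesh look
        ang <- atan2(eg$y2 - eg$y1, eg$x2 - eg$x1)
        ord_key <- order(len, ang)
        rank_at <- function(idx_vec) {
          r <- integer(nrow(eg))
          spl <- split(seq_len(nrow(eg)), idx_vec)
          for (s in spl) r[s[order(match(s, ord_key))]] <- seq_along(s)
          r
        }
        r1 <- rank_at(eg$ind1); r2 <- rank_at(eg$ind2)
        eg <- eg[r1 <= 3 & r2 <= 3, , drop = FALSE]
        nodes <- pts
        if (nrow(eg)) {
          edges <- data.frame(
            from = eg$ind1, to = eg$ind2,
            radius_um = stats::runif(nrow(eg), spec$capillary_radius[1],
                                     spec$capillary_radius[2]),
            class = "capillary", stringsAsFactors = FALSE)
        }
      }
    }

    # radial arterioles / venules, alternating, jittered polylines
    if (spec$n_radial_vessels > 0) {
      base <- stats::runif(1, 0, 2 * pi)
      for (v in seq_len(spec$n_radial_vessels)) {
        theta0 <- base + 2 * pi * (v - 1) / spec$n_radial_vessels +
          stats::rnorm(1, 0, 0.08)
        cls <- if (v %% 2 == 1) "arteriole" else "venule"
        r_out <- h / max(abs(cos(theta0)), abs(sin(theta0))) * 0.999
        r_in <- faz_rad + 0.06
        if (r_in >= r_out) next
        rr <- seq(r_out, r_in, by = -0.12)
        if (rr[length(rr)] > r_in) rr <- c(rr, r_in)
        th <- theta0 + cumsum(c(0, stats::rnorm(length(rr) - 1, 0, 0.035)))
        vx <- rr * cos(th); vy <- rr * sin(th)
        inside <- vx > -h & vx < h & vy > -h & vy < h
        vx <- vx[inside]; vy <- vy[inside]
        if (length(vx) < 2) next
        id0 <- nrow(nodes)
        nodes <- rbind(nodes, cbind(vx, vy, deparse.level = 0))
        rad <- if (cls == "arteriole") spec$arteriole_radius else 1.25 * spec$arteriole_radius
        edges <- rbind(edges, data.frame(
          from = id0 + seq_len(length(vx) - 1),
          to = id0 + seq_len(length(vx) - 1) + 1,
          radius_um = rad, class = cls, stringsAsFactors = FALSE))
      }
    }

    # periarteriolar capillary-free zone: drop capillaries near arterioles
    art <- edges[edges$class == "arteriole", , drop = FALSE]
    if (nrow(art) && any(edges$class == "capillary") &&
        spec$capillary_free_halfwidth > 0) {
      cap_idx <- which(edges$class == "capillary")
      mx <- (nodes[edges$from[cap_idx], 1] + nodes[edges$to[cap_idx], 1]) / 2
      my <- (nodes[edges$from[cap_idx], 2] + nodes[edges$to[cap_idx], 2]) / 2
      dmin <- rep(Inf, length(cap_idx))
      for (a in seq_len(nrow(art))) {
        d <- dist_point_segment(mx, my,
                                nodes[art$from[a], 1], nodes[art$from[a], 2],
                                nodes[art$to[a], 1], nodes[art$to[a], 2])
        dmin <- pmin(dmin, d)
      }
      drop <- cap_idx[dmin < spec$capillary_free_halfwidth / 1000]
      if (length(drop)) edges <- edges[-drop, , drop = FALSE]
    }

    # vortex patterns: swirl node coordinates around each center so nearby
    # capillary edges run tangentially (deep capillary complex anatomy)
    if (spec$vortex_centers > 0 && nrow(nodes)) {
      for (vtx in seq_len(spec$vortex_centers)) {
        va <- stats::runif(1, 0, 2 * pi)
        vr <- stats::runif(1, 0.55, 0.8) * h
        vc <- c(vr * cos(va), vr * sin(va))
        dx <- nodes[, 1] - vc[1]; dy <- nodes[, 2] - vc[2]
        d <- sqrt(dx^2 + dy^2)
        w <- pmax(0, 1 - d / 0.3)
        rot <- 1.4 * w
        cs <- cos(rot); sn <- sin(rot)
        nodes[, 1] <- vc[1] + cs * dx - sn * dy
        nodes[, 2] <- vc[2] + sn * dx + cs * dy
      }
      nodes[, 1] <- pmin(pmax(nodes[, 1], -h), h)
      nodes[, 2] <- pmin(pmax(nodes[, 2], -h), h)
    }

    # connect stray components to the main one so the graph outside the FAZ
    # is connected
    if (nrow(edges)) {
      g <- igraph::graph_from_edgelist(as.matrix(edges[, c("from", "to")]),
                                       directed = FALSE)
      g <- igraph::add_vertices(g, max(0, nrow(nodes) - igraph::vcount(g)))
      comp <- igraph::components(g)
      used <- sort(unique(c(edges$from, edges$to)))
      memb <- comp$membership
      tab <- table(memb[used])
      main <- as.integer(names(tab)[which.max(tab)])
      for (cid in setdiff(unique(memb[used]), main)) {
        a_idx <- intersect(which(memb == cid), used)
        b_idx <- intersect(which(memb == main), used)
        d2 <- outer(seq_along(a_idx), seq_along(b_idx), function(i, j)
          (nodes[a_idx[i], 1] - nodes[b_idx[j], 1])^2 +
            (nodes[a_idx[i], 2] - nodes[b_idx[j], 2])^2)
        hit <- arrayInd(which.min(d2), dim(d2))
        edges <- rbind(edges, data.frame(
          from = a_idx[hit[1]], to = b_idx[hit[2]],
          radius_um = mean(spec$capillary_radius), class = "capillary",
          stringsAsFactors = FALSE))
        memb[memb == cid] <- main
      }
    }
    rownames(edges) <- NULL
    structure(list(nodes = nodes, edges = edges,
                   faz_polygon = faz, spec = spec, seed = seed),
              class = "vessel_network")
  })
}

#' @export
print.vessel_network <- function(x, ...) {
  cat(sprintf("<vessel_network> %d nodes, %d edges (%s), FAZ area %.3f mm^2\n",
              nrow(x$nodes), nrow(x$edges),
              paste(names(table(x$edges$class)), table(x$edges$class),
                    sep = ":", collapse = ", "),
              if (is.null(x$faz_polygon)) 0 else shoelace_area(x$faz_polygon)))
  invisible(x)
}

#' Define a circular or annular region of interest in physical coordinates
#'
#' @param inner_d Inner diameter, mm (0 gives a full disk).
#' @param outer_d Outer diameter, mm.
#' @param center Region center (x, y) in mm, fovea-centered coordinates.
#' @return An object of class `annulus_region`.
#' @export
annulus_region <- function(inner_d = 1, outer_d = 2, center = c(0, 0)) {
  if (outer_d <= inner_d || outer_d <= 0 || inner_d < 0)
    stop_domain("need outer_d > inner_d >= 0")
  structure(list(inner_d = inner_d, outer_d = outer_d, center = center),
            class = "annulus_region")
}

in_region <- function(region, x, y) {
  d <- sqrt((x - region$center[1])^2 + (y - region$center[2])^2)
  d >= region$inner_d / 2 & d < region$outer_d / 2
}

# Rasterize vessel capsules over an arbitrary window at a given pitch (um).
# Returns a logical occupancy matrix (rows = y, cols = x).
raster_occupancy <- function(net, pitch_um, xlim, ylim) {
  p <- pitch_um / 1000
  nc <- max(1L, round((xlim[2] - xlim[1]) / p))
  nr <- max(1L, round((ylim[2] - ylim[1]) / p))
  occ <- matrix(FALSE, nr, nc)
  if (!nrow(net$edges)) return(occ)
  e <- net$edges
  x1 <- net$nodes[e$from, 1]; y1 <- net$nodes[e$from, 2]
  x2 <- net$nodes[e$to, 1]; y2 <- net$nodes[e$to, 2]
  r <- e$radius_um / 1000
  col_of <- function(x) (x - xlim[1]) / p + 0.5  # fractional column of x
  row_of <- function(y) (y - ylim[1]) / p + 0.5
  for (i in seq_len(nrow(e))) {
    c0 <- max(1L, floor(col_of(min(x1[i], x2[i]) - r[i])))
    c1 <- min(nc, ceiling(col_of(max(x1[i], x2[i]) + r[i])))
    r0 <- max(1L, floor(row_of(min(y1[i], y2[i]) - r[i])))
    r1 <- min(nr, ceiling(row_of(max(y1[i], y2[i]) + r[i])))
    if (c0 > c1 || r0 > r1) next
    cx <- xlim[1] + (c0:c1 - 0.5) * p
    cy <- ylim[1] + (r0:r1 - 0.5) * p
    gx <- rep(cx, each = length(cy))
    gy <- rep(cy, times = length(cx))
    d <- dist_point_segment(gx, gy, x1[i], y1[i], x2[i], y2[i])
    hit <- matrix(d <= r[i], length(cy), length(cx))
    occ[r0:r1, c0:c1] <- occ[r0:r1, c0:c1] | hit
  }
  occ
}

#' Ground-truth morphometry of a network within a region
#'
#' Computes the quantities the image-based metrics try to recover, directly
#' from the network geometry: total centerline length clipped to the region
#' (1 um arc-length subdivision), perfused area (union of vessel capsules on
#' a 1 um raster), and FAZ polygon area/perimeter (shoelace formula and
#' polyline length).
#'
#' @param net A [generate_network()] result.
#' @param roi An [annulus_region()]; must lie within the field of view.
#' @return List with `true_vessel_length` (mm), `true_perfused_area` (mm^2),
#'   `true_faz_area` (mm^2), `true_faz_perimeter` (mm).
#' @export
network_ground_truth <- function(net, roi = annulus_region(1, 2)) {
  stopifnot(inherits(net, "vessel_network"), inherits(roi, "annulus_region"))
  h <- net$spec$fov / 2
  if (max(abs(roi$center)) + roi$outer_d / 2 > h + 1e-9)
    stop_domain("roi extends beyond the field of view")
  e <- net$edges
  len_in <- 0
  if (nrow(e)) {
    x1 <- net$nodes[e$from, 1]; y1 <- net$nodes[e$from, 2]
    x2 <- net$nodes[e$to, 1]; y2 <- net$nodes[e$to, 2]
    L <- sqrt((x2 - x1)^2 + (y2 - y1)^2)
    ns <- pmax(1L, ceiling(L / 0.001))
    idx <- rep.int(seq_along(L), ns)
    t <- (sequence(ns) - 0.5) / ns[idx]
    px <- x1[idx] + t * (x2[idx] - x1[idx])
    py <- y1[idx] + t * (y2[idx] - y1[idx])
    frac_in <- rowsum(as.numeric(in_region(roi, px, py)), idx) / ns
    len_in <- sum(L * as.numeric(frac_in))
  }
  # perfused area on a 1 um raster over the roi bounding box
  bx <- roi$center[1] + c(-1, 1) * roi$outer_d / 2
  by <- roi$center[2] + c(-1, 1) * roi$outer_d / 2
  bx <- pmin(pmax(bx, -h), h); by <- pmin(pmax(by, -h), h)
  occ <- raster_occupancy(net, 1, bx, by)
  p <- 0.001
  cx <- bx[1] + (seq_len(ncol(occ)) - 0.5) * p
  cy <- by[1] + (seq_len(nrow(occ)) - 0.5) * p
  roim <- outer(cy, cx, function(y, x) in_region(roi, x, y))
  area <- sum(occ & roim) * p^2
  list(
    true_vessel_length = len_in,
    true_perfused_area = area,
    true_faz_area = if (is.null(net$faz_polygon)) 0 else shoelace_area(net$faz_polygon),
    true_faz_perimeter = if (is.null(net$faz_polygon)) 0 else polygon_perimeter(net$faz_polygon)
  )
}

#' Serialize / deserialize a vessel network as JSON
#'
#' @param net A `vessel_network`.
#' @param path Output / input file path.
#' @return `read_network` returns a `vessel_network`.
#' @export
write_network <- function(net, path) {
  obj <- list(nodes = unname(as.matrix(net$nodes)),
              edges = net$edges,
              faz_polygon = if (is.null(net$faz_polygon)) NULL else unname(net$faz_polygon),
              spec = unclass(net$spec), seed = net$seed)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- do.call(vasculature_spec, obj$spec[setdiff(names(obj$spec), NULL)])
  structure(list(nodes = matrix(as.numeric(obj$nodes), ncol = 2),
                 edges = as.data.frame(obj$edges),
                 faz_polygon = if (is.null(obj$faz_polygon)) NULL else
                   matrix(as.numeric(obj$faz_polygon), ncol = 2),
                 spec = spec, seed = obj$seed),
            class = "vessel_network")
}
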