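# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_domain <- function(...) stop(..., call. = FALSE)

#' Evaluate an expression under a fixed RNG seed, restoring global RNG state
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop_domain("seed must be a single finite number")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# Deterministic child-seed derivation (Lehmer-style step, stays below 2^31).
derive_seed <- function(seed, k) {
  s <- (as.numeric(seed) %% 2147483647)
  as.integer((s * 48271 + as.numeric(k) * 7919 + 12345) %% 2147483647)
}

# Shift a matrix by (dr, dc) filling vacated cells.
shift_mat <- function(m, dr, dc, fill = 0) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(fill, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  if (length(rs) && length(cs))
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# Vectorized even-odd point-in-polygon test. poly: m x 2 (open; closure implied).
in_polygon <- function(px, py, poly) {
  n <- nrow(poly)
  xs <- poly[, 1]; ys <- poly[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  inside <- logical(length(px))
  for (i in seq_len(n)) {
    crosses <- ((ys[i] > py) != (ye[i] > py))
    if (any(crosses)) {
      xint <- xs[i] + (py[crosses] - ys[i]) / (ye[i] - ys[i]) * (xe[i] - xs[i])
      inside[crosses] <- xor(inside[crosses], px[crosses] < xint)
    }
  }
  inside
}

# Shoelace area of a polygon (open vertex list), absolute value.
shoelace_area <- function(poly) {
  x <- poly[, 1]; y <- poly[, 2]
  n <- length(x)
  j <- c(2:n, 1)
  abs(sum(x * y[j] - x[j] * y)) / 2
}

polygon_perimeter <- function(poly) {
  n <- nrow(poly)
  j <- c(2:n, 1)
  sum(sqrt((poly[j, 1] - poly[, 1])^2 + (poly[j, 2] - poly[, 2])^2))
}

# TRUE if the closed polygon has no self-intersections (brute-force O(n^2)).
polygon_is_simple <- function(poly) {
  n <- nrow(poly)
  a1 <- poly; a2 <- poly[c(2:n, 1), , drop = FALSE]
  segs_intersect <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2); d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
       ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0)))
  }
  for (i in seq_len(n - 2)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in (i + 2):jmax) {
      if (j > n) next
      if (segs_intersect(a1[i, ], a2[i, ], a1[j, ], a2[j, ])) return(FALSE)
    }
  }
  TRUE
}

# Connected-component labelling on a logical matrix.
# EBImage::bwlabel is 4-connected; for 8-connectivity, diagonal-adjacent
# labels are merged with a small union-find pass.
label_components <- function(mask, connectivity = 8) {
  stopifnot(connectivity %in% c(4, 8))
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(round(lab)), nrow(mask), ncol(mask))
  if (connectivity == 4 || max(lab) <= 1L) return(lab)
  pairs <- NULL
  for (d in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(nrow(lab) - 1), , drop = FALSE]
    b <- lab[-1, , drop = FALSE]
    if (d[2] == 1) { a <- a[, seq_len(ncol(a) - 1), drop = FALSE]; b <- b[, -1, drop = FALSE] }
    else          { a <- a[, -1, drop = FALSE]; b <- b[, seq_len(ncol(b) - 1), drop = FALSE] }
    sel <- a > 0L & b > 0L & a != b
    if (any(sel)) pairs <- rbind(pairs, cbind(a[sel], b[sel]))
  }
  if (is.null(pairs)) return(lab)
  parent <- seq_len(max(lab))
  find <- function(x) { while (parent[x] != x) { parent[x] <<- parent[parent[x]]; x <- parent[x] }; x }
  for (i in seq_len(nrow(pairs))) {
    ra <- find(pairs[i, 1]); rb <- find(pairs[i, 2])
    if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
  }
  root <- vapply(seq_along(parent), find, integer(1))
  root <- match(root, sort(unique(root)))
  lab[lab > 0L] <- root[lab[lab > 0L]]
  lab
}

# Sizes of labelled components, as a named integer vector.
component_sizes <- function(lab) {
  v <- lab[lab > 0L]
  if (!length(v)) return(integer(0))
  tabulate(v, nbins = max(v))
}

# Bilinear interpolation of matrix m at fractional (row, col) positions.
# Positions are clamped to the valid range (replicate border).
bilinear_at <- function(m, r, cc) {
  nr <- nrow(m); nc <- ncol(m)
  r <- pmin(pmax(r, 1), nr); cc <- pmin(pmax(cc, 1), nc)
  r0 <- pmin(floor(r), nr - 1); c0 <- pmin(floor(cc), nc - 1)
  fr <- r - r0; fc <- cc - c0
  i00 <- (c0 - 1) * nr + r0
  m[i00] * (1 - fr) * (1 - fc) + m[i00 + 1] * fr * (1 - fc) +
    m[i00 + nr] * (1 - fr) * fc + m[i00 + nr + 1] * fr * fc
}
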