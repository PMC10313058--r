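# Shared fixtures, built lazily and cached for the duration of a test file.

.octa_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .octa_cache)) assign(key, force(expr), envir = .octa_cache)
  get(key, envir = .octa_cache)
}

# The "default synthetic eye" used by recovery tests (fixed seed).
default_eye <- function() cached("eye42", generate_network(vasculature_spec(), seed = 42))

be_config <- function() default_optical_configs()$beam_expander
std_config <- function() default_optical_configs()$standard

# Beam-expander render of the default eye with default noise.
be_scan <- function() cached("be_scan", {
  render_scan(default_eye(), be_config(), noise_spec(), seed = 7)
})

# Quantification intermediates for the default BE scan.
be_quant <- function() cached("be_quant", quantify_scan(be_scan()))

# Hand-built network: a list of straight vessels in a given field of view.
# segments: data.frame x1, y1, x2, y2 (mm), radius_um, class.
manual_network <- function(segments, fov = 3, faz_polygon = NULL) {
  nodes <- matrix(numeric(0), 0, 2)
  edges <- data.frame(from = integer(0), to = integer(0),
                      radius_um = numeric(0), class = character(0))
  for (i in seq_len(nrow(segments))) {
    nodes <- rbind(nodes, c(segments$x1[i], segments$y1[i]),
                   c(segments$x2[i], segments$y2[i]))
    edges <- rbind(edges, data.frame(from = nrow(nodes) - 1, to = nrow(nodes),
                                     radius_um = segments$radius_um[i],
                                     class = segments$class[i] %||% "capillary"))
  }
  spec <- vasculature_spec(fov = fov, faz_area_target = 0,
                           capillary_point_density = 0, n_radial_vessels = 0)
  structure(list(nodes = nodes, edges = edges, faz_polygon = faz_polygon,
                 spec = spec, seed = 0L), class = "vessel_network")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rasterized disk mask of radius r_px centered in an n x n image.
disk_mask <- function(n, r_px, cx = (n + 1) / 2, cy = (n + 1) / 2) {
  d2 <- outer((seq_len(n) - cy)^2, (seq_len(n) - cx)^2, "+")
  d2 <= r_px^2
}

# Rasterized axis-aligned ellipse mask (semi-axes a_px, b_px).
ellipse_mask <- function(n, a_px, b_px) {
  cx <- (n + 1) / 2
  x <- matrix(rep(seq_len(n) - cx, each = n), n, n)
  y <- matrix(rep(seq_len(n) - cx, n), n, n)
  (x / a_px)^2 + (y / b_px)^2 <= 1
}

# Simple angiogram wrapper around a matrix.
as_scan <- function(px, pitch = 10, fov = nrow(px) * pitch / 1000, ...) {
  enface_angiogram(px, pitch = pitch, fov = fov, ...)
}
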