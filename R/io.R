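#' Write an en-face angiogram as a 16-bit TIFF with a JSON sidecar
#'
#' Integer-valued images with a maximum below 65536 are stored losslessly.
#' Other images are quantized to 16 bits; the scale is recorded in the
#' sidecar (`intensity_max`) so reading reverses it up to quantization.
#'
#' @param scan An `enface_angiogram`.
#' @param image_path Output TIFF path.
#' @param sidecar_path Output JSON path (default: image path + ".json").
#' @return Invisibly, the image path.
#' @export
write_angiogram <- function(scan, image_path,
                            sidecar_path = paste0(image_path, ".json")) {
  stopifnot(inherits(scan, "enface_angiogram"))
  px <- scan$pixels
  integer_native <- all(px == round(px)) && max(px) <= 65535
  meta <- list(pitch_um = scan$pitch, fov_mm = scan$fov,
               fovea_center_px = scan$fovea_center, slab = scan$slab,
               signal_strength = scan$signal_strength, eye_id = scan$eye_id,
               repeat_index = scan$repeat_index, config_name = scan$config_name)
  if (integer_native) {
    tiff::writeTIFF(px / 65535, image_path, bits.per.sample = 16)
  } else {
    imax <- max(px, 1e-12)
    meta$intensity_max <- imax
    tiff::writeTIFF(round(px / imax * 65535) / 65535, image_path,
                    bits.per.sample = 16)
  }
  jsonlite::write_json(meta, sidecar_path, auto_unbox = TRUE, digits = NA)
  invisible(image_path)
}

#' Read an en-face angiogram from a TIFF/PNG image and its JSON sidecar
#'
#' Pixel values are kept in the native integer range (a 16-bit maximum reads
#' as 65535, never silently rescaled to 1), unless the sidecar records an
#' `intensity_max` written by [write_angiogram()], in which case the original
#' physical scale is restored. The image side must agree with
#' `fov_mm * 1000 / pitch_um` within one pixel.
#'
#' @param image_path TIFF or PNG file (8/16-bit grayscale).
#' @param sidecar_path JSON sidecar path (default: image path + ".json").
#' @return An `enface_angiogram`.
#' @export
read_angiogram <- function(image_path, sidecar_path = paste0(image_path, ".json")) {
  meta <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  need <- c("pitch_um", "fov_mm", "slab", "signal_strength")
  miss <- setdiff(need, names(meta))
  if (length(miss)) stop_domain("sidecar missing fields: ", paste(miss, collapse = ", "))
  ext <- tolower(tools::file_ext(image_path))
  if (ext %in% c("tif", "tiff")) {
    px <- tiff::readTIFF(image_path, as.is = TRUE)
  } else if (ext == "png") {
    if (!requireNamespace("png", quietly = TRUE))
      stop_domain("the png package is required to read PNG angiograms")
    px <- png::readPNG(image_path)
    px <- round(px * 65535)
  } else stop_domain("unsupported image format: ", ext)
  if (length(dim(px)) == 3) px <- px[, , 1]
  px <- matrix(as.numeric(px), nrow(px), ncol(px))
  if (!is.null(meta$intensity_max)) px <- px / 65535 * meta$intensity_max
  n_expected <- round(1000 * meta$fov_mm / meta$pitch_um)
  if (abs(nrow(px) - n_expected) > 1)
    stop_domain("image side ", nrow(px), " px inconsistent with sidecar: fov ",
                meta$fov_mm, " mm at ", meta$pitch_um, " um implies ",
                n_expected, " px")
  enface_angiogram(px, pitch = meta$pitch_um, fov = meta$fov_mm,
                   fovea_center = if (!is.null(meta$fovea_center_px))
                     as.numeric(meta$fovea_center_px) else NULL,
                   slab = meta$slab,
                   signal_strength = meta$signal_strength,
                   eye_id = meta$eye_id %||% "unknown",
                   repeat_index = meta$repeat_index %||% 1L,
                   config_name = meta$config_name %||% "unknown")
}

#' Default study configuration
#'
#' The fully resolved default configuration of the simulation/quantification
#' pipeline, as a plain named list (suitable for YAML round-tripping).
#'
#' @return Named list with sections `optics`, `vasculature`, `noise`,
#'   `quantify`, `study`.
#' @export
default_study_config <- function() {
  list(
    optics = list(
      standard = list(pupil_beam_diameter = 0.86, magnification = 1,
                      fov = 3, n_samples = 300, spot_diameter_retina = 25),
      beam_expander = list(pupil_beam_diameter = 0.86, magnification = 2.2,
                           fov = 2.25, n_samples = 300, spot_diameter_retina = 14)
    ),
    vasculature = list(fov = 3, faz_area_target = 0.18, n_radial_vessels = 8,
                       capillary_point_density = 380,
                       capillary_radius = c(2.5, 4), arteriole_radius = 10,
                       capillary_free_halfwidth = 50, vortex_centers = 0,
                       slab = "SCP"),
    noise = list(background_scale = 0.05, speckle_cv = 0.25,
                 defocus_widen = 1),
    quantify = list(scales = c(1, 1.5, 2, 3), beta = 0.5, k = 0.2,
                    min_object_px = 10, max_hole_px = 10,
                    inner_d = 1, outer_d = 2),
    study = list(n_eyes = 22, n_repeats = 3, seed = 1)
  )
}

#' Load and validate a study configuration file
#'
#' Reads a YAML (or JSON) configuration, applies defaults for any omitted
#' keys, and rejects unknown keys by name. An empty file yields the full
#' default configuration.
#'
#' @param path Configuration file path.
#' @return Resolved configuration list (same structure as
#'   [default_study_config()]) with an attribute `objects` holding the
#'   constructed `optical_config`, `vasculature_spec`, `noise_spec` and
#'   `frangi_params` objects.
#' @export
load_study_config <- function(path) {
  raw <- yaml::yaml.load_file(path)
  if (is.null(raw)) raw <- list()
  def <- default_study_config()
  unknown <- setdiff(names(raw), names(def))
  if (length(unknown))
    stop_domain("unknown configuration key: ", paste(unknown, collapse = ", "))
  cfg <- def
  for (sec in names(raw)) {
    bad <- setdiff(names(raw[[sec]]), c(names(def[[sec]]), NULL))
    if (sec != "optics" && length(bad))
      stop_domain("unknown key in '", sec, "': ", paste(bad, collapse = ", "))
    cfg[[sec]] <- utils::modifyList(def[[sec]], raw[[sec]])
  }
  if (!is.null(cfg$vasculature$fov) && cfg$vasculature$fov <= 0)
    stop_domain("fov must be positive")
  objs <- list(
    configs = lapply(names(cfg$optics), function(nm)
      do.call(optical_config, c(list(name = nm), cfg$optics[[nm]]))),
    vasculature = do.call(vasculature_spec, cfg$vasculature),
    noise = do.call(noise_spec, cfg$noise),
    frangi = frangi_params(scales = cfg$quantify$scales, beta = cfg$quantify$beta)
  )
  names(objs$configs) <- names(cfg$optics)
  attr(cfg, "objects") <- objs
  cfg
}

#' Write a configuration list as YAML
#'
#' @param cfg Configuration list (as from [load_study_config()] or
#'   [default_study_config()]).
#' @param path Output path.
#' @export
write_study_config <- function(cfg, path) {
  attr(cfg, "objects") <- NULL
  yaml::write_yaml(cfg, path)
  invisible(path)
}
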