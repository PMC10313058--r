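#' Beam diameter at the pupil plane after telescope magnification
#'
#' A Galilean beam-expander telescope placed before the scanning optics
#' magnifies the collimated beam at the ocular pupil plane by its angular
#' magnification, which in turn shrinks the focused spot on the retina.
#'
#' @param d_pupil Beam diameter at the pupil plane without the expander, mm.
#' @param magnification Telescope magnification (1 for no expander).
#' @return Expanded beam diameter in mm (`d_pupil * magnification`).
#' @examples
#' expanded_beam_diameter(0.86, 2.2)  # ~1.9 mm
#' @export
expanded_beam_diameter <- function(d_pupil, magnification) {
  if (!is.numeric(d_pupil) || any(d_pupil <= 0))
    stop_domain("d_pupil must be positive")
  if (!is.numeric(magnification) || any(magnification <= 0))
    stop_domain("magnification must be positive")
  d_pupil * magnification
}

#' Transverse sampling pitch of a raster scan
#'
#' @param fov Field of view per axis, mm.
#' @param n_samples Number of samples (A-scans) per axis.
#' @return Sampling pitch in micrometres: `1000 * fov / n_samples`.
#' @examples
#' sampling_pitch(3, 300)     # 10 um
#' sampling_pitch(2.25, 300)  # 7.5 um
#' @export
sampling_pitch <- function(fov, n_samples) {
  if (!is.numeric(fov) || any(fov <= 0)) stop_domain("fov must be positive")
  if (!is.numeric(n_samples) || any(n_samples < 1) ||
      any(n_samples != round(n_samples)))
    stop_domain("n_samples must be a positive integer")
  1000 * fov / n_samples
}

#' Diffraction-limited Gaussian spot diameter at the retina
#'
#' Focused-spot 1/e^2 intensity diameter for a collimated Gaussian beam of
#' 1/e^2 diameter `d_pupil` focused by the eye:
#' `4 * wavelength * focal_length / (pi * d_pupil)`.
#' The 1/e^2 convention is used throughout the package. Real systems have
#' additional apertures (e.g. at the scanning galvanometers) that can make
#' the measured spot slightly larger than this pure diffraction limit.
#'
#' @param d_pupil Beam 1/e^2 diameter at the pupil plane, mm.
#' @param wavelength Center wavelength, micrometres (default 1.06).
#' @param focal_length Effective eye focal length, mm (default 17, the
#'   standard reduced-eye value).
#' @return Spot 1/e^2 diameter at the retina, micrometres.
#' @export
gaussian_spot_diameter <- function(d_pupil, wavelength = 1.06, focal_length = 17) {
  if (any(c(d_pupil, wavelength, focal_length) <= 0))
    stop_domain("all inputs must be positive")
  4 * wavelength * focal_length / (pi * d_pupil)
}

#' Rayleigh range of a focused Gaussian beam
#'
#' `pi * w0^2 / wavelength` with waist radius `w0 = spot_diameter / 2`
#' (1/e^2 convention). The Rayleigh range is the axial distance over which
#' the beam cross-section doubles; it is a proxy for depth of focus, hence
#' the tolerance on focus placement at the retina. A smaller spot buys
#' lateral resolution at the cost of a quadratically shorter Rayleigh range.
#'
#' @param spot_diameter Focused-spot 1/e^2 diameter, micrometres.
#' @param wavelength Wavelength, micrometres (default 1.06).
#' @return Rayleigh range in micrometres.
#' @export
rayleigh_range <- function(spot_diameter, wavelength = 1.06) {
  if (any(c(spot_diameter, wavelength) <= 0))
    stop_domain("all inputs must be positive")
  pi * (spot_diameter / 2)^2 / wavelength
}

#' Build an acquisition configuration
#'
#' Bundles the beam/pupil geometry and scan-pattern parameters of one
#' acquisition mode and derives spot size, Rayleigh range and sampling pitch.
#'
#' @param name Configuration label, e.g. `"standard"` or `"beam_expander"`.
#' @param pupil_beam_diameter Native beam diameter at the pupil plane, mm.
#' @param magnification Beam-expander magnification (1 = no expander).
#' @param wavelength Center wavelength, micrometres.
#' @param fov Field of view per axis, mm.
#' @param n_samples Samples per axis.
#' @param focal_length Eye focal length, mm.
#' @param spot_diameter_retina Optional override of the retinal spot 1/e^2
#'   diameter in micrometres. When `NULL`, the diffraction-limited value for
#'   the magnified beam is used. An override is useful when the measured spot
#'   of a real instrument (which includes aperture effects) is known.
#' @return An object of class `optical_config`.
#' @examples
#' optical_config("beam_expander", 0.86, magnification = 2.2,
#'                fov = 2.25, spot_diameter_retina = 14)
#' @export
optical_config <- function(name, pupil_beam_diameter, magnification = 1,
                           wavelength = 1.06, fov = 3, n_samples = 300,
                           focal_length = 17, spot_diameter_retina = NULL) {
  if (pupil_beam_diameter <= 0) stop_domain("pupil_beam_diameter must be positive")
  if (magnification < 1) stop_domain("magnification must be >= 1")
  d_eff <- expanded_beam_diameter(pupil_beam_diameter, magnification)
  spot_dl <- gaussian_spot_diameter(d_eff, wavelength, focal_length)
  spot <- spot_diameter_retina %||% spot_dl
  structure(list(
    name = name,
    pupil_beam_diameter = pupil_beam_diameter,
    magnification = magnification,
    wavelength = wavelength,
    expanded_beam_diameter = d_eff,
    spot_diameter_retina = spot,
    spot_diameter_diffraction = spot_dl,
    rayleigh_range = rayleigh_range(spot, wavelength),
    fov = fov,
    n_samples = as.integer(n_samples),
    pitch = sampling_pitch(fov, n_samples),
    focal_length = focal_length
  ), class = "optical_config")
}

#' The two acquisition configurations of the resolution study
#'
#' Standard mode: 0.86 mm pupil beam, ~25 um retinal spot, 3 mm field of
#' view at 300 samples (10 um pitch). Beam-expander mode: 2.2x telescope,
#' ~14 um spot, 2.25 mm field of view at 300 samples (7.5 um pitch). The
#' retinal spot diameters are the instrument's nominal values, which include
#' the galvanometer-aperture effect that the pure diffraction formula omits.
#'
#' @return Named list with elements `standard` and `beam_expander`.
#' @export
default_optical_configs <- function() {
  list(
    standard = optical_config("standard", 0.86, magnification = 1,
                              fov = 3, n_samples = 300,
                              spot_diameter_retina = 25),
    beam_expander = optical_config("beam_expander", 0.86, magnification = 2.2,
                                   fov = 2.25, n_samples = 300,
                                   spot_diameter_retina = 14)
  )
}

#' Tabulate derived optical quantities for a set of configurations
#'
#' @param configs List of `optical_config` objects
#'   (default [default_optical_configs()]).
#' @return A data.frame with one row per configuration.
#' @export
optics_table <- function(configs = default_optical_configs()) {
  do.call(rbind, lapply(configs, function(cf) {
    data.frame(
      name = cf$name,
      pupil_beam_mm = cf$pupil_beam_diameter,
      magnification = cf$magnification,
      expanded_beam_mm = cf$expanded_beam_diameter,
      spot_um = cf$spot_diameter_retina,
      spot_diffraction_um = cf$spot_diameter_diffraction,
      rayleigh_um = cf$rayleigh_range,
      fov_mm = cf$fov,
      n_samples = cf$n_samples,
      pitch_um = cf$pitch,
      row.names = NULL
    )
  }))
}

#' @export
print.optical_config <- function(x, ...) {
  cat(sprintf("<optical_config> %s\n", x$name))
  cat(sprintf("  beam at pupil: %.3g mm x %.2g = %.3g mm\n",
              x$pupil_beam_diameter, x$magnification, x$expanded_beam_diameter))
  cat(sprintf("  retinal spot (1/e2): %.3g um (diffraction limit %.3g um)\n",
              x$spot_diameter_retina, x$spot_diameter_diffraction))
  cat(sprintf("  Rayleigh range: %.3g um\n", x$rayleigh_range))
  cat(sprintf("  scan: %d x %d over %.3g mm (pitch %.3g um)\n",
              x$n_samples, x$n_samples, x$fov, x$pitch))
  invisible(x)
}
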