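# System geometry and the elementary illumination descriptors.

#' Optical system geometry for Fourier-plane pattern design
#'
#' Describes the relay from a binary micromirror array (DMD) sitting in a
#' plane conjugate to the objective back focal plane, through to the sample.
#' A spot displayed on the DMD at position `rp` with carrier frequency `fp`
#' produces a plane wave in the sample whose angle is set by the spot
#' *position* and whose lateral offset is set by the spot *frequency*:
#' `delta_r = (fl * lambda / M) * (fp - fc)` and
#' `f = (M / (fl * lambda)) * (rp - rc)`.
#'
#' @param objective_focal_length focal length of the objective (millimetres).
#' @param magnification_dmd_to_bfp magnification M between the DMD plane and
#'   the objective back focal plane (dimensionless).
#' @param wavelength vacuum wavelength (micrometres).
#' @param carrier_frequency length-2 spatial carrier frequency on the DMD
#'   (cycles per micrometre, (fy, fx)).
#' @param dmd_center length-2 DMD position aligned with the optical axis
#'   (micrometres, (y, x), measured from the DMD corner).
#' @param mirror_pitch mirror pitch (micrometres).
#' @param dmd_shape integer pair (rows, cols) of the mirror array.
#' @param illumination_na numerical aperture available for illumination.
#' @param detection_na numerical aperture of the detection path.
#' @param background_index background (immersion) refractive index n0.
#' @return an object of class `system_geometry`.
#' @export
system_geometry <- function(objective_focal_length = 3.333,
                            magnification_dmd_to_bfp = 0.85,
                            wavelength = 0.785,
                            carrier_frequency = c(0, 1 / (4 * 7.56)),
                            dmd_center = NULL,
                            mirror_pitch = 7.56,
                            dmd_shape = c(1080L, 1920L),
                            illumination_na = 0.9,
                            detection_na = 1.0,
                            background_index = 1.515) {
  if (is.null(dmd_center)) {
    dmd_center <- (dmd_shape / 2) * mirror_pitch
  }
  g <- structure(list(
    objective_focal_length = objective_focal_length,
    magnification_dmd_to_bfp = magnification_dmd_to_bfp,
    wavelength = wavelength,
    carrier_frequency = as.numeric(carrier_frequency),
    dmd_center = as.numeric(dmd_center),
    mirror_pitch = mirror_pitch,
    dmd_shape = as.integer(dmd_shape),
    illumination_na = illumination_na,
    detection_na = detection_na,
    background_index = background_index
  ), class = "system_geometry")
  validate_system_geometry(g)
  g
}

validate_system_geometry <- function(g) {
  stopifnot(
    g$objective_focal_length > 0, g$magnification_dmd_to_bfp > 0,
    g$wavelength > 0, g$mirror_pitch > 0,
    all(g$dmd_shape >= 1L),
    length(g$carrier_frequency) == 2, length(g$dmd_center) == 2
  )
  if (g$illumination_na <= 0 || g$illumination_na > g$background_index)
    stop("illumination_na must lie in (0, background_index]")
  if (g$detection_na <= 0 || g$detection_na > g$background_index)
    stop("detection_na must lie in (0, background_index]")
  nyq <- 1 / (2 * g$mirror_pitch)
  if (sqrt(sum(g$carrier_frequency^2)) >= nyq)
    stop("carrier frequency must be below the DMD Nyquist frequency 1/(2*pitch)")
  invisible(g)
}

# Focal length in micrometres (stored in mm per convention for objectives).
.fl_um <- function(geom) geom$objective_focal_length * 1000

# Pupil radius expressed as a distance on the DMD face (micrometres):
# |rp - rc| at which |f| = NA/lambda.
#' @rdname system_geometry
#' @param geom a `system_geometry`.
#' @param na numerical aperture defining the pupil (defaults to the
#'   illumination NA).
#' @export
dmd_pupil_radius <- function(geom, na = geom$illumination_na) {
  .fl_um(geom) * na / geom$magnification_dmd_to_bfp
}

#' @export
print.system_geometry <- function(x, ...) {
  cat("<system_geometry>\n")
  cat(sprintf("  objective fl %.3f mm, M(DMD->BFP) %.3f, lambda %.3f um\n",
              x$objective_focal_length, x$magnification_dmd_to_bfp, x$wavelength))
  cat(sprintf("  DMD %d x %d mirrors, pitch %.2f um, carrier (%.4f, %.4f) 1/um\n",
              x$dmd_shape[1], x$dmd_shape[2], x$mirror_pitch,
              x$carrier_frequency[1], x$carrier_frequency[2]))
  cat(sprintf("  NA ill/det %.2f/%.2f, n0 %.4f\n",
              x$illumination_na, x$detection_na, x$background_index))
  invisible(x)
}

#' Single plane-wave illumination in the sample plane
#'
#' @param object_frequency length-2 spatial frequency (fy, fx) in the sample
#'   plane (cycles per micrometre); sets the illumination angle through
#'   `sin(theta) = |f| * lambda / n0`.
#' @param position_offset length-2 lateral displacement (y, x) of the beam in
#'   the sample plane (micrometres).
#' @param phase phase of the beam (radians).
#' @param amplitude relative amplitude (dimensionless).
#' @return an object of class `plane_wave`.
#' @export
plane_wave <- function(object_frequency = c(0, 0), position_offset = c(0, 0),
                       phase = 0, amplitude = 1) {
  structure(list(
    object_frequency = as.numeric(object_frequency),
    position_offset = as.numeric(position_offset),
    phase = as.numeric(phase),
    amplitude = as.numeric(amplitude)
  ), class = "plane_wave")
}

#' Spot pattern descriptor on the DMD
#'
#' @param spot_frequency length-2 DMD-plane spatial frequency (fy, fx) of the
#'   binary carrier (cycles per micrometre).
#' @param spot_position length-2 DMD position (y, x) of the spot centre
#'   (micrometres from the DMD corner).
#' @param phase carrier phase (radians).
#' @param diameter spot diameter in mirrors.
#' @return an object of class `spot_spec`.
#' @export
spot_spec <- function(spot_frequency, spot_position, phase = 0, diameter = 20) {
  s <- structure(list(
    spot_frequency = as.numeric(spot_frequency),
    spot_position = as.numeric(spot_position),
    phase = as.numeric(phase),
    diameter = as.numeric(diameter)
  ), class = "spot_spec")
  s
}

validate_spot <- function(s, geom) {
  if (s$diameter < 0) stop("spot diameter must be non-negative")
  nyq <- 1 / (2 * geom$mirror_pitch)
  if (sqrt(sum(s$spot_frequency^2)) >= nyq)
    stop("spot carrier frequency at or above the DMD Nyquist frequency")
  invisible(s)
}
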