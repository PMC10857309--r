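#' Viewing geometry of a binocular gaze recording
#'
#' Bundles the physical quantities needed to convert on-screen gaze
#' coordinates (pixels) into angular gaze directions: eye-to-screen
#' distance, screen resolution and physical size, and the interocular
#' distance. Defaults describe a 15.6-inch 16:9 HD laptop panel
#' (1366 x 768 px, 345.2 x 194.2 mm) viewed from 500 mm with the adult
#' population-average interpupillary distance of 63 mm.
#'
#' @param viewing_distance Eye-to-screen distance in mm.
#' @param screen_w_px,screen_h_px Screen resolution in pixels.
#' @param screen_w_mm,screen_h_mm Physical screen size in mm.
#' @param ipd Interocular (interpupillary) distance in mm.
#' @return An object of class `"geometry_config"`.
#' @examples
#' geom <- geometry_config()
#' vergence_angle(
#'   gaze_to_azimuth(683, -geom$ipd / 2, geom),
#'   gaze_to_azimuth(683, +geom$ipd / 2, geom)
#' ) # ~7.21 deg for symmetric fixation of the screen centre
#' @export
geometry_config <- function(viewing_distance = 500,
                            screen_w_px = 1366, screen_h_px = 768,
                            screen_w_mm = 345.2, screen_h_mm = 194.2,
                            ipd = 63) {
  vals <- list(viewing_distance = viewing_distance,
               screen_w_px = screen_w_px, screen_h_px = screen_h_px,
               screen_w_mm = screen_w_mm, screen_h_mm = screen_h_mm,
               ipd = ipd)
  for (nm in names(vals)) {
    stopifnot_scalar_number(vals[[nm]], nm)
    if (vals[[nm]] <= 0) param_error("'%s' must be strictly positive", nm)
  }
  structure(vals, class = "geometry_config")
}

#' @export
print.geometry_config <- function(x, ...) {
  cat("Viewing geometry:\n")
  cat(sprintf("  distance %g mm, IPD %g mm\n", x$viewing_distance, x$ipd))
  cat(sprintf("  screen %g x %g px (%g x %g mm)\n",
              x$screen_w_px, x$screen_h_px, x$screen_w_mm, x$screen_h_mm))
  invisible(x)
}

# horizontal pixel coordinate -> mm from screen centre (positive rightward)
px_to_mm_x <- function(gaze_x, geometry) {
  (gaze_x - geometry$screen_w_px / 2) * geometry$screen_w_mm / geometry$screen_w_px
}

mm_to_px_x <- function(x_mm, geometry) {
  x_mm * geometry$screen_w_px / geometry$screen_w_mm + geometry$screen_w_px / 2
}

# screen pixels subtended by one degree of gaze rotation at the viewing distance
px_per_deg <- function(geometry) {
  geometry$viewing_distance * (pi / 180) *
    geometry$screen_w_px / geometry$screen_w_mm
}

#' Horizontal gaze direction of one eye
#'
#' Converts an on-screen horizontal gaze coordinate (pixels) into the
#' azimuth of the eye's line of sight, measured in a common head-centred
#' frame where positive angles point rightward. The eye sits at
#' `eye_offset` mm right of the line normal to the screen centre (so the
#' left eye has a negative offset, conventionally `-ipd/2`).
#'
#' @param gaze_x Horizontal gaze coordinate on screen, in pixels. Vectorised.
#' @param eye_offset Signed horizontal eye position in mm relative to the
#'   screen-centre normal.
#' @param geometry A [geometry_config()].
#' @return Azimuth in degrees (positive = rightward), same length as `gaze_x`.
#' @export
gaze_to_azimuth <- function(gaze_x, eye_offset, geometry) {
  x_mm <- px_to_mm_x(gaze_x, geometry)
  atan((x_mm - eye_offset) / geometry$viewing_distance) * 180 / pi
}

#' Vergence angle from the two eyes' azimuths
#'
#' The vergence angle gamma is the angle between the left- and right-eye
#' lines of sight, `gamma = left_azimuth - right_azimuth`, with both
#' azimuths in the common positive-rightward frame. Two eyes fixating a
#' common point nearer than optical infinity give gamma > 0, and gamma
#' increases as fixation moves closer (convergence). Symmetric fixation at
#' distance `d` gives the closed form `2 * atan(ipd / (2 d))`.
#'
#' @param left_azimuth,right_azimuth Azimuths in degrees
#'   (see [gaze_to_azimuth()]). Vectorised.
#' @return Vergence angle in degrees.
#' @export
vergence_angle <- function(left_azimuth, right_azimuth) {
  left_azimuth - right_azimuth
}

# per-sample vergence angle series from on-screen pixel coordinates
gamma_from_px <- function(left_x, right_x, geometry) {
  vergence_angle(gaze_to_azimuth(left_x, -geometry$ipd / 2, geometry),
                 gaze_to_azimuth(right_x, +geometry$ipd / 2, geometry))
}
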