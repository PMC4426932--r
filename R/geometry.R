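#' Machine geometry constants
#'
#' Geometry of the linac / portal-imager setup used throughout the package:
#' source-axis distance (SAD), source-imager distance (SID), the water depth
#' of the measurement plane, and the portal imager (EPID) panel layout.
#' All lengths are millimetres.
#'
#' @param sad Source-to-isocenter distance in mm.
#' @param sid Source-to-imager distance in mm.
#' @param measurement_depth Depth of the QA measurement plane in mm.
#' @param epid_pixels Integer pair, EPID panel size in pixels (rows, cols).
#' @param epid_pitch EPID pixel pitch in mm/pixel at the detector plane.
#'
#' @return An object of class `rt_geometry`.
#' @export
#' @examples
#' g <- rt_geometry()
#' g$sid / g$sad   # imager magnification, 1.5
rt_geometry <- function(sad = 1000, sid = 1500, measurement_depth = 100,
                        epid_pixels = c(1024L, 1024L), epid_pitch = 0.40) {
  if (!(sid > sad && sad > 0)) {
    stop("rt_geometry: need sid > sad > 0", call. = FALSE)
  }
  structure(
    list(sad = sad, sid = sid, measurement_depth = measurement_depth,
         epid_pixels = as.integer(epid_pixels), epid_pitch = epid_pitch),
    class = "rt_geometry"
  )
}

#' Project patient-space points into the beam's-eye-view isocenter plane
#'
#' Rotates points into the beam-fixed frame for a gantry angle (IEC 61217:
#' rotation about the patient's longitudinal axis, gantry 0 pointing down
#' from above) and projects them divergently from the source onto the plane
#' through the isocenter perpendicular to the beam axis.
#'
#' The beam frame is `x_b = x cos(theta) - z sin(theta)`, `y_b = y`,
#' `z_b = x sin(theta) + z cos(theta)` with `z_b` pointing toward the source;
#' the projection is `u = x_b * sad / (sad - z_b)` (crossplane, along MLC
#' leaf travel) and `v = y_b * sad / (sad - z_b)` (inplane, along leaf width).
#'
#' @param points Numeric matrix (n x 3) or length-3 vector of patient
#'   coordinates in mm (isocenter origin).
#' @param gantry_angle Gantry angle in degrees, IEC 61217.
#' @param geometry An [rt_geometry()] object.
#'
#' @return An n x 2 matrix with columns `u`, `v` (mm in the isocenter plane).
#' @export
#' @examples
#' project_voxel_to_bev(c(10, 0, 0), 0)  # u = 10, v = 0
project_voxel_to_bev <- function(points, gantry_angle, geometry = rt_geometry()) {
  if (is.null(dim(points))) points <- matrix(points, ncol = 3L, byrow = TRUE)
  stopifnot(ncol(points) == 3L)
  th <- gantry_angle * pi / 180
  ct <- cos(th); st <- sin(th)
  xb <- points[, 1L] * ct - points[, 3L] * st
  yb <- points[, 2L]
  zb <- points[, 1L] * st + points[, 3L] * ct
  sad <- geometry$sad
  if (any(zb >= sad)) {
    stop("project_voxel_to_bev: point at or behind the source (z_b >= sad)",
         call. = FALSE)
  }
  f <- sad / (sad - zb)
  cbind(u = xb * f, v = yb * f)
}
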