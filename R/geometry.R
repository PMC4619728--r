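#' Screen and viewing geometry
#'
#' Describes the display and viewing distance used to convert gaze
#' coordinates from screen pixels to degrees of visual angle. Defaults
#' correspond to a 17-inch 4:3 monitor at 1024 x 768 driven from 60 cm,
#' the typical set-up for remote eye trackers used with young children.
#'
#' @param resolution_px Integer vector of length 2, horizontal and vertical
#'   resolution in pixels.
#' @param screen_cm Numeric vector of length 2, physical width and height of
#'   the display area in centimetres.
#' @param distance_cm Viewing distance in centimetres.
#'
#' @return An object of class `screen_geometry`.
#' @examples
#' geom <- screen_geometry()
#' px_per_degree(geom) # about 31 px per degree on each axis
#' @export
screen_geometry <- function(resolution_px = c(1024L, 768L),
                            screen_cm = c(34.5, 25.9),
                            distance_cm = 60) {
  stopifnot(length(resolution_px) == 2, length(screen_cm) == 2,
            length(distance_cm) == 1)
  if (any(c(resolution_px, screen_cm, distance_cm) <= 0)) {
    abort("All geometry dimensions must be positive.", class = "gazenet_config_error")
  }
  structure(
    list(resolution_px = as.numeric(resolution_px),
         screen_cm = as.numeric(screen_cm),
         distance_cm = as.numeric(distance_cm)),
    class = "screen_geometry"
  )
}

#' @export
print.screen_geometry <- function(x, ...) {
  cat(sprintf("<screen_geometry> %d x %d px, %.1f x %.1f cm, %.0f cm viewing distance\n",
              x$resolution_px[1], x$resolution_px[2],
              x$screen_cm[1], x$screen_cm[2], x$distance_cm))
  invisible(x)
}

#' Pixels per degree of visual angle
#'
#' Small-angle planar conversion: one degree subtends
#' `distance_cm * tan(1 degree)` centimetres at the screen plane, divided by
#' the physical pixel pitch per axis. `exact = TRUE` instead converts a pixel
#' offset from screen centre through the arctangent; the difference is
#' negligible for stimuli up to about 20 degrees but the option makes the
#' approximation explicit.
#'
#' @param geometry A [screen_geometry()].
#' @return Named numeric vector `c(x =, y =)`, pixels per degree on each axis.
#' @export
px_per_degree <- function(geometry) {
  stopifnot(inherits(geometry, "screen_geometry"))
  cm_per_deg <- geometry$distance_cm * tan(pi / 180)
  pitch <- geometry$screen_cm / geometry$resolution_px # cm per px
  c(x = cm_per_deg / pitch[1], y = cm_per_deg / pitch[2])
}

#' Convert a pixel displacement to degrees of visual angle
#'
#' @param dx,dy Displacement in pixels along each axis.
#' @param geometry A [screen_geometry()].
#' @param exact If `TRUE`, use the full arctangent of the physical
#'   displacement; otherwise the planar small-angle approximation.
#' @return Numeric vector of angular displacements in degrees.
#' @export
px_to_degrees <- function(dx, dy, geometry, exact = FALSE) {
  stopifnot(inherits(geometry, "screen_geometry"))
  pitch <- geometry$screen_cm / geometry$resolution_px
  dcm <- sqrt((dx * pitch[1])^2 + (dy * pitch[2])^2)
  if (exact) {
    atan(dcm / geometry$distance_cm) * 180 / pi
  } else {
    dcm / (geometry$distance_cm * tan(pi / 180))
  }
}
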