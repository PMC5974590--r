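#' Physical display model
#'
#' Describes the monitor that gaze coordinates refer to: pixel resolution plus
#' physical size, from which the physical size of one pixel (the pixel pitch)
#' is derived. The pitch is the bridge between pixel coordinates in a gaze
#' export and degrees of visual angle.
#'
#' Either `diagonal_cm` alone (square pixels assumed) or both `width_cm` and
#' `height_cm` must be given. The default corresponds to a 27-inch 1920x1080
#' monitor, a common desk-mounted eye-tracking setup.
#'
#' @param resolution_x,resolution_y Pixel counts of the display.
#' @param diagonal_cm Physical diagonal in cm (27 in = 68.58 cm).
#' @param width_cm,height_cm Explicit physical width/height in cm; overrides
#'   the square-pixel assumption made when only a diagonal is given.
#' @return An object of class `display_model` with fields `resolution_x`,
#'   `resolution_y`, `width_cm`, `height_cm`, `pitch_x_cm`, `pitch_y_cm`.
#' @examples
#' d <- display_model()          # 27-inch 1920x1080
#' pixel_pitch(d)                # ~0.0311 cm/px on both axes
#' @export
display_model <- function(resolution_x = 1920, resolution_y = 1080,
                          diagonal_cm = 27 * 2.54,
                          width_cm = NULL, height_cm = NULL) {
  if (!is.numeric(resolution_x) || length(resolution_x) != 1L ||
      !is.finite(resolution_x) || resolution_x <= 0 ||
      !is.numeric(resolution_y) || length(resolution_y) != 1L ||
      !is.finite(resolution_y) || resolution_y <= 0) {
    stop("invalid geometry: resolution_x and resolution_y must be positive numbers",
         call. = FALSE)
  }
  if (!is.null(width_cm) || !is.null(height_cm)) {
    if (is.null(width_cm) || is.null(height_cm)) {
      stop("invalid geometry: width_cm and height_cm must be given together",
           call. = FALSE)
    }
    if (width_cm <= 0 || height_cm <= 0) {
      stop("invalid geometry: width_cm and height_cm must be positive", call. = FALSE)
    }
  } else {
    if (!is.numeric(diagonal_cm) || length(diagonal_cm) != 1L ||
        !is.finite(diagonal_cm) || diagonal_cm <= 0) {
      stop("invalid geometry: diagonal_cm must be a positive number", call. = FALSE)
    }
    # square pixels: split the diagonal in proportion to the pixel grid
    diag_px <- sqrt(resolution_x^2 + resolution_y^2)
    width_cm <- diagonal_cm * resolution_x / diag_px
    height_cm <- diagonal_cm * resolution_y / diag_px
  }
  structure(
    list(
      resolution_x = as.numeric(resolution_x),
      resolution_y = as.numeric(resolution_y),
      width_cm = width_cm,
      height_cm = height_cm,
      pitch_x_cm = width_cm / resolution_x,
      pitch_y_cm = height_cm / resolution_y
    ),
    class = "display_model"
  )
}

#' @export
print.display_model <- function(x, ...) {
  cat(sprintf("<display_model> %g x %g px, %.2f x %.2f cm (pitch %.5f, %.5f cm/px)\n",
              x$resolution_x, x$resolution_y, x$width_cm, x$height_cm,
              x$pitch_x_cm, x$pitch_y_cm))
  invisible(x)
}

stopifnot_display <- function(display) {
  if (!inherits(display, "display_model")) {
    stop("`display` must be a display_model object", call. = FALSE)
  }
  invisible(display)
}

stopifnot_distance <- function(distance_cm) {
  if (!is.numeric(distance_cm) || length(distance_cm) != 1L ||
      !is.finite(distance_cm) || distance_cm <= 0) {
    stop("invalid geometry: viewing distance must be a positive number of cm",
         call. = FALSE)
  }
  invisible(distance_cm)
}

#' Physical size of one pixel
#'
#' @param display A [display_model()].
#' @return Named numeric vector `c(x = , y = )` in cm per pixel.
#' @export
pixel_pitch <- function(display) {
  stopifnot_display(display)
  c(x = display$pitch_x_cm, y = display$pitch_y_cm)
}

#' Convert a pixel displacement to degrees of visual angle
#'
#' The angle subtended at the eye by a displacement of `offset_px` pixels on
#' the screen plane, for an eye on the perpendicular through screen center:
#' `atan(offset_px * pitch / distance)`. Odd and strictly increasing in the
#' offset; vectorised over `offset_px`.
#'
#' @param offset_px Pixel displacement(s); may be fractional or negative.
#' @param display A [display_model()].
#' @param distance_cm Viewing distance in cm.
#' @param axis `"x"` or `"y"`; selects which pixel pitch applies.
#' @return Angle(s) in degrees, same sign as `offset_px`.
#' @examples
#' px_offset_to_deg(480, display_model(), 60)   # ~14.0 degrees
#' px_offset_to_deg(270, display_model(), 60, axis = "y")  # ~8.0 degrees
#' @export
px_offset_to_deg <- function(offset_px, display, distance_cm, axis = c("x", "y")) {
  stopifnot_display(display)
  stopifnot_distance(distance_cm)
  axis <- match.arg(axis)
  pitch <- if (axis == "x") display$pitch_x_cm else display$pitch_y_cm
  atan(offset_px * pitch / distance_cm) * 180 / pi
}

#' Convert degrees of visual angle to a pixel displacement
#'
#' Exact inverse of [px_offset_to_deg()] when `round = FALSE`.
#'
#' @param angle_deg Angle(s) in degrees; must satisfy `abs(angle_deg) < 90`.
#' @param display A [display_model()].
#' @param distance_cm Viewing distance in cm.
#' @param axis `"x"` or `"y"`.
#' @param round Round the result to whole pixels.
#' @return Pixel displacement(s).
#' @export
deg_to_px <- function(angle_deg, display, distance_cm, axis = c("x", "y"),
                      round = FALSE) {
  stopifnot_display(display)
  stopifnot_distance(distance_cm)
  axis <- match.arg(axis)
  if (any(abs(angle_deg) >= 90, na.rm = TRUE)) {
    stop("invalid angle: |angle_deg| must be < 90", call. = FALSE)
  }
  pitch <- if (axis == "x") display$pitch_x_cm else display$pitch_y_cm
  px <- tan(angle_deg * pi / 180) * distance_cm / pitch
  if (round) round(px) else px
}

#' Per-axis visual angles of on-screen points
#'
#' Converts pixel coordinates (origin top-left, x rightward, y downward) to
#' per-axis angles relative to the line of sight through screen center. This
#' is the angular convention used throughout: each axis is converted with its
#' own arctangent, and two-point separations combine the per-axis angular
#' offsets Euclideanly.
#'
#' @param x_px,y_px Pixel coordinates (vectorised).
#' @param display A [display_model()].
#' @param distance_cm Viewing distance in cm.
#' @return A two-column matrix with columns `ax_deg`, `ay_deg`.
#' @export
point_angles <- function(x_px, y_px, display, distance_cm) {
  stopifnot_display(display)
  stopifnot_distance(distance_cm)
  cbind(
    ax_deg = atan((x_px - display$resolution_x / 2) * display$pitch_x_cm / distance_cm) * 180 / pi,
    ay_deg = atan((y_px - display$resolution_y / 2) * display$pitch_y_cm / distance_cm) * 180 / pi
  )
}

#' Inverse of [point_angles()]: per-axis angles back to pixel coordinates
#'
#' @param ax_deg,ay_deg Per-axis angles in degrees relative to screen center.
#' @inheritParams point_angles
#' @return A two-column matrix with columns `x_px`, `y_px`.
#' @export
angles_to_point <- function(ax_deg, ay_deg, display, distance_cm) {
  stopifnot_display(display)
  stopifnot_distance(distance_cm)
  cbind(
    x_px = tan(ax_deg * pi / 180) * distance_cm / display$pitch_x_cm + display$resolution_x / 2,
    y_px = tan(ay_deg * pi / 180) * distance_cm / display$pitch_y_cm + display$resolution_y / 2
  )
}

#' Angular separation between two on-screen points
#'
#' Euclidean combination of the per-axis angular offsets of `p` and `q` (see
#' [point_angles()] for the convention). Symmetric, zero iff `p == q`, and
#' satisfies the triangle inequality.
#'
#' @param p,q Length-2 numeric vectors `c(x_px, y_px)`, or n-by-2 matrices.
#' @param display A [display_model()].
#' @param distance_cm Viewing distance in cm.
#' @return Angle(s) in degrees.
#' @examples
#' d <- display_model()
#' angular_separation(c(960, 540), c(990, 540), d, 60)
#' @export
angular_separation <- function(p, q, display, distance_cm) {
  p <- if (is.matrix(p)) p else matrix(p, ncol = 2)
  q <- if (is.matrix(q)) q else matrix(q, ncol = 2)
  ap <- point_angles(p[, 1], p[, 2], display, distance_cm)
  aq <- point_angles(q[, 1], q[, 2], display, distance_cm)
  as.numeric(sqrt((ap[, 1] - aq[, 1])^2 + (ap[, 2] - aq[, 2])^2))
}

#' Default five-target verification layout
#'
#' Five targets: one at each screen corner, inset by `inset_px` pixels from
#' the nearest edges, plus one at screen center. On a 1920x1080 display with
#' the default inset of (480, 270) px the corner targets sit at 14 and 8
#' degrees of horizontal/vertical eccentricity at a 60 cm viewing distance,
#' and the center target at (960, 540) px.
#'
#' @param display A [display_model()].
#' @param inset_px Length-2 vector: horizontal and vertical inset of the
#'   corner targets from the screen edges, in pixels.
#' @param diameter_deg Target diameter in degrees (annotation only; the
#'   default is a 0.63 degree bullseye with three annuli growing by 0.63
#'   degrees each, i.e. 2.52 degrees overall).
#' @return A `target_layout` data frame with columns `target_id`, `x_px`,
#'   `y_px` and attribute `diameter_deg`.
#' @export
default_target_layout <- function(display, inset_px = c(480, 270),
                                  diameter_deg = 2.52) {
  stopifnot_display(display)
  rx <- display$resolution_x
  ry <- display$resolution_y
  ix <- inset_px[1]
  iy <- inset_px[2]
  if (ix <= 0 || ix >= rx / 2 || iy <= 0 || iy >= ry / 2) {
    stop("invalid geometry: target inset must place targets on-screen", call. = FALSE)
  }
  layout <- data.frame(
    target_id = c("upper_left", "upper_right", "center", "lower_left", "lower_right"),
    x_px = c(ix, rx - ix, rx / 2, ix, rx - ix),
    y_px = c(iy, iy, ry / 2, ry - iy, ry - iy),
    stringsAsFactors = FALSE
  )
  attr(layout, "diameter_deg") <- diameter_deg
  class(layout) <- c("target_layout", "data.frame")
  layout
}

#' Read a display/viewing geometry config
#'
#' Reads the `display` block of a YAML config file. Recognised keys:
#' `resolution_x`, `resolution_y`, and either `diagonal_cm` or
#' `width_cm` + `height_cm`, plus `viewing_distance_cm_default`.
#'
#' @param path Path to a YAML file with a top-level `display` block (or the
#'   keys at top level).
#' @return A list with elements `display` (a [display_model()]) and
#'   `viewing_distance_cm_default` (numeric, 60 if unspecified).
#' @export
read_geometry_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  blk <- if (!is.null(cfg$display)) cfg$display else cfg
  display <- display_model(
    resolution_x = blk$resolution_x %||% 1920,
    resolution_y = blk$resolution_y %||% 1080,
    diagonal_cm = blk$diagonal_cm %||% (27 * 2.54),
    width_cm = blk$width_cm,
    height_cm = blk$height_cm
  )
  list(
    display = display,
    viewing_distance_cm_default = blk$viewing_distance_cm_default %||% 60
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
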