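#' Screen and viewing geometry
#'
#' A screen model holds the physical monitor dimensions, its pixel
#' resolution, and the viewing distance, and provides the pixel to
#' degree-of-visual-angle conversion used by every procedure in the
#' package. Screen coordinates have their origin at the geometric center
#' of the screen, with x increasing rightward and y increasing upward.
#'
#' Pixels must be square: the horizontal and vertical pixels-per-cm must
#' agree within 1%, otherwise construction fails. Anisotropic displays are
#' not supported.
#'
#' @param width_cm,height_cm Physical screen size in cm.
#' @param width_pix,height_pix Screen resolution in pixels.
#' @param viewing_distance_cm Eye-to-screen-center distance in cm.
#' @return An object of class `bs_screen`.
#' @examples
#' scr <- screen_model(40, 30, 1280, 960, 57)
#' pix_to_deg(300, scr)  # about 9.34 degrees
#' @export
screen_model <- function(width_cm, height_cm, width_pix, height_pix,
                         viewing_distance_cm) {
  vals <- c(width_cm, height_cm, width_pix, height_pix, viewing_distance_cm)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all screen parameters must be strictly positive and finite")
  ppc_x <- width_pix / width_cm
  ppc_y <- height_pix / height_cm
  if (abs(ppc_x - ppc_y) / ppc_x > 0.01)
    stop("non-square pixels: horizontal and vertical pixels/cm differ by more than 1%")
  structure(
    list(width_cm = width_cm, height_cm = height_cm,
         width_pix = width_pix, height_pix = height_pix,
         viewing_distance_cm = viewing_distance_cm,
         cm_per_pix = width_cm / width_pix),
    class = "bs_screen")
}

#' Default screen model
#'
#' The default apparatus: a 40 x 30 cm monitor at 1280 x 960 pixels viewed
#' from 57 cm, at which distance 1 cm at screen center subtends very nearly
#' 1 degree (about 32 pixels per degree).
#'
#' @return A `bs_screen` object.
#' @export
default_screen <- function() screen_model(40, 30, 1280, 960, 57)

#' @export
print.bs_screen <- function(x, ...) {
  cat(sprintf("<bs_screen> %.1f x %.1f cm, %d x %d pix, viewing distance %.1f cm\n",
              x$width_cm, x$height_cm, x$width_pix, x$height_pix,
              x$viewing_distance_cm))
  cat(sprintf("  %.2f pix/cm, central magnification %.3f deg/cm\n",
              1 / x$cm_per_pix,
              atan(1 / x$viewing_distance_cm) * 180 / pi))
  invisible(x)
}

#' Convert a pixel offset to degrees of visual angle
#'
#' The conversion is per axis: an offset of `n` pixels from the screen
#' center corresponds to `atan(n * cm_per_pix / viewing_distance)` degrees.
#' It is an odd, strictly increasing function of the offset and its
#' magnitude is always below 90 degrees.
#'
#' @param offset_pix Signed pixel offset(s) along one axis, measured from
#'   the screen center.
#' @param screen A `bs_screen`.
#' @return Degrees of visual angle, same sign as `offset_pix`.
#' @export
pix_to_deg <- function(offset_pix, screen = default_screen()) {
  stopifnot(inherits(screen, "bs_screen"))
  atan(offset_pix * screen$cm_per_pix / screen$viewing_distance_cm) * 180 / pi
}

#' Convert degrees of visual angle to a pixel offset
#'
#' Inverse of [pix_to_deg()]. Angles at or beyond 90 degrees lie outside
#' the visual half-field subtended by any flat screen and are an error.
#'
#' @param angle_deg Angle(s) in degrees, `|angle_deg| < 90`.
#' @param screen A `bs_screen`.
#' @return Signed pixel offset(s) from screen center.
#' @export
deg_to_pix <- function(angle_deg, screen = default_screen()) {
  stopifnot(inherits(screen, "bs_screen"))
  if (any(abs(angle_deg) >= 90))
    stop("angle of 90 degrees or more is outside the displayable field")
  tan(angle_deg * pi / 180) * screen$viewing_distance_cm / screen$cm_per_pix
}

#' Convert a screen point to visual-field coordinates
#'
#' Field coordinates are horizontal and vertical eccentricities, in degrees
#' of visual angle, of a screen location relative to the fixation object.
#' The conversion is applied per axis to the pixel offset from fixation, so
#' the fixation object itself maps to (0, 0).
#'
#' @param p Screen point, `c(x, y)` in pixels (origin at screen center,
#'   y upward), or an n x 2 matrix of points.
#' @param fixation Fixation object position in screen pixels.
#' @param screen A `bs_screen`.
#' @return Field coordinates in degrees, same shape as `p`.
#' @export
screen_to_field <- function(p, fixation = c(-300, 0), screen = default_screen()) {
  p <- to_xy(p)
  if (abs(fixation[1]) > screen$width_pix / 2 ||
      abs(fixation[2]) > screen$height_pix / 2)
    stop("fixation must be on-screen")
  out <- cbind(pix_to_deg(p[, 1] - fixation[1], screen),
               pix_to_deg(p[, 2] - fixation[2], screen))
  drop_xy(out, p)
}

#' Convert visual-field coordinates to a screen point
#'
#' Inverse of [screen_to_field()].
#'
#' @inheritParams screen_to_field
#' @param f Field point `c(h, v)` in degrees, or an n x 2 matrix.
#' @return Screen pixel coordinates, same shape as `f`.
#' @export
field_to_screen <- function(f, fixation = c(-300, 0), screen = default_screen()) {
  f <- to_xy(f)
  out <- cbind(deg_to_pix(f[, 1], screen) + fixation[1],
               deg_to_pix(f[, 2], screen) + fixation[2])
  drop_xy(out, f)
}

# coerce a length-2 vector or n x 2 matrix to matrix form
to_xy <- function(p) {
  if (is.null(dim(p))) {
    stopifnot(length(p) == 2)
    matrix(p, ncol = 2)
  } else {
    stopifnot(ncol(p) == 2)
    as.matrix(p)
  }
}

drop_xy <- function(out, p_in) {
  if (nrow(out) == 1 && nrow(p_in) == 1) as.numeric(out) else out
}
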