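#' Simulated observer with an elliptical scotoma
#'
#' The simulated observer stands in for a human participant (and
#' eye-tracker) in every procedure of the package. Its ground truth is an
#' upright ellipse in the visual field, symmetric about its horizontal and
#' vertical axes, inside which stimuli are invisible. The visibility
#' transition at the boundary is a logistic function of signed distance to
#' the ellipse, with softness `boundary_slope` (0 gives a hard step).
#' Response noise is controlled by a lapse rate (probability of answering
#' "no" to a clearly visible stimulus), a guess rate (probability of
#' answering "yes" to a clearly invisible one), isotropic Gaussian fixation
#' jitter, and Gaussian click error on moving-probe reports.
#'
#' @param center Field coordinates `c(h, v)` of the scotoma center, deg.
#' @param width,height Horizontal and vertical ellipse diameters, deg.
#' @param boundary_slope Logistic softness of the visibility transition,
#'   deg; 0 means a perfectly sharp boundary.
#' @param lapse_rate,guess_rate Response error rates, each in \[0, 0.1\]
#'   and jointly below 1.
#' @param fixation_jitter_sd SD of isotropic Gaussian gaze error, deg.
#' @param click_error_sd SD of positional error on moving-probe clicks, deg.
#' @param click_bias Mean click displacement along the movement direction,
#'   deg (real observers tend to click late; default 0).
#' @return An object of class `bs_observer`.
#' @export
scotoma_observer <- function(center = c(16.00, -2.05),
                             width = 6.28, height = 7.02,
                             boundary_slope = 0.15,
                             lapse_rate = 0.02, guess_rate = 0.02,
                             fixation_jitter_sd = 0.3,
                             click_error_sd = 0.2,
                             click_bias = 0) {
  stopifnot(length(center) == 2, is.finite(center))
  if (width <= 0 || height <= 0) stop("width and height must be positive")
  if (boundary_slope < 0) stop("boundary_slope must be >= 0")
  if (lapse_rate < 0 || guess_rate < 0 || lapse_rate + guess_rate >= 1)
    stop("need 0 <= lapse_rate + guess_rate < 1")
  if (fixation_jitter_sd < 0 || click_error_sd < 0)
    stop("noise SDs must be >= 0")
  structure(
    list(center = as.numeric(center), width = width, height = height,
         boundary_slope = boundary_slope,
         lapse_rate = lapse_rate, guess_rate = guess_rate,
         fixation_jitter_sd = fixation_jitter_sd,
         click_error_sd = click_error_sd, click_bias = click_bias),
    class = "bs_observer")
}

#' Default simulated observer
#'
#' Ground truth mirroring the average adult right-eye blind spot: centered
#' 16 degrees temporal and about 2 degrees below the horizontal meridian,
#' 6.28 x 7.02 degrees in size, with a fairly sharp boundary and small
#' response/fixation noise.
#'
#' @return A `bs_observer`.
#' @export
default_observer <- function() scotoma_observer()

#' An idealized observer: hard boundary, no noise of any kind
#' @param center,width,height Scotoma geometry (deg).
#' @return A `bs_observer`.
#' @export
ideal_observer <- function(center = c(16, -2), width = 6, height = 7)
  scotoma_observer(center, width, height, boundary_slope = 0,
                   lapse_rate = 0, guess_rate = 0,
                   fixation_jitter_sd = 0, click_error_sd = 0)

#' @export
print.bs_observer <- function(x, ...) {
  cat(sprintf("<bs_observer> scotoma %.2f x %.2f deg at (%.2f, %.2f)\n",
              x$width, x$height, x$center[1], x$center[2]))
  cat(sprintf("  boundary slope %.2f deg, lapse %.2f, guess %.2f, jitter SD %.2f deg, click SD %.2f deg\n",
              x$boundary_slope, x$lapse_rate, x$guess_rate,
              x$fixation_jitter_sd, x$click_error_sd))
  invisible(x)
}

#' Visual stimulus descriptor
#'
#' @param kind One of `"point"`, `"ellipse"`, `"rect"`.
#' @param center Field coordinates `c(h, v)`, deg.
#' @param width,height Extents in deg (0 for a point). Ellipses and
#'   rectangles are axis-aligned.
#' @return An object of class `bs_stimulus`.
#' @export
stimulus <- function(kind = c("point", "ellipse", "rect"),
                     center, width = 0, height = 0) {
  kind <- match.arg(kind)
  stopifnot(length(center) == 2, width >= 0, height >= 0)
  if (kind != "point" && (width == 0 || height == 0))
    stop("extended stimuli need positive width and height")
  structure(list(kind = kind, center = as.numeric(center),
                 width = width, height = height),
            class = "bs_stimulus")
}

#' Signed distance from a field point to the scotoma boundary
#'
#' Negative inside the ellipse, zero on it, positive outside. The value is
#' the normalized radial coordinate `r - 1` rescaled by the local
#' along-ray half-diameter of the ellipse, which makes it an exact
#' Euclidean distance on the principal axes and a smooth monotone proxy
#' elsewhere (only the sign, zero set, and monotonicity are relied upon).
#'
#' @param p Field point `c(h, v)` or n x 2 matrix, deg.
#' @param obs A `bs_observer`.
#' @return Signed distance(s) in deg.
#' @export
signed_boundary_distance <- function(p, obs) {
  stopifnot(inherits(obs, "bs_observer"))
  p <- to_xy(p)
  dx <- p[, 1] - obs$center[1]
  dy <- p[, 2] - obs$center[2]
  a <- obs$width / 2
  b <- obs$height / 2
  r <- sqrt((dx / a)^2 + (dy / b)^2)
  theta <- atan2(dy, dx)                     # ray angle; 0 at center is fine
  s <- (obs$width * obs$height) /
    (2 * sqrt((obs$height * cos(theta))^2 + (obs$width * sin(theta))^2))
  d <- (r - 1) * s
  if (length(d) == 1) as.numeric(d) else d
}

#' Probability that a point stimulus is seen
#'
#' The psychometric model underlying every simulated response: the
#' probability of "yes, I see it" is
#' `guess + (1 - guess - lapse) * sigma(d / boundary_slope)`,
#' where `d` is the signed boundary distance of the stimulus after
#' correcting for the current gaze offset and `sigma` is the standard
#' logistic. With a sharp boundary (`boundary_slope = 0`) the logistic
#' degenerates to a step: 0 inside, 1 outside, 0.5 exactly on the boundary.
#' The raw border points of the moving-probe procedure sit at this 50%
#' visibility level; the staircase then drives them to the 21% level.
#'
#' @param p Field point(s), `c(h, v)` or n x 2 matrix, deg.
#' @param obs A `bs_observer`.
#' @param gaze_offset Gaze error `c(h, v)` in deg; the stimulus is
#'   evaluated at `p - gaze_offset`.
#' @return Probability (or vector of probabilities) in \[0, 1\].
#' @export
point_visibility <- function(p, obs, gaze_offset = c(0, 0)) {
  p <- to_xy(p)
  q <- cbind(p[, 1] - gaze_offset[1], p[, 2] - gaze_offset[2])
  d <- signed_boundary_distance(q, obs)
  core <- if (obs$boundary_slope == 0) {
    ifelse(d > 0, 1, ifelse(d < 0, 0, 0.5))
  } else {
    stats::plogis(d / obs$boundary_slope)
  }
  obs$guess_rate + (1 - obs$guess_rate - obs$lapse_rate) * core
}

#' Probability that a stimulus (point or extended) is seen
#'
#' An extended stimulus is reported as seen if any part of it is visible:
#' the see-probability is the maximum of [point_visibility()] over a
#' deterministic sample of its outline (64 points) and interior (25
#' points). A point stimulus reduces to [point_visibility()]. For a hard,
#' noise-free observer this gives 0 for a stimulus strictly inside the
#' scotoma and 1 for any stimulus with a sampled point outside, which
#' matches the behavior of near-size validation ellipses that protrude
#' past the true boundary.
#'
#' @param s A `bs_stimulus`.
#' @param obs A `bs_observer`.
#' @param gaze_offset Gaze error in deg.
#' @return Probability in \[0, 1\].
#' @export
stimulus_visibility <- function(s, obs, gaze_offset = c(0, 0)) {
  stopifnot(inherits(s, "bs_stimulus"))
  if (s$kind == "point")
    return(point_visibility(s$center, obs, gaze_offset))
  pts <- stimulus_sample_points(s)
  max(point_visibility(pts, obs, gaze_offset))
}

# deterministic sample of an extended stimulus: 64 outline + 25 interior pts
stimulus_sample_points <- function(s) {
  cx <- s$center[1]; cy <- s$center[2]
  a <- s$width / 2; b <- s$height / 2
  if (s$kind == "ellipse") {
    th <- seq(0, 2 * pi, length.out = 65)[-65]
    outline <- cbind(cx + a * cos(th), cy + b * sin(th))
    rr <- rep(seq(0, 0.9, length.out = 5), each = 5)
    ta <- rep(seq(0, 2 * pi, length.out = 6)[-6], times = 5)
    interior <- cbind(cx + rr * a * cos(ta), cy + rr * b * sin(ta))
  } else {                                   # rect
    t16 <- seq(-1, 1, length.out = 17)[-17]
    outline <- rbind(
      cbind(cx + t16 * a, cy - b), cbind(cx + a, cy + t16 * b),
      cbind(cx - t16 * a, cy + b), cbind(cx - a, cy - t16 * b))
    g <- seq(-0.9, 0.9, length.out = 5)
    interior <- as.matrix(expand.grid(cx + g * a, cy + g * b))
  }
  unname(rbind(outline, interior))
}

#' Simulate one yes/no answer from the observer
#'
#' Draws one gaze offset from the observer's fixation jitter (a single
#' offset per trial; trials are brief), evaluates the stimulus visibility
#' under that gaze, and returns a Bernoulli response together with the
#' sampled gaze, for logging and fixation gating. Uses the current R
#' random number stream.
#'
#' @param s A `bs_stimulus`.
#' @param obs A `bs_observer`.
#' @return A list with `response` (`"yes"`/`"no"`), `seen` (logical),
#'   `gaze_offset` (deg), and `visibility` (the probability used).
#' @export
observer_answer <- function(s, obs) {
  gaze <- stats::rnorm(2, 0, obs$fixation_jitter_sd)
  v <- stimulus_visibility(s, obs, gaze)
  seen <- stats::runif(1) < v
  list(response = if (seen) "yes" else "no", seen = seen,
       gaze_offset = gaze, visibility = v)
}

#' Draw a batch of random simulated observers
#'
#' Utility for batch simulation studies: observer parameters are drawn
#' uniformly from plausible ranges around the canonical adult blind spot.
#'
#' @param n Number of observers.
#' @param center_h,center_v,width,height,boundary_slope,lapse_rate,guess_rate,fixation_jitter_sd,click_error_sd
#'   Length-2 `c(lo, hi)` ranges to draw each parameter from.
#' @return A data.frame with one row of parameters per observer; pass rows
#'   to [scotoma_observer()] via [as_observer()].
#' @export
sample_observers <- function(n,
                             center_h = c(15, 17), center_v = c(-4.5, 0),
                             width = c(5.4, 7.5), height = c(5.8, 8.2),
                             boundary_slope = c(0.05, 0.3),
                             lapse_rate = c(0, 0.05), guess_rate = c(0, 0.05),
                             fixation_jitter_sd = c(0.1, 0.5),
                             click_error_sd = c(0.1, 0.3)) {
  u <- function(rg) stats::runif(n, rg[1], rg[2])
  data.frame(observer_id = seq_len(n),
             center_h = u(center_h), center_v = u(center_v),
             width = u(width), height = u(height),
             boundary_slope = u(boundary_slope),
             lapse_rate = u(lapse_rate), guess_rate = u(guess_rate),
             fixation_jitter_sd = u(fixation_jitter_sd),
             click_error_sd = u(click_error_sd))
}

#' Build an observer from one row of a parameter table
#' @param row A one-row data.frame as produced by [sample_observers()].
#' @return A `bs_observer`.
#' @export
as_observer <- function(row) {
  scotoma_observer(center = c(row$center_h, row$center_v),
                   width = row$width, height = row$height,
                   boundary_slope = row$boundary_slope,
                   lapse_rate = row$lapse_rate, guess_rate = row$guess_rate,
                   fixation_jitter_sd = row$fixation_jitter_sd,
                   click_error_sd = row$click_error_sd)
}
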