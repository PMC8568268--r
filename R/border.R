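#' Test path for the moving-probe procedure
#'
#' A test path is a horizontal or vertical line segment in the visual
#' field along which the flickering probe is moved forth and back. The
#' fixed coordinate is the `anchor` (y for horizontal paths, x for
#' vertical ones); the probe moves along the free axis between
#' `extent[1]` and `extent[2]`.
#'
#' @param index Execution order of the path (1-based).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @param anchor Fixed coordinate, deg.
#' @param extent `c(start, end)` along the free axis, deg.
#' @return An object of class `bs_path`.
#' @export
test_path <- function(index, orientation = c("horizontal", "vertical"),
                      anchor, extent) {
  orientation <- match.arg(orientation)
  stopifnot(length(extent) == 2)
  if (extent[1] == extent[2]) stop("path extent must be non-degenerate")
  structure(list(index = index, orientation = orientation,
                 anchor = anchor, extent = sort(extent)),
            class = "bs_path")
}

#' @export
print.bs_path <- function(x, ...) {
  cat(sprintf("<bs_path %d> %s, %s = %.2f deg, range [%.2f, %.2f] deg\n",
              x$index, x$orientation,
              if (x$orientation == "horizontal") "y" else "x",
              x$anchor, x$extent[1], x$extent[2]))
  invisible(x)
}

# points where a path line crosses the observer's (possibly gaze-shifted)
# scotoma boundary; NULL when the line misses the ellipse
path_scotoma_crossings <- function(path, obs, gaze_offset = c(0, 0)) {
  cx <- obs$center[1] + gaze_offset[1]
  cy <- obs$center[2] + gaze_offset[2]
  a <- obs$width / 2; b <- obs$height / 2
  if (path$orientation == "horizontal") {
    u <- (path$anchor - cy) / b
    if (abs(u) >= 1) return(NULL)
    half <- a * sqrt(1 - u^2)
    c(cx - half, cx + half)
  } else {
    u <- (path$anchor - cx) / a
    if (abs(u) >= 1) return(NULL)
    half <- b * sqrt(1 - u^2)
    c(cy - half, cy + half)
  }
}

#' Simulate moving-probe passes along one test path
#'
#' Each round trip is a forward plus a backward pass. On every pass the
#' observer reports where the probe disappeared (entering the scotoma)
#' and reappeared (leaving it), so a path with `round_trips` trips yields
#' `4 * round_trips` clicks, `2 * round_trips` per border point. Click
#' positions are the true visibility-transition crossings of the path with
#' the scotoma boundary under that pass's sampled gaze offset, plus
#' Gaussian click error (and any systematic click bias, applied along the
#' movement direction).
#'
#' @param path A `bs_path`.
#' @param obs A `bs_observer`.
#' @param round_trips Number of forth-and-back trips (default 3).
#' @return A data.frame of click records: `path_index`, `round_trip`,
#'   `pass_direction`, `transition`, `x_deg`, `y_deg`.
#' @export
simulate_probe_run <- function(path, obs, round_trips = 3) {
  stopifnot(inherits(path, "bs_path"), inherits(obs, "bs_observer"),
            round_trips >= 1)
  if (is.null(path_scotoma_crossings(path, obs)))
    stop(sprintf("path %d does not cross the scotoma: mis-aimed path", path$index))
  rows <- vector("list", 2L * round_trips)
  k <- 0L
  for (trip in seq_len(round_trips)) {
    for (dir in c("forward", "backward")) {
      cr <- NULL
      for (try in 1:100) {                   # gaze occasionally pushes the
        gaze <- stats::rnorm(2, 0, obs$fixation_jitter_sd)  # boundary off the path
        cr <- path_scotoma_crossings(path, obs, gaze)
        if (!is.null(cr)) break
      }
      if (is.null(cr)) stop("gaze jitter keeps the path off the scotoma")
      sgn <- if (dir == "forward") 1 else -1
      noisy <- cr + stats::rnorm(2, 0, obs$click_error_sd) + sgn * obs$click_bias
      # moving in +direction the lower crossing is the entry (disappear)
      trans <- if (dir == "forward") c("disappear", "reappear")
               else c("reappear", "disappear")
      k <- k + 1L
      rows[[k]] <- data.frame(
        path_index = path$index, round_trip = trip, pass_direction = dir,
        transition = trans,
        x_deg = if (path$orientation == "horizontal") noisy
                else rep(path$anchor, 2),
        y_deg = if (path$orientation == "horizontal") rep(path$anchor, 2)
                else noisy)
    }
  }
  do.call(rbind, rows)
}

#' Cluster one path's clicks into its two border points
#'
#' Clicks are sorted along the path's free axis and split at the largest
#' gap into two subgroups, which are separately averaged to give the two
#' border point estimates. For well-separated borders (every real case)
#' this is the lower-half / upper-half split. An odd click count, a
#' subgroup with fewer than two clicks, or clicks that do not separate
#' into two distinct clusters (largest gap not exceeding the spread of
#' either subgroup) signal an unusable pass.
#'
#' @param clicks Click data.frame for a single path, as produced by
#'   [simulate_probe_run()].
#' @param path The `bs_path` the clicks belong to.
#' @return A 2-row data.frame (`side` = `"lo"`/`"hi"`) of border points.
#' @export
cluster_clicks <- function(clicks, path) {
  v <- if (path$orientation == "horizontal") clicks$x_deg else clicks$y_deg
  n <- length(v)
  if (n < 4) stop("need at least 4 clicks to form two border points")
  if (n %% 2 != 0) stop("odd click count: unusable pass")
  sv <- sort(v)
  gaps <- diff(sv)
  cut <- which.max(gaps)
  lo <- sv[seq_len(cut)]
  hi <- sv[(cut + 1):n]
  if (length(lo) < 2 || length(hi) < 2)
    stop("degenerate clusters: a border point needs at least 2 clicks")
  spread <- max(diff(range(lo)), diff(range(hi)))
  if (max(gaps) <= spread || mean(hi) - mean(lo) < .Machine$double.eps^0.5)
    stop("degenerate clusters: clicks do not separate into two border points")
  free <- c(mean(lo), mean(hi))
  if (path$orientation == "horizontal")
    data.frame(path_index = path$index, side = c("lo", "hi"),
               x_deg = free, y_deg = path$anchor)
  else
    data.frame(path_index = path$index, side = c("lo", "hi"),
               x_deg = path$anchor, y_deg = free)
}

#' Plan the three paths of the standard (Low mode) procedure
#'
#' Path 1 is the horizontal line through the vertical center of the prior
#' search region. Path 2 is the vertical line through the midpoint of
#' path 1's two border points. Path 3 is the horizontal line through the
#' midpoint of path 2's two border points. Paths 2 and 3 therefore pass
#' (up to estimation noise) through the scotoma center, and their border
#' points are the four cardinal border points.
#'
#' @param step Which path to plan (1, 2 or 3).
#' @param prior_region `c(x_lo, x_hi, y_lo, y_hi)` search region, deg.
#' @param previous_points Border points (2-row data.frame) of the
#'   prerequisite path; required for steps 2 and 3.
#' @return A `bs_path`.
#' @export
plan_low_mode_path <- function(step, prior_region = c(12, 20, -6, 2),
                               previous_points = NULL) {
  stopifnot(step %in% 1:3, length(prior_region) == 4)
  xr <- prior_region[1:2]; yr <- prior_region[3:4]
  if (step == 1)
    return(test_path(1, "horizontal", anchor = mean(yr), extent = xr))
  if (is.null(previous_points) || nrow(previous_points) != 2)
    stop(sprintf("path %d needs the two border points of path %d", step, step - 1))
  if (step == 2) {
    test_path(2, "vertical", anchor = mean(previous_points$x_deg),
              extent = yr + c(-2, 2))
  } else {
    test_path(3, "horizontal", anchor = mean(previous_points$y_deg),
              extent = xr + c(-2, 2))
  }
}

#' Plan the additional paths of Medium (and High) mode
#'
#' Medium mode reuses the three standard paths and adds four more, placed
#' from the Low-mode estimates: vertical lines at `cx +/- width/4` and
#' horizontal lines at `cy +/- height/4`, sampling the quadrants between
#' the cardinal points (14 border points in total over 7 paths). High
#' mode adds four further paths at `cx +/- width/8` and `cy +/- height/8`
#' (22 points over 11 paths); it is provided as configured but was only
#' lightly exercised.
#'
#' @param location `c(h, v)` Low-mode location estimate, deg.
#' @param width,height Low-mode size estimates, deg.
#' @param mode `"medium"` or `"high"`.
#' @return A list of `bs_path` objects (indices 4 onward).
#' @export
plan_extra_paths <- function(location, width, height,
                             mode = c("medium", "high")) {
  mode <- match.arg(mode)
  stopifnot(width > 0, height > 0)
  cx <- location[1]; cy <- location[2]
  fracs <- if (mode == "medium") 1 / 4 else c(1 / 4, 1 / 8)
  paths <- list(); idx <- 4L
  for (f in fracs) {
    for (s in c(-1, 1)) {
      paths[[length(paths) + 1L]] <-
        test_path(idx, "vertical", anchor = cx + s * f * width,
                  extent = cy + c(-1, 1) * height)
      idx <- idx + 1L
    }
    for (s in c(-1, 1)) {
      paths[[length(paths) + 1L]] <-
        test_path(idx, "horizontal", anchor = cy + s * f * height,
                  extent = cx + c(-1, 1) * width)
      idx <- idx + 1L
    }
  }
  paths
}

#' Combine cardinal border points into location and size estimates
#'
#' The blind spot location is the intersection of paths 2 and 3 (the x of
#' the vertical path and the y of the second horizontal path); the width
#' is the separation of path 3's two border points and the height the
#' separation of path 2's.
#'
#' @param path2,path3 The vertical and second horizontal `bs_path`.
#' @param points2,points3 Their 2-row border point data.frames.
#' @return A list with `location` (`c(h, v)`), `width`, `height`, deg.
#' @export
estimate_location_and_size <- function(path2, points2, path3, points3) {
  if (path2$orientation != "vertical" || path3$orientation != "horizontal")
    stop("paths 2 and 3 must be a perpendicular vertical/horizontal pair")
  height <- abs(diff(points2$y_deg))
  width <- abs(diff(points3$x_deg))
  if (width <= 0 || height <= 0)
    stop("coincident border points give a non-positive size")
  list(location = c(path2$anchor, path3$anchor), width = width, height = height)
}

#' Run a full border points detection section
#'
#' Executes the three-step moving-probe procedure (and, for Medium/High
#' modes, the additional quadrant paths) against a simulated observer:
#' plans each path, simulates its probe passes, clusters the clicks into
#' border points, and combines the cardinal points into location and size
#' estimates. Low mode yields 6 border points, Medium 14, High 22.
#'
#' @param obs A `bs_observer`.
#' @param mode `"low"`, `"medium"` or `"high"`.
#' @param prior_region `c(x_lo, x_hi, y_lo, y_hi)` prior search region, deg.
#' @param round_trips Round trips per path (default 3).
#' @return A list of class `bs_border_result`: `paths`, `clicks`,
#'   `border_points` (with `cardinal` flags), `location`, `width`,
#'   `height`, `mode`.
#' @export
run_border_detection <- function(obs, mode = c("low", "medium", "high"),
                                 prior_region = c(12, 20, -6, 2),
                                 round_trips = 3) {
  mode <- match.arg(mode)
  paths <- list(); clicks <- list(); pts <- list()
  run_one <- function(path) {
    cl <- simulate_probe_run(path, obs, round_trips)
    bp <- cluster_clicks(cl, path)
    clicks[[length(clicks) + 1L]] <<- cl
    pts[[length(pts) + 1L]] <<- bp
    paths[[path$index]] <<- path
    bp
  }
  bp1 <- run_one(plan_low_mode_path(1, prior_region))
  bp2 <- run_one(plan_low_mode_path(2, prior_region, bp1))
  bp3 <- run_one(plan_low_mode_path(3, prior_region, bp2))
  est <- estimate_location_and_size(paths[[2]], bp2, paths[[3]], bp3)
  if (mode != "low") {
    for (path in plan_extra_paths(est$location, est$width, est$height, mode))
      run_one(path)
  }
  border_points <- do.call(rbind, pts)
  border_points$cardinal <- border_points$path_index %in% c(2, 3)
  border_points$point_id <- seq_len(nrow(border_points))
  structure(list(mode = mode, paths = paths,
                 clicks = do.call(rbind, clicks),
                 border_points = border_points,
                 location = est$location,
                 width = est$width, height = est$height),
            class = "bs_border_result")
}

#' @export
print.bs_border_result <- function(x, ...) {
  cat(sprintf("<bs_border_result> %s mode: %d border points over %d paths\n",
              x$mode, nrow(x$border_points), length(x$paths)))
  cat(sprintf("  location (%.2f, %.2f) deg, width %.2f deg, height %.2f deg\n",
              x$location[1], x$location[2], x$width, x$height))
  invisible(x)
}
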