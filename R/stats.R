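#' Standard distance of a 2D point cloud
#'
#' The root-mean-square Euclidean distance of a set of points from their
#' centroid: `sqrt(mean((x - xbar)^2 + (y - ybar)^2))`. It quantifies how
#' repeated 2D estimates spread, so it is a precision measure (lower is
#' more precise). It is invariant under translation and rotation.
#'
#' @param points An n x 2 matrix or data.frame of `(x, y)` coordinates.
#' @return Standard distance, same units as the coordinates.
#' @export
standard_distance <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 1) stop("need at least one point")
  stopifnot(ncol(points) == 2)
  dx <- points[, 1] - mean(points[, 1])
  dy <- points[, 2] - mean(points[, 2])
  sqrt(mean(dx^2 + dy^2))
}

#' Root-mean-square aggregation
#'
#' Aggregates standard distances (or SDs) across observers as the square
#' root of the mean of squares. Always at least the arithmetic mean, with
#' equality only for constant input.
#'
#' @param x Non-empty numeric vector.
#' @return `sqrt(mean(x^2))`.
#' @export
rms_aggregate <- function(x) {
  if (length(x) < 1) stop("empty input")
  sqrt(mean(x^2))
}

#' Precision quotient of a location estimate
#'
#' Standard distance divided by the minor axis length (the smaller of
#' blind spot width and height): a dimensionless measure of how large the
#' location scatter is relative to the structure being located.
#'
#' @param stdist Standard distance, deg.
#' @param width,height Blind spot size, deg (positive).
#' @return `stdist / min(width, height)`.
#' @export
precision_quotient <- function(stdist, width, height) {
  if (any(width <= 0) || any(height <= 0)) stop("sizes must be positive")
  stdist / pmin(width, height)
}

#' Paired t test statistic
#'
#' Classical two-tailed paired t on the element-wise differences, with
#' `df = n - 1`. Thin wrapper over [stats::t.test()] returning the pieces
#' used in reporting.
#'
#' @param a,b Equal-length numeric vectors, `n >= 2`.
#' @return A list: `t`, `df`, `p`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  if (stats::sd(a - b) == 0) stop("zero-variance differences")
  tt <- stats::t.test(a, b, paired = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Pooled-variance independent-samples t test statistic
#'
#' Classical two-sample t with pooled variance (not Welch), so
#' `df = n1 + n2 - 2`.
#'
#' @param a,b Numeric vectors, each `n >= 2`.
#' @return A list: `t`, `df`, `p`.
#' @export
independent_t <- function(a, b) {
  stopifnot(length(a) >= 2, length(b) >= 2)
  if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    stop("both samples constant and equal")
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value)
}

#' Safe zone within the blind spot
#'
#' A central region in which stimuli can be placed with confidence that
#' no observer will see them: the given coefficient (default one half)
#' times the smallest per-observer mean width and height. Reported to two
#' decimals (half away from zero), matching reporting convention;
#' internal computation is exact.
#'
#' @param widths,heights Per-observer mean blind spot sizes, deg.
#' @param coefficient Scaling coefficient (default 0.5).
#' @return `c(width, height)` of the safe zone, deg, rounded to 2
#'   decimals.
#' @export
safe_zone <- function(widths, heights, coefficient = 0.5) {
  if (length(widths) == 0 || length(heights) == 0) stop("empty input")
  if (any(widths <= 0) || any(heights <= 0)) stop("sizes must be positive")
  c(width = round_half_up(coefficient * min(widths), 2),
    height = round_half_up(coefficient * min(heights), 2))
}

# round half away from zero (base round() is banker's rounding)
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Summarize one observer's repeated mapping blocks
#'
#' Given per-block estimates for one observer, computes the per-observer
#' summary row: mean location with per-axis SD and range, the standard
#' distance of the block locations, mean width and height with SD and
#' range, the range of block-to-mean location distances, and the summed
#' standard distance of the four cardinal border points for the raw and
#' the staircase-adjusted stages. Sample (n-1) SDs are used throughout.
#'
#' @param blocks A data.frame with one row per block and columns `loc_h`,
#'   `loc_v`, `width`, `height`, plus, for the border-point precision
#'   sums, `<stage>_<cardinal>_x` / `_y` columns for
#'   `stage` in `raw`, `adj` and `cardinal` in `left`, `right`, `top`,
#'   `bottom` (omitted columns simply yield `NA` sums).
#' @param observer_id Identifier carried into the output.
#' @return A one-row data.frame matching the study-table layout.
#' @export
summarize_observer <- function(blocks, observer_id = NA) {
  if (nrow(blocks) < 2) stop("need at least 2 blocks (SDs undefined)")
  loc <- cbind(blocks$loc_h, blocks$loc_v)
  ctr <- colMeans(loc)
  dists <- sqrt((loc[, 1] - ctr[1])^2 + (loc[, 2] - ctr[2])^2)
  sum_stdist <- function(stage) {
    pts <- c("left", "right", "top", "bottom")
    cols <- as.vector(outer(pts, c("x", "y"),
                            function(p, a) paste(stage, p, a, sep = "_")))
    if (!all(cols %in% names(blocks))) return(NA_real_)
    sum(vapply(pts, function(p) {
      standard_distance(blocks[, paste(stage, p, c("x", "y"), sep = "_")])
    }, 0))
  }
  data.frame(
    observer = observer_id, n_blocks = nrow(blocks),
    loc_h = ctr[1], loc_v = ctr[2],
    loc_h_min = min(loc[, 1]), loc_h_max = max(loc[, 1]),
    loc_h_sd = stats::sd(loc[, 1]),
    loc_v_min = min(loc[, 2]), loc_v_max = max(loc[, 2]),
    loc_v_sd = stats::sd(loc[, 2]),
    loc_stdist = standard_distance(loc),
    loc_dist_min = min(dists), loc_dist_max = max(dists),
    width = mean(blocks$width),
    width_min = min(blocks$width), width_max = max(blocks$width),
    width_sd = stats::sd(blocks$width),
    height = mean(blocks$height),
    height_min = min(blocks$height), height_max = max(blocks$height),
    height_sd = stats::sd(blocks$height),
    raw_sum_stdist = sum_stdist("raw"),
    adj_sum_stdist = sum_stdist("adj"),
    row.names = NULL)
}

#' Summarize a study across observers
#'
#' Aggregates per-observer summary rows into the study-level table:
#' arithmetic means of per-observer means (location, width, height, and
#' the arithmetic mean of location standard distances), across-observer
#' SDs and CVs, ranges, RMS aggregation for the SD and standard-distance
#' columns (the average of SDs is the square root of the mean variance,
#' and likewise for standard distances), per-observer precision
#' quotients, the two precision comparisons (paired t on raw vs adjusted
#' summed border-point standard distances; pooled independent t on width
#' vs height SDs), and the safe zone.
#'
#' @param observers A data.frame with one row per observer: `loc_h`,
#'   `loc_v`, `loc_h_sd`, `loc_v_sd`, `loc_stdist`, `width`, `width_sd`,
#'   `height`, `height_sd`, `raw_sum_stdist`, `adj_sum_stdist` (the
#'   layout produced by [summarize_observer()], or the packaged reference
#'   table from [reference_observers()]).
#' @param safe_zone_coefficient Coefficient for [safe_zone()].
#' @return A list of class `bs_study_summary`; see the fields in the
#'   examples.
#' @examples
#' summ <- summarize_study(reference_observers())
#' summ$width_mean; summ$safe_zone
#' @export
summarize_study <- function(observers, safe_zone_coefficient = 0.5) {
  stopifnot(nrow(observers) >= 2)
  o <- observers
  quot <- precision_quotient(o$loc_stdist, o$width, o$height)
  out <- list(
    n_observers = nrow(o),
    loc_h_mean = mean(o$loc_h), loc_h_sd = stats::sd(o$loc_h),
    loc_h_range = range(o$loc_h),
    loc_v_mean = mean(o$loc_v), loc_v_sd = stats::sd(o$loc_v),
    loc_v_range = range(o$loc_v),
    loc_h_sd_rms = rms_aggregate(o$loc_h_sd),
    loc_v_sd_rms = rms_aggregate(o$loc_v_sd),
    loc_stdist_mean = mean(o$loc_stdist),
    loc_stdist_sd = stats::sd(o$loc_stdist),
    loc_stdist_range = range(o$loc_stdist),
    loc_stdist_rms = rms_aggregate(o$loc_stdist),
    width_mean = mean(o$width), width_sd = stats::sd(o$width),
    width_cv = stats::sd(o$width) / mean(o$width),
    width_range = range(o$width),
    width_sd_mean = mean(o$width_sd), width_sd_sd = stats::sd(o$width_sd),
    width_sd_cv = stats::sd(o$width_sd) / mean(o$width_sd),
    width_sd_rms = rms_aggregate(o$width_sd),
    height_mean = mean(o$height), height_sd = stats::sd(o$height),
    height_cv = stats::sd(o$height) / mean(o$height),
    height_range = range(o$height),
    height_sd_mean = mean(o$height_sd), height_sd_sd = stats::sd(o$height_sd),
    height_sd_cv = stats::sd(o$height_sd) / mean(o$height_sd),
    height_sd_rms = rms_aggregate(o$height_sd),
    quotient = quot, quotient_mean = mean(quot),
    quotient_sd = stats::sd(quot), quotient_range = range(quot),
    safe_zone = safe_zone(o$width, o$height, safe_zone_coefficient))
  if (all(c("raw_sum_stdist", "adj_sum_stdist") %in% names(o)) &&
      !anyNA(o$raw_sum_stdist) && !anyNA(o$adj_sum_stdist)) {
    out$raw_sum_stdist_mean <- mean(o$raw_sum_stdist)
    out$adj_sum_stdist_mean <- mean(o$adj_sum_stdist)
    out$raw_vs_adj <- paired_t(o$raw_sum_stdist, o$adj_sum_stdist)
  }
  out$width_sd_vs_height_sd <- independent_t(o$width_sd, o$height_sd)
  class(out) <- "bs_study_summary"
  out
}

#' @export
print.bs_study_summary <- function(x, ...) {
  cat(sprintf("<bs_study_summary> %d observers\n", x$n_observers))
  cat(sprintf("  location (%.2f, %.2f) deg; Stdist mean %.2f, RMS %.2f deg\n",
              x$loc_h_mean, x$loc_v_mean, x$loc_stdist_mean, x$loc_stdist_rms))
  cat(sprintf("  width %.2f deg (SD %.2f, CV %.2f), height %.2f deg (SD %.2f, CV %.2f)\n",
              x$width_mean, x$width_sd, x$width_cv,
              x$height_mean, x$height_sd, x$height_cv))
  cat(sprintf("  precision quotient mean %.2f, range [%.2f, %.2f]\n",
              x$quotient_mean, x$quotient_range[1], x$quotient_range[2]))
  cat(sprintf("  safe zone %.2f x %.2f deg\n",
              x$safe_zone["width"], x$safe_zone["height"]))
  if (!is.null(x$raw_vs_adj))
    cat(sprintf("  raw vs adjusted summed Stdist: paired t = %.2f, df = %.0f, p = %.3f\n",
                x$raw_vs_adj$t, x$raw_vs_adj$df, x$raw_vs_adj$p))
  cat(sprintf("  width SD vs height SD: pooled t = %.2f, df = %.0f, p = %.3f\n",
              x$width_sd_vs_height_sd$t, x$width_sd_vs_height_sd$df,
              x$width_sd_vs_height_sd$p))
  invisible(x)
}

#' Packaged 12-observer reference summary table
#'
#' Per-observer blind spot summary statistics for a published group of 12
#' adults (six mapping blocks each, Low mode with scaling validation),
#' shipped as a plain-text fixture for regression tests and as ready-made
#' input for [summarize_study()].
#'
#' @return A data.frame with one row per observer.
#' @export
reference_observers <- function() {
  path <- system.file("extdata", "reference_observers.csv",
                      package = "blindspotr", mustWork = TRUE)
  utils::read.csv(path)
}
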