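#' Plot a staircase trace
#'
#' Increment (pix) against trial index, each point labeled with the
#' response (Y/N), reversals circled, and a reference line at zero
#' increment (the raw border point position).
#'
#' @param trace Trace data.frame from [run_staircase()] or
#'   [staircase_trace()]; invalid-fixation attempts, if present, are
#'   dropped.
#' @return A ggplot object.
#' @export
plot_staircase_trace <- function(trace) {
  if (is.null(trace) || nrow(trace) == 0) stop("empty trace")
  if ("fixation_ok" %in% names(trace)) trace <- trace[trace$fixation_ok, ]
  trace$label <- ifelse(trace$response == "yes", "Y", "N")
  rev_pts <- trace[!is.na(trace$reversal) & trace$reversal, ]
  p <- ggplot2::ggplot(trace,
                       ggplot2::aes(x = .data$trial_index,
                                    y = .data$increment_pix)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted", color = "grey40") +
    ggplot2::geom_line(color = "grey55") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -1, size = 3)
  if (nrow(rev_pts) > 0)
    p <- p + ggplot2::geom_point(data = rev_pts, shape = 1, size = 5,
                                 color = "firebrick")
  p + ggplot2::labs(x = "Successful trial",
                    y = "Increment (pix, positive toward scotoma center)") +
    ggplot2::theme_minimal()
}

#' Plot raw and adjusted border points
#'
#' The raw border points are joined with a dashed closed polyline and the
#' staircase-adjusted points with a solid one (a diamond in low mode),
#' with the estimated location marked by a cross.
#'
#' @param border_points Data.frame with `stage`, `x_deg`, `y_deg` (as in
#'   a `bs_block_result`).
#' @param location `c(h, v)` estimated location, deg.
#' @return A ggplot object.
#' @export
plot_border_overlay <- function(border_points, location) {
  close_ring <- function(df) {
    if (nrow(df) < 3) stop("need at least 3 points per stage")
    ctr <- c(mean(df$x_deg), mean(df$y_deg))
    df <- df[order(atan2(df$y_deg - ctr[2], df$x_deg - ctr[1])), ]
    rbind(df, df[1, ])
  }
  stages <- split(border_points, border_points$stage)
  if (length(stages) == 0) stop("no border points")
  rings <- lapply(names(stages), function(s) {
    r <- close_ring(stages[[s]])
    r$stage <- s
    r
  })
  rings <- do.call(rbind, rings)
  ggplot2::ggplot(rings, ggplot2::aes(x = .data$x_deg, y = .data$y_deg,
                                      linetype = .data$stage,
                                      group = .data$stage)) +
    ggplot2::geom_path() +
    ggplot2::geom_point() +
    ggplot2::annotate("point", x = location[1], y = location[2],
                      shape = 3, size = 3, color = "firebrick") +
    ggplot2::scale_linetype_manual(
      values = c(raw = "dashed", adjusted = "solid")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Horizontal eccentricity (deg)",
                  y = "Vertical eccentricity (deg)") +
    ggplot2::theme_minimal()
}

#' Plot a visibility heat map
#'
#' Cell-colored visibility matrix in field coordinates, optionally with
#' border points overlaid.
#'
#' @param heatmap A `bs_heatmap` (or a bare matrix with `grid` supplied).
#' @param grid The `bs_heatmap_grid` when `heatmap` is a bare matrix.
#' @param border_points Optional data.frame with `x_deg`, `y_deg` (and
#'   optionally `stage`).
#' @return A ggplot object.
#' @export
plot_visibility_heatmap <- function(heatmap, grid = NULL,
                                    border_points = NULL) {
  if (inherits(heatmap, "bs_heatmap")) {
    grid <- heatmap$grid
    m <- heatmap$matrix
  } else m <- heatmap
  if (is.null(grid)) stop("grid required for a bare matrix")
  if (nrow(m) != grid$rows || ncol(m) != grid$cols)
    stop("matrix shape does not match grid")
  cells <- grid$cells
  cells$visibility <- m[cbind(cells$row, cells$col)]
  p <- ggplot2::ggplot(cells, ggplot2::aes(x = .data$cx, y = .data$cy,
                                           fill = .data$visibility)) +
    ggplot2::geom_tile(width = grid$cell_width, height = grid$cell_height) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "Horizontal eccentricity (deg)",
                  y = "Vertical eccentricity (deg)",
                  fill = "Visibility") +
    ggplot2::theme_minimal()
  if (!is.null(border_points))
    p <- p + ggplot2::geom_point(
      data = border_points,
      ggplot2::aes(x = .data$x_deg, y = .data$y_deg),
      inherit.aes = FALSE, color = "red", size = 2)
  p
}

#' Plot a scaling validation curve with its sigmoid fit
#'
#' Per-size visibility proportions with binomial standard error bars
#' (zero half-width at proportions 0 and 1) and, if supplied, the fitted
#' logistic visibility curve, which crosses 50% at `x0`.
#'
#' @param scaling A `bs_scaling` data.frame.
#' @param fit Optional `bs_sigmoid_fit`.
#' @return A ggplot object.
#' @export
plot_scaling_curve <- function(scaling, fit = NULL) {
  df <- as.data.frame(scaling)
  df$se <- sqrt(df$proportion * (1 - df$proportion) / df$n_trials)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$coefficient,
                                        y = 100 * .data$proportion)) +
    ggplot2::geom_errorbar(ggplot2::aes(
      ymin = 100 * (.data$proportion - .data$se),
      ymax = 100 * (.data$proportion + .data$se)), width = 0.01) +
    ggplot2::geom_point(size = 2)
  if (!is.null(fit)) {
    xs <- seq(min(df$coefficient), max(df$coefficient), length.out = 200)
    curve_df <- data.frame(coefficient = xs, fitted = fit$predict(xs))
    p <- p + ggplot2::geom_line(data = curve_df,
                                ggplot2::aes(x = .data$coefficient,
                                             y = .data$fitted),
                                inherit.aes = FALSE, color = "steelblue")
  }
  p + ggplot2::labs(x = "Scaling coefficient (relative to estimated size)",
                    y = "Visibility (%)") +
    ggplot2::theme_minimal()
}
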