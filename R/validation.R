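#' Build the heat-map grid over the estimated blind spot
#'
#' The perimetric validation tests a rectangular region that fully covers
#' the estimated blind spot: 1.1 times the estimated width and 1.2 times
#' the estimated height, centered on the estimated location, evenly
#' gridded into `rows x cols` congruent rectangular cells.
#'
#' @param center `c(h, v)` estimated blind spot location, deg.
#' @param est_width,est_height Estimated blind spot size, deg.
#' @param rows,cols Grid resolution (default 10 x 10).
#' @param screen Optional `bs_screen`; when supplied together with
#'   `fixation`, an error is raised if the rectangle extends beyond the
#'   displayable field.
#' @param fixation Fixation position in screen pixels (with `screen`).
#' @return An object of class `bs_heatmap_grid` with the rectangle
#'   geometry and a `cells` data.frame (`row`, `col`, centers, extents).
#' @export
heatmap_grid <- function(center, est_width, est_height,
                         rows = 10, cols = 10,
                         screen = NULL, fixation = c(-300, 0)) {
  stopifnot(est_width > 0, est_height > 0, rows >= 1, cols >= 1)
  rect_w <- 1.1 * est_width
  rect_h <- 1.2 * est_height
  if (!is.null(screen)) {
    corners <- rbind(center + c(-rect_w, -rect_h) / 2,
                     center + c(rect_w, rect_h) / 2)
    pix <- field_to_screen(corners, fixation, screen)
    if (any(abs(pix[, 1]) > screen$width_pix / 2) ||
        any(abs(pix[, 2]) > screen$height_pix / 2))
      stop("heat-map rectangle extends beyond the displayable field")
  }
  cell_w <- rect_w / cols
  cell_h <- rect_h / rows
  x0 <- center[1] - rect_w / 2
  y0 <- center[2] - rect_h / 2
  cells <- expand.grid(col = seq_len(cols), row = seq_len(rows))
  cells <- cells[, c("row", "col")]
  cells$cx <- x0 + (cells$col - 0.5) * cell_w
  cells$cy <- y0 + (cells$row - 0.5) * cell_h
  structure(list(center = as.numeric(center),
                 rect_width = rect_w, rect_height = rect_h,
                 rows = rows, cols = cols,
                 cell_width = cell_w, cell_height = cell_h,
                 cells = cells),
            class = "bs_heatmap_grid")
}

#' @export
print.bs_heatmap_grid <- function(x, ...) {
  cat(sprintf("<bs_heatmap_grid> %.2f x %.2f deg at (%.2f, %.2f), %d x %d cells of %.2f x %.2f deg\n",
              x$rect_width, x$rect_height, x$center[1], x$center[2],
              x$rows, x$cols, x$cell_width, x$cell_height))
  invisible(x)
}

#' Run the perimetric heat-map validation
#'
#' Presents a rectangular target fully filling one grid cell per trial,
#' `trials_per_cell` times per cell in a randomly shuffled order, and
#' records the simulated observer's yes/no answers. Trials with gaze
#' outside the fixation tolerance are re-run. The per-cell proportion of
#' "yes" answers is the visual sensitivity ("visibility") of that cell.
#'
#' @param grid A `bs_heatmap_grid`.
#' @param obs A `bs_observer`.
#' @param trials_per_cell Trials per cell (default 10).
#' @param fixation_tolerance Gaze tolerance, deg.
#' @param max_attempts Re-run guard per trial.
#' @return A list of class `bs_heatmap`: `matrix` (rows x cols visibility
#'   proportions, row 1 = bottom row of the field), `grid`,
#'   `trials_per_cell`, and the trial log.
#' @export
run_heatmap <- function(grid, obs, trials_per_cell = 10,
                        fixation_tolerance = 1.5, max_attempts = 1000) {
  stopifnot(inherits(grid, "bs_heatmap_grid"), trials_per_cell >= 1)
  n_cells <- nrow(grid$cells)
  order_idx <- sample(rep(seq_len(n_cells), times = trials_per_cell))
  yes <- matrix(0L, grid$rows, grid$cols)
  log <- vector("list", length(order_idx))
  for (k in seq_along(order_idx)) {
    cell <- grid$cells[order_idx[k], ]
    stim <- stimulus("rect", c(cell$cx, cell$cy),
                     grid$cell_width, grid$cell_height)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_attempts) stop("fixation never within tolerance")
      ans <- observer_answer(stim, obs)
      if (fixation_gate(ans$gaze_offset, fixation_tolerance)) break
    }
    if (ans$seen) yes[cell$row, cell$col] <- yes[cell$row, cell$col] + 1L
    log[[k]] <- data.frame(trial = k, row = cell$row, col = cell$col,
                           response = ans$response)
  }
  structure(list(matrix = yes / trials_per_cell, grid = grid,
                 trials_per_cell = trials_per_cell,
                 trials = do.call(rbind, log)),
            class = "bs_heatmap")
}

#' Extract the blind spot region and size from a heat map
#'
#' Cells with visibility below the threshold constitute the estimated
#' blind spot. The width is the separation between the outer edges of the
#' leftmost and rightmost member columns, and the height the separation
#' between the outer edges of the top and bottom member rows (e.g. the
#' upper boundary of the uppermost blind cell to the lower boundary of
#' the lowermost one). Connectivity of the region is not enforced. An
#' empty region yields zero sizes.
#'
#' @param matrix A rows x cols visibility matrix.
#' @param grid The matching `bs_heatmap_grid`.
#' @param threshold Visibility threshold (default 0.5).
#' @return A list: `cells` (data.frame of member cells), `width`,
#'   `height` (deg).
#' @export
blind_spot_from_heatmap <- function(matrix, grid, threshold = 0.5) {
  if (inherits(matrix, "bs_heatmap")) matrix <- matrix$matrix
  stopifnot(nrow(matrix) == grid$rows, ncol(matrix) == grid$cols)
  idx <- which(matrix < threshold, arr.ind = TRUE)
  if (nrow(idx) == 0)
    return(list(cells = grid$cells[0, ], width = 0, height = 0))
  member <- merge(grid$cells, data.frame(row = idx[, 1], col = idx[, 2]))
  width <- (max(member$cx) + grid$cell_width / 2) -
    (min(member$cx) - grid$cell_width / 2)
  height <- (max(member$cy) + grid$cell_height / 2) -
    (min(member$cy) - grid$cell_height / 2)
  list(cells = member, width = width, height = height)
}

#' Scaling coefficients for the scaling validation
#'
#' Uniformly spaced scaling coefficients, by default 10 values spanning
#' \[0.6, 1.2\] inclusive.
#'
#' @param n Number of coefficients (>= 2).
#' @param lo,hi Range endpoints, `lo < hi`.
#' @return Ascending numeric vector of length `n`.
#' @export
scaling_coefficients <- function(n = 10, lo = 0.6, hi = 1.2) {
  stopifnot(n >= 2)
  if (lo >= hi) stop("lo must be strictly below hi")
  seq(lo, hi, length.out = n)
}

#' Run the scaling validation
#'
#' Presents center-anchored ellipses with the same aspect ratio as the
#' estimated blind spot at a range of scaling coefficients relative to
#' the estimated size, `trials_per_size` trials per size, and records the
#' proportion of "yes" answers per size. Trials with gaze outside the
#' fixation tolerance are re-run.
#'
#' @param center `c(h, v)` estimated blind spot location, deg.
#' @param est_width,est_height Estimated blind spot size, deg.
#' @param obs A `bs_observer`.
#' @param trials_per_size Trials per coefficient (default 10).
#' @param coefficients Scaling coefficients (default
#'   `scaling_coefficients()`).
#' @param fixation_tolerance Gaze tolerance, deg.
#' @param max_attempts Re-run guard per trial.
#' @return A data.frame of class `bs_scaling`: `coefficient`, `n_trials`,
#'   `n_yes`, `proportion`.
#' @export
run_scaling <- function(center, est_width, est_height, obs,
                        trials_per_size = 10,
                        coefficients = scaling_coefficients(),
                        fixation_tolerance = 1.5, max_attempts = 1000) {
  stopifnot(est_width > 0, est_height > 0, trials_per_size >= 1)
  rows <- lapply(coefficients, function(cc) {
    stim <- stimulus("ellipse", center, cc * est_width, cc * est_height)
    n_yes <- 0L
    for (t in seq_len(trials_per_size)) {
      tries <- 0L
      repeat {
        tries <- tries + 1L
        if (tries > max_attempts) stop("fixation never within tolerance")
        ans <- observer_answer(stim, obs)
        if (fixation_gate(ans$gaze_offset, fixation_tolerance)) break
      }
      if (ans$seen) n_yes <- n_yes + 1L
    }
    data.frame(coefficient = cc, n_trials = trials_per_size,
               n_yes = n_yes, proportion = n_yes / trials_per_size)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("bs_scaling", class(out))
  out
}

#' Fit the sigmoid visibility model to scaling data
#'
#' Fits the two-parameter logistic
#' `f(x) = 100% / (1 + exp(-t (x - x0)))`
#' to percentage-visibility data by unweighted least squares, with the
#' slope constrained positive (visibility grows with probe size: from 0%
#' for probes deep inside the blind spot to 100% for clearly protruding
#' ones, with `f(x0) = 50%`). The fit is multi-started over `x0` at each
#' observed size (plus the data midpoint) and several slope magnitudes to
#' avoid local minima.
#'
#' @param sizes Scaling coefficients (>= 3 distinct values).
#' @param proportions Visibility as proportions in \[0, 1\] (or a
#'   `bs_scaling` data.frame in `sizes`).
#' @return A list of class `bs_sigmoid_fit`: `t` (slope), `x0`
#'   (50%-visibility size), `sse` (on the percentage scale), and
#'   `predict(x)` returning fitted percentages.
#' @export
fit_sigmoid <- function(sizes, proportions = NULL) {
  if (inherits(sizes, "bs_scaling") ||
      (is.data.frame(sizes) && is.null(proportions))) {
    proportions <- sizes$proportion
    sizes <- sizes$coefficient
  }
  stopifnot(length(sizes) == length(proportions))
  if (length(unique(sizes)) < 3) stop("need at least 3 distinct sizes")
  if (any(proportions < 0 | proportions > 1))
    stop("proportions must lie in [0, 1]")
  y <- 100 * proportions
  if (all(y == 0) || all(y == 100))
    stop("degenerate data: visibility never crosses between 0% and 100%")
  f <- function(par) 100 / (1 + exp(-par[1] * (sizes - par[2])))
  sse <- function(par) sum((f(par) - y)^2)
  starts <- expand.grid(t = c(2, 5, 10, 20, 50, 100),
                        x0 = unique(c(sizes, mean(range(sizes)))))
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- stats::optim(as.numeric(starts[i, ]), sse, method = "L-BFGS-B",
                        lower = c(1e-6, -Inf), upper = c(Inf, Inf),
                        control = list(factr = 1e3, maxit = 500))
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  t_hat <- best$par[1]; x0_hat <- best$par[2]
  structure(list(t = t_hat, x0 = x0_hat, sse = best$value,
                 predict = function(x) 100 / (1 + exp(-t_hat * (x - x0_hat)))),
            class = "bs_sigmoid_fit")
}

#' @export
print.bs_sigmoid_fit <- function(x, ...) {
  cat(sprintf("<bs_sigmoid_fit> t = %.3f per unit size, x0 = %.3f (50%% visibility), SSE = %.3g\n",
              x$t, x$x0, x$sse))
  invisible(x)
}

#' Largest fully invisible probe size
#'
#' The largest tested scaling coefficient at and below which every
#' observed visibility proportion is exactly zero; `NA` when even the
#' smallest size was sometimes seen.
#'
#' @param sizes Ascending scaling coefficients (or a `bs_scaling`).
#' @param proportions Visibility proportions.
#' @return A scaling coefficient, or `NA_real_`.
#' @export
zero_visible_size <- function(sizes, proportions = NULL) {
  if (inherits(sizes, "bs_scaling") ||
      (is.data.frame(sizes) && is.null(proportions))) {
    proportions <- sizes$proportion
    sizes <- sizes$coefficient
  }
  if (is.unsorted(sizes)) stop("sizes must be ascending")
  nz <- which(proportions > 0)
  if (length(nz) == 0) return(sizes[length(sizes)])
  if (nz[1] == 1) return(NA_real_)
  sizes[nz[1] - 1]
}
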