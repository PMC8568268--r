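# Independent oracles used across the test files. These deliberately take
# different computational routes than the package code.

# Ellipse/line crossings via the roots of the quadratic in the free
# coordinate (polyroot), not the package's direct sqrt form.
oracle_crossings <- function(center, width, height, orientation, anchor) {
  a <- width / 2; b <- height / 2
  if (orientation == "horizontal") {
    K <- 1 - ((anchor - center[2]) / b)^2
    if (K <= 0) return(NULL)
    r <- polyroot(c(center[1]^2 / a^2 - K, -2 * center[1] / a^2, 1 / a^2))
  } else {
    K <- 1 - ((anchor - center[1]) / a)^2
    if (K <= 0) return(NULL)
    r <- polyroot(c(center[2]^2 / b^2 - K, -2 * center[2] / b^2, 1 / b^2))
  }
  sort(Re(r))
}

# Standard distance via the pairwise-distance identity
# sum_i |p_i - pbar|^2 = (1/2n) sum_ij |p_i - p_j|^2.
oracle_stdist <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  d2 <- as.matrix(stats::dist(points))^2
  sqrt(sum(d2) / (2 * n^2))
}

# Brute-force least-squares logistic fit on a dense (t, x0) grid.
oracle_sigmoid_grid <- function(sizes, proportions,
                                t_grid = seq(0.5, 100, by = 0.5),
                                x0_grid = seq(0.4, 1.4, by = 0.0025)) {
  y <- 100 * proportions
  best <- c(Inf, NA, NA)
  for (t in t_grid) {
    for (x0 in x0_grid) {
      sse <- sum((100 / (1 + exp(-t * (sizes - x0))) - y)^2)
      if (sse < best[1]) best <- c(sse, t, x0)
    }
  }
  list(sse = best[1], t = best[2], x0 = best[3])
}

# Cell membership for an ideal observer: a rectangular cell is blind iff
# all four corners are strictly inside the ellipse (convexity).
oracle_blind_cells <- function(grid, center, width, height) {
  inside <- function(x, y)
    ((x - center[1]) / (width / 2))^2 + ((y - center[2]) / (height / 2))^2 < 1
  cells <- grid$cells
  hw <- grid$cell_width / 2; hh <- grid$cell_height / 2
  blind <- inside(cells$cx - hw, cells$cy - hh) &
    inside(cells$cx + hw, cells$cy - hh) &
    inside(cells$cx - hw, cells$cy + hh) &
    inside(cells$cx + hw, cells$cy + hh)
  cells[blind, ]
}

# Default-geometry ideal observer used in noise-free checks.
ideal_default <- function() ideal_observer(c(16, -2.05), 6.28, 7.02)
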