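test_that("the heat-map grid covers 1.1 x width by 1.2 x height in congruent cells", {
  g <- heatmap_grid(c(0, 0), 10, 10, rows = 10, cols = 10)
  expect_equal(g$rect_width, 11)
  expect_equal(g$rect_height, 12)
  expect_equal(c(g$cell_width, g$cell_height), c(1.1, 1.2))
  # estimates implying a 7.26 x 9.16 deg rectangle, 10 x 10 grid
  g2 <- heatmap_grid(c(16, -2), 7.26 / 1.1, 9.16 / 1.2)
  expect_equal(round(c(g2$cell_width, g2$cell_height), 2), c(0.73, 0.92))
  expect_equal(round(c(g2$rect_width, g2$rect_height), 2), c(7.26, 9.16))
  # exact tiling: cells are disjoint and their areas sum to the rectangle
  expect_equal(nrow(g$cells), 100)
  expect_equal(nrow(unique(g$cells[, c("cx", "cy")])), 100)
  expect_equal(nrow(g$cells) * g$cell_width * g$cell_height,
               g$rect_width * g$rect_height)
  xs <- sort(unique(g$cells$cx))
  expect_equal(diff(xs), rep(g$cell_width, 9))
  expect_equal(min(xs) - g$cell_width / 2, -g$rect_width / 2)
  expect_error(heatmap_grid(c(30, 0), 20, 20, screen = default_screen()),
               "beyond the displayable field")
})

test_that("an ideal observer yields a binary heat map matching containment", {
  obs <- ideal_observer(c(16, -2), 6, 7)
  g <- heatmap_grid(c(16, -2), 6, 7, rows = 9, cols = 9)
  set.seed(21)
  hm <- run_heatmap(g, obs, trials_per_cell = 2)
  expect_equal(nrow(hm$trials), 9 * 9 * 2)
  blind <- oracle_blind_cells(g, c(16, -2), 6, 7)
  for (i in seq_len(nrow(g$cells))) {
    cell <- g$cells[i, ]
    is_blind <- any(blind$row == cell$row & blind$col == cell$col)
    expect_equal(hm$matrix[cell$row, cell$col], if (is_blind) 0 else 1)
  }
})

test_that("a guessing observer scores inner cells at the guess rate", {
  obs <- scotoma_observer(c(16, -2), 6, 7, boundary_slope = 0,
                          lapse_rate = 0, guess_rate = 0.1,
                          fixation_jitter_sd = 0)
  g <- heatmap_grid(c(16, -2), 2, 2, rows = 2, cols = 2)  # deep inside
  set.seed(22)
  vals <- replicate(300, run_heatmap(g, obs, trials_per_cell = 10)$matrix[1, 1])
  expect_true(all(vals %in% ((0:10) / 10)))
  expect_equal(mean(vals), 0.10, tolerance = 0.03)
})

test_that("blind spot extraction takes outer edges of sub-threshold cells", {
  g <- heatmap_grid(c(0, 0), 3 / 1.1, 3 / 1.2, rows = 3, cols = 3)  # 1x1 cells
  m <- matrix(1, 3, 3); m[2, 2] <- 0
  bs <- blind_spot_from_heatmap(m, g)
  expect_equal(nrow(bs$cells), 1)
  expect_equal(c(bs$width, bs$height), c(1, 1))
  empty <- blind_spot_from_heatmap(matrix(1, 3, 3), g)
  expect_equal(c(empty$width, empty$height), c(0, 0))
  expect_error(blind_spot_from_heatmap(matrix(1, 4, 3), g))
})

test_that("heat-map sizes converge to the true axes with grid resolution", {
  # the any-part-visible rule marks a cell blind only when fully contained,
  # so each side can lose up to one partially-covered cell: the estimate is
  # within two cells of the true axis per dimension, and the absolute error
  # shrinks as the grid is refined
  obs <- ideal_observer(c(16, -2.05), 6.28, 7.02)
  err <- sapply(c(10, 20, 40), function(n) {
    g <- heatmap_grid(c(16, -2.05), 6.28, 7.02, rows = n, cols = n)
    set.seed(100 + n)
    hm <- run_heatmap(g, obs, trials_per_cell = 1)
    bs <- blind_spot_from_heatmap(hm$matrix, g)
    expect_lte(abs(bs$width - 6.28), 2 * g$cell_width)
    expect_lte(abs(bs$height - 7.02), 2 * g$cell_height)
    abs(bs$width - 6.28) + abs(bs$height - 7.02)
  })
  expect_lt(err[3], err[1])
  expect_lt(err[3], 0.5)
})

test_that("scaling coefficients are an inclusive arithmetic progression", {
  cc <- scaling_coefficients()
  expect_equal(length(cc), 10)
  expect_equal(cc[1], 0.6)
  expect_equal(cc[10], 1.2)
  expect_equal(unique(round(diff(cc), 4)), 0.0667)
  expect_true(all(abs(c(0.6667, 0.8667, 1.0667) -
                        cc[c(2, 5, 8)]) < 1e-4))
  expect_equal(scaling_coefficients(2), c(0.6, 1.2))
  expect_error(scaling_coefficients(10, 1.2, 0.6), "below")
})

test_that("scaling with a perfect estimate separates contained from protruding probes", {
  obs <- ideal_observer(c(16, -2), 6, 7)
  set.seed(23)
  sc <- run_scaling(c(16, -2), 6, 7, obs, trials_per_size = 3)
  expect_equal(nrow(sc), 10)
  expect_equal(sum(sc$n_trials), 30)
  expect_true(all(sc$proportion[sc$coefficient < 1] == 0))
  expect_true(all(sc$proportion[sc$coefficient > 1] == 1))
  expect_true(all(diff(sc$proportion) >= 0))
})

test_that("fixation jitter makes near-size probes easier to see than small ones", {
  obs <- scotoma_observer(c(16, -2.05), 6.28, 7.02, boundary_slope = 0,
                          lapse_rate = 0, guess_rate = 0,
                          fixation_jitter_sd = 0.3)
  set.seed(24)
  sc <- run_scaling(c(16, -2.05), 6.28, 7.02, obs, trials_per_size = 10)
  expect_gt(sc$proportion[sc$coefficient == 1],
            sc$proportion[sc$coefficient == 0.6])
})

test_that("the logistic visibility fit recovers exact parameters and matches a grid oracle", {
  x <- scaling_coefficients()
  y <- 1 / (1 + exp(-10 * (x - 0.8)))
  fit <- fit_sigmoid(x, y)
  expect_equal(fit$t, 10, tolerance = 1e-6)
  expect_equal(fit$x0, 0.8, tolerance = 1e-6)
  expect_equal(fit$predict(fit$x0), 50)
  props <- c(0, 0, 0, 0, 0.1, 0.3, 0.6, 0.9, 1, 1)
  fit2 <- fit_sigmoid(x, props)
  oracle <- oracle_sigmoid_grid(x, props)
  expect_lte(fit2$sse, oracle$sse + 1e-6)
  expect_equal(fit2$x0, oracle$x0, tolerance = 0.01)
  expect_gt(fit2$x0, 0.87)
  expect_lt(fit2$x0, 1.0)
  expect_error(fit_sigmoid(x, rep(0, 10)), "degenerate")
  expect_error(fit_sigmoid(x[1:2], c(0, 1)), "3 distinct")
})

test_that("the largest fully invisible size follows its definition", {
  x <- scaling_coefficients()
  expect_equal(zero_visible_size(x, c(0, 0, 0, 0.1, rep(1, 6))), x[3])
  expect_equal(round(x[3], 3), 0.733)
  expect_equal(zero_visible_size(x, rep(0, 10)), 1.2)
  expect_true(is.na(zero_visible_size(x, c(0.1, rep(0, 9)))))
})
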