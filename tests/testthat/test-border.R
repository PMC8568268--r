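test_that("clicks cluster into two averaged border points", {
  path <- test_path(3, "horizontal", anchor = -2, extent = c(10, 22))
  clicks <- data.frame(x_deg = c(12.9, 13.1, 13.0, 18.9, 19.1, 19.0),
                       y_deg = -2)
  bp <- cluster_clicks(clicks, path)
  expect_equal(bp$x_deg, c(13, 19))
  expect_equal(bp$y_deg, c(-2, -2))
  expect_equal(bp$side, c("lo", "hi"))
})

test_that("degenerate or unusable click sets are rejected", {
  path <- test_path(1, "horizontal", anchor = -2, extent = c(10, 22))
  tight <- data.frame(x_deg = 13 + c(0, 0.02, 0.04, 0.06, 0.08, 0.1),
                      y_deg = -2)
  expect_error(cluster_clicks(tight, path), "degenerate")
  odd <- data.frame(x_deg = c(13, 13.1, 18.9, 19, 19.1), y_deg = -2)
  expect_error(cluster_clicks(odd, path), "odd")
  expect_error(cluster_clicks(tight[1:2, ], path), "at least 4")
})

test_that("noise-free probe runs click exactly at the boundary crossings", {
  obs <- ideal_default()
  path <- test_path(1, "horizontal", anchor = -2.05, extent = c(10, 22))
  clicks <- simulate_probe_run(path, obs, round_trips = 3)
  expect_equal(nrow(clicks), 12)  # 2 clicks x 2 passes x 3 trips
  want <- oracle_crossings(c(16, -2.05), 6.28, 7.02, "horizontal", -2.05)
  expect_equal(sort(unique(round(clicks$x_deg, 9))), round(want, 9),
               tolerance = 1e-9)
  expect_setequal(clicks$transition, c("disappear", "reappear"))
  # a path that misses the scotoma entirely is a planning error
  far <- test_path(1, "horizontal", anchor = 10, extent = c(10, 22))
  expect_error(simulate_probe_run(far, obs), "mis-aimed")
})

test_that("the three-step paths are planned through the running midpoints", {
  p1pts <- data.frame(x_deg = c(13, 19), y_deg = c(-2, -2))
  p2 <- plan_low_mode_path(2, previous_points = p1pts)
  expect_equal(p2$anchor, 16)
  expect_equal(p2$orientation, "vertical")
  p2pts <- data.frame(x_deg = c(16, 16), y_deg = c(1.5, -5.5))
  p3 <- plan_low_mode_path(3, previous_points = p2pts)
  expect_equal(p3$anchor, -2)
  p1 <- plan_low_mode_path(1, prior_region = c(12, 20, -6, 2))
  expect_equal(p1$anchor, -2)
  expect_error(plan_low_mode_path(2), "border points")
})

test_that("cardinal points combine into location, width and height", {
  p2 <- test_path(2, "vertical", 16, c(-8, 4))
  p3 <- test_path(3, "horizontal", -2, c(10, 22))
  pts2 <- data.frame(x_deg = 16, y_deg = c(-5.5, 1.5))
  pts3 <- data.frame(x_deg = c(13, 19), y_deg = -2)
  est <- estimate_location_and_size(p2, pts2, p3, pts3)
  expect_equal(est$location, c(16, -2))
  expect_equal(est$width, 6)
  expect_equal(est$height, 7)
  expect_error(estimate_location_and_size(p3, pts3, p3, pts3),
               "perpendicular")
  same <- data.frame(x_deg = c(16, 16), y_deg = c(-2, -2))
  expect_error(estimate_location_and_size(p2, same, p3, same))
})

test_that("a noise-free low-mode run recovers the scotoma geometry", {
  obs <- ideal_default()
  set.seed(1)
  det <- run_border_detection(obs, "low")
  expect_equal(nrow(det$border_points), 6)
  expect_lt(sqrt(sum((det$location - c(16, -2.05))^2)), 0.05)
  expect_equal(det$width, 6.28, tolerance = 1e-6)
  expect_equal(det$height, 7.02, tolerance = 1e-6)
  expect_equal(sum(det$border_points$cardinal), 4)
})

test_that("medium mode detects 14 points, all on the true ellipse", {
  obs <- ideal_default()
  set.seed(2)
  det <- run_border_detection(obs, "medium")
  expect_equal(nrow(det$border_points), 14)
  expect_equal(length(det$paths), 7)
  # shared prefix with low mode
  expect_equal(vapply(det$paths[1:3], function(p) p$index, 0), 1:3)
  r <- sqrt(((det$border_points$x_deg - 16) / 3.14)^2 +
              ((det$border_points$y_deg + 2.05) / 3.51)^2)
  expect_equal(r, rep(1, 14), tolerance = 1e-9)
  set.seed(3)
  expect_equal(nrow(run_border_detection(obs, "high")$border_points), 22)
})

test_that("the estimate is invariant to small prior-region shifts", {
  obs <- ideal_default()
  set.seed(4)
  a <- run_border_detection(obs, "low", prior_region = c(12, 20, -6, 2))
  b <- run_border_detection(obs, "low", prior_region = c(13, 21, -5, 3))
  expect_equal(a$location, b$location, tolerance = 1e-9)
  expect_equal(a$width, b$width, tolerance = 1e-9)
})

test_that("raw border points track the boundary under the default noise", {
  obs <- default_observer()
  set.seed(5)
  errs <- t(replicate(50, {
    det <- run_border_detection(obs, "low")
    c(sqrt(sum((det$location - c(16, -2.05))^2)),
      abs(det$width - 6.28) / 6.28, abs(det$height - 7.02) / 7.02)
  }))
  expect_lte(median(errs[, 1]), obs$fixation_jitter_sd)
  expect_lte(median(errs[, 2]), 0.05)
  expect_lte(median(errs[, 3]), 0.05)
})
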