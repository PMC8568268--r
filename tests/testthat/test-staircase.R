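run_scripted <- function(responses, rules = staircase_rules()) {
  s <- staircase_init(rules)
  for (r in responses) s <- staircase_step(s, r, rules)
  s
}

test_that("scripted N,Y,Y reproduces the hand-simulated trace", {
  s <- run_scripted(c("no", "yes", "yes"))
  tr <- staircase_trace(s)
  expect_equal(tr$increment_pix, c(50, 20, 35))
  expect_equal(s$increment, 50)              # next presentation
  expect_equal(tr$reversal, c(FALSE, TRUE, FALSE))
  expect_equal(tr$step_size, c(30, 15, 15))  # reversal move uses the new step
})

test_that("the pre-reversal regime is 1-up-1-down and monotone under all-N", {
  s <- run_scripted(rep("no", 6))
  tr <- staircase_trace(s)
  expect_equal(tr$increment_pix, c(50, 20, -10, -40, -70, -100))
  expect_equal(s$reversal_count, 0L)
})

test_that("after the first reversal three consecutive no's are needed to move down", {
  s <- run_scripted(c("no", "yes", "no", "no", "no"))
  tr <- staircase_trace(s)
  # holds at 35 for two N's, third N moves down with the post-reversal step
  expect_equal(tr$increment_pix, c(50, 20, 35, 35, 35))
  expect_equal(tr$move, c("down", "up", "hold", "hold", "down"))
  expect_equal(s$increment, 35 - 7)          # down move is itself a reversal
  expect_equal(s$reversal_count, 2L)
  # a yes resets the consecutive-no counter
  s2 <- run_scripted(c("no", "yes", "no", "no", "yes", "no", "no"))
  expect_equal(s2$consecutive_no, 2L)
  expect_equal(staircase_trace(s2)$move[6:7], c("hold", "hold"))
})

test_that("increments change only by the step in force and steps shrink at reversals", {
  rules <- staircase_rules()
  set.seed(8)
  for (rep in 1:10) {
    s <- run_scripted(sample(c("yes", "no"), 40, replace = TRUE), rules)
    tr <- staircase_trace(s)
    deltas <- diff(tr$increment_pix)
    expect_true(all(abs(deltas) %in% c(0, rules$step_sizes)))
    steps <- tr$step_size[!is.na(tr$step_size)]
    expect_true(all(diff(match(steps, rules$step_sizes)) >= 0))
    if (s$reversal_count >= 4)
      expect_equal(steps[length(steps)], 3)
  }
  expect_error(staircase_step(staircase_init(rules), "maybe", rules),
               "yes.*no")
  expect_error(staircase_rules(step_sizes = c(3, 7, 15, 30)), "decreasing")
})

test_that("run_staircase consumes exactly n_trials successful trials", {
  obs <- default_observer()
  set.seed(9)
  res <- run_staircase(c(19.14, -2.05), c(16, -2.05), obs)
  ok <- res$trace[res$trace$fixation_ok, ]
  expect_equal(nrow(ok), 20)
  expect_equal(ok$trial_index, 1:20)
  # collinearity: adjusted point on the ray from the raw point to center
  v1 <- res$adjusted_point - c(19.14, -2.05)
  v2 <- c(16, -2.05) - c(19.14, -2.05)
  expect_lt(abs(v1[1] * v2[2] - v1[2] * v2[1]), 1e-9)
  expect_error(run_staircase(c(16, -2), c(16, -2), obs), "coincides")
})

test_that("against a hard ellipse the staircase ends inward of the raw point", {
  obs <- ideal_observer(c(16, -2), 6, 7)
  # raw point slightly outside the true boundary on the temporal side
  raw <- c(19.3, -2)
  for (seed in 1:5) {
    set.seed(seed)
    res <- run_staircase(raw, c(16, -2), obs)
    expect_gt(res$final_increment_pix, 0)
  }
})

test_that("adjusted border points are less visible than raw ones on average", {
  obs <- default_observer()
  raw <- c(16 + 3.14, -2.05)                 # true 50% boundary point
  set.seed(10)
  vis <- t(replicate(100, {
    res <- run_staircase(raw, obs$center, obs)
    c(point_visibility(raw, obs), point_visibility(res$adjusted_point, obs))
  }))
  expect_lt(mean(vis[, 2]), mean(vis[, 1]))
})

test_that("1-up-1-down converges to the 50% level", {
  pyes <- function(x) 1 - plogis((x - 1) / 0.5)
  set.seed(12)
  res <- convergence_probability(staircase_rules(down_count = 1),
                                 pyes, n_runs = 500)
  expect_lte(abs(res$p_no - 0.5), 0.02)
})

test_that("a step psychometric pins the staircase at the step location", {
  pyes <- function(x) as.numeric(x < 1)
  set.seed(13)
  res <- convergence_probability(staircase_rules(), pyes,
                                 n_runs = 200, step = 0.05)
  expect_lt(abs(res$mean_level - 1), 0.05 * 2)
  nonmono <- function(x) 0.5 + 0.4 * sin(x)
  expect_error(convergence_probability(staircase_rules(), nonmono,
                                       n_runs = 10),
               "monotone")
})
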