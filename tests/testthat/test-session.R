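test_that("expected trial counts follow mode and validation choice", {
  low_hm <- block_protocol("low", validation = list(
    kind = "heatmap", rows = 10, cols = 10, trials_per_cell = 10))
  expect_equal(expected_trial_counts(low_hm),
               c(detection = 36, staircase = 80, validation = 1000))
  med_sc <- block_protocol("medium", validation = list(
    kind = "scaling", n_sizes = 10, trials_per_size = 10))
  expect_equal(expected_trial_counts(med_sc),
               c(detection = 84, staircase = 280, validation = 100))
  low_15 <- block_protocol("low", validation = list(
    kind = "heatmap", rows = 15, cols = 15, trials_per_cell = 10))
  expect_equal(unname(expected_trial_counts(low_15)["validation"]), 2250)
  high <- block_protocol("high", validation = list(kind = "none"))
  expect_equal(expected_trial_counts(high),
               c(detection = 132, staircase = 440, validation = 0))
})

test_that("the fixation gate is boundary-inclusive on the Euclidean norm", {
  expect_true(fixation_gate(c(0, 0)))
  expect_true(fixation_gate(c(1.5, 0), tolerance = 1.5))
  expect_false(fixation_gate(c(1.2, 1.2), tolerance = 1.5))
  expect_error(fixation_gate(c(0, 0), tolerance = 0))
})

test_that("blocks are deterministic given protocol, observer and seed", {
  proto <- block_protocol()
  obs <- default_observer()
  a <- run_block(proto, obs, seed = 99)
  b <- run_block(proto, obs, seed = 99)
  expect_identical(a$location, b$location)
  expect_identical(a$border_points, b$border_points)
  expect_identical(a$staircase_traces, b$staircase_traces)
  expect_identical(as.data.frame(a$validation), as.data.frame(b$validation))
  c_ <- run_block(proto, obs, seed = 100)
  expect_false(identical(a$location, c_$location))
})

test_that("a jitter-free observer never triggers the fixation gate", {
  obs <- scotoma_observer(fixation_jitter_sd = 0)
  blk <- run_block(block_protocol(), obs, seed = 5)
  expect_true(all(blk$staircase_traces$fixation_ok))
  ok <- blk$staircase_traces[blk$staircase_traces$fixation_ok, ]
  expect_equal(nrow(ok),
               unname(expected_trial_counts(blk$protocol)["staircase"]))
})

test_that("a medium block logs 14 raw and 14 adjusted border points", {
  proto <- block_protocol("medium", validation = list(kind = "none"))
  blk <- run_block(proto, default_observer(), seed = 6)
  bp <- blk$border_points
  expect_equal(sum(bp$stage == "raw"), 14)
  expect_equal(sum(bp$stage == "adjusted"), 14)
  expect_equal(length(unique(blk$staircase_traces$point_id)), 14)
})

test_that("block rows feed the per-observer summary pipeline", {
  proto <- block_protocol()
  obs <- default_observer()
  rows <- do.call(rbind, lapply(1:3, function(s)
    block_row(run_block(proto, obs, seed = s), block_id = s)))
  summ <- summarize_observer(rows, observer_id = "sim")
  expect_equal(summ$n_blocks, 3)
  expect_false(is.na(summ$raw_sum_stdist))
  expect_false(is.na(summ$adj_sum_stdist))
  expect_lt(abs(summ$loc_h - 16), 1)
})

test_that("JSON configuration round-trips into a protocol and observer", {
  cfg <- list(mode = "low", round_trips = 2,
              screen = list(width_cm = 40, height_cm = 30,
                            width_pix = 1280, height_pix = 960,
                            viewing_distance_cm = 57,
                            fixation_pix = c(-300, 0)),
              staircase = list(n_trials = 10),
              validation = list(kind = "scaling", n_sizes = 5,
                                trials_per_size = 4),
              fixation_tolerance = 1.0,
              observer = list(center = c(15.5, -1.8), width = 6, height = 7))
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(cfg, path, auto_unbox = TRUE)
  loaded <- read_config(path)
  expect_equal(loaded$protocol$round_trips, 2)
  expect_equal(loaded$protocol$staircase$n_trials, 10)
  expect_equal(loaded$protocol$staircase$initial_increment, 50)
  expect_equal(loaded$protocol$fixation_tolerance, 1.0)
  expect_equal(loaded$observer$center, c(15.5, -1.8))
})

test_that("block artifacts are written as plain-text files", {
  blk <- run_block(block_protocol(), default_observer(), seed = 3)
  dir <- withr::local_tempdir()
  paths <- write_block(blk, dir)
  expect_true(all(file.exists(paths)))
  bp <- read.csv(file.path(dir, "border_points.csv"))
  expect_setequal(unique(bp$stage), c("raw", "adjusted"))
  js <- jsonlite::read_json(file.path(dir, "block_result.json"))
  expect_equal(js$mode, "low")
  expect_equal(js$width, blk$width)
})
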