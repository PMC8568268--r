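#' Protocol for a full mapping block
#'
#' A block runs three sections in order: border points detection,
#' staircase refinement, and validation. The protocol fixes the mode
#' (which determines how many border points are detected and
#' staircased), the number of probe round trips per path, the staircase
#' rules, the validation procedure, and the fixation tolerance.
#'
#' @param mode `"low"` (6 border points, 4 cardinal points staircased),
#'   `"medium"` (14 points, all staircased) or `"high"` (22 points).
#' @param round_trips Probe round trips per path (default 3).
#' @param staircase A `bs_staircase_rules`.
#' @param validation A list: either
#'   `list(kind = "scaling", n_sizes = 10, trials_per_size = 10)` or
#'   `list(kind = "heatmap", rows = 10, cols = 10, trials_per_cell = 10)`,
#'   or `list(kind = "none")`.
#' @param fixation_tolerance Gaze tolerance in deg (default 1.5); trials
#'   with gaze further from fixation are invalidated and re-run.
#' @param prior_region `c(x_lo, x_hi, y_lo, y_hi)` prior search region
#'   for the first test path, deg.
#' @param screen A `bs_screen`.
#' @param fixation Fixation object position, screen pixels.
#' @return An object of class `bs_protocol`.
#' @export
block_protocol <- function(mode = c("low", "medium", "high"),
                           round_trips = 3,
                           staircase = staircase_rules(),
                           validation = list(kind = "scaling",
                                             n_sizes = 10,
                                             trials_per_size = 10),
                           fixation_tolerance = 1.5,
                           prior_region = c(12, 20, -6, 2),
                           screen = default_screen(),
                           fixation = c(-300, 0)) {
  mode <- match.arg(mode)
  stopifnot(round_trips >= 1, fixation_tolerance > 0,
            inherits(staircase, "bs_staircase_rules"))
  if (!validation$kind %in% c("scaling", "heatmap", "none"))
    stop("validation kind must be 'scaling', 'heatmap' or 'none'")
  structure(list(mode = mode, round_trips = round_trips,
                 staircase = staircase, validation = validation,
                 fixation_tolerance = fixation_tolerance,
                 prior_region = prior_region, screen = screen,
                 fixation = fixation),
            class = "bs_protocol")
}

#' Is a gaze offset within the fixation tolerance?
#'
#' A trial is valid when the Euclidean norm of the gaze offset from the
#' fixation object does not exceed the tolerance (boundary inclusive).
#'
#' @param gaze_offset `c(h, v)` gaze error, deg.
#' @param tolerance Tolerance, deg (> 0).
#' @return Logical.
#' @export
fixation_gate <- function(gaze_offset, tolerance = 1.5) {
  stopifnot(tolerance > 0)
  sqrt(sum(gaze_offset^2)) <= tolerance
}

#' Minimum trial counts per section of a block
#'
#' Detection counts click events: border points times two clicks per
#' point per round trip. The staircase runs `n_trials` per staircased
#' point (the 4 cardinal points in low mode; all points in medium and
#' high). Validation counts cells times trials per cell, or sizes times
#' trials per size. Invalid-fixation re-runs only ever add to these.
#'
#' @param protocol A `bs_protocol`.
#' @return Named numeric vector `c(detection, staircase, validation)`.
#' @export
expected_trial_counts <- function(protocol) {
  stopifnot(inherits(protocol, "bs_protocol"))
  n_points <- switch(protocol$mode, low = 6, medium = 14, high = 22)
  n_staircased <- if (protocol$mode == "low") 4 else n_points
  v <- protocol$validation
  validation <- switch(v$kind,
    heatmap = v$rows * v$cols * v$trials_per_cell,
    scaling = v$n_sizes * v$trials_per_size,
    none = 0)
  c(detection = n_points * 2 * protocol$round_trips,
    staircase = n_staircased * protocol$staircase$n_trials,
    validation = validation)
}

#' Run a full mapping block against a simulated observer
#'
#' Executes the three sections in order, passing estimates forward: the
#' border detection section produces raw border points and the location
#' and size estimates; the staircase section refines each staircased
#' border point along the ray toward the estimated location; the final
#' width and height are recomputed from the adjusted cardinal points; and
#' the validation section (heat map or scaling) is built on the adjusted
#' estimates. The run is deterministic given (protocol, observer, seed).
#'
#' @param protocol A `bs_protocol`.
#' @param obs A `bs_observer`.
#' @param seed Integer seed for the block's random stream.
#' @return A list of class `bs_block_result`: `location`, `width`,
#'   `height` (adjusted), `raw_width`, `raw_height`, `border_points`
#'   (raw and adjusted stages), `staircase_traces`, `validation`,
#'   `detection`, `protocol`, `seed`.
#' @export
run_block <- function(protocol, obs, seed = 1) {
  stopifnot(inherits(protocol, "bs_protocol"), inherits(obs, "bs_observer"))
  set.seed(seed)
  det <- run_border_detection(obs, protocol$mode, protocol$prior_region,
                              protocol$round_trips)
  raw <- det$border_points
  stair_ids <- if (protocol$mode == "low")
    raw$point_id[raw$cardinal] else raw$point_id
  traces <- list()
  adj <- raw
  adj$stage <- "adjusted"
  raw$stage <- "raw"
  adj <- adj[adj$point_id %in% stair_ids, ]
  for (i in seq_len(nrow(adj))) {
    pid <- adj$point_id[i]
    res <- run_staircase(c(adj$x_deg[i], adj$y_deg[i]), det$location, obs,
                         protocol$staircase, protocol$screen,
                         protocol$fixation_tolerance)
    adj$x_deg[i] <- res$adjusted_point[1]
    adj$y_deg[i] <- res$adjusted_point[2]
    res$trace$point_id <- pid
    traces[[i]] <- res$trace
  }
  # final size from the adjusted cardinal points
  card2 <- adj[adj$path_index == 2, ]   # vertical path: top/bottom
  card3 <- adj[adj$path_index == 3, ]   # horizontal path: left/right
  height <- abs(diff(card2$y_deg))
  width <- abs(diff(card3$x_deg))
  v <- protocol$validation
  validation <- switch(v$kind,
    none = NULL,
    heatmap = {
      grid <- heatmap_grid(det$location, width, height,
                           rows = v$rows, cols = v$cols)
      run_heatmap(grid, obs, v$trials_per_cell,
                  protocol$fixation_tolerance)
    },
    scaling = run_scaling(det$location, width, height, obs,
                          v$trials_per_size,
                          scaling_coefficients(v$n_sizes),
                          protocol$fixation_tolerance))
  structure(list(location = det$location,
                 width = width, height = height,
                 raw_width = det$width, raw_height = det$height,
                 border_points = rbind(raw, adj),
                 staircase_traces = do.call(rbind, traces),
                 validation = validation, detection = det,
                 protocol = protocol, seed = seed),
            class = "bs_block_result")
}

#' @export
print.bs_block_result <- function(x, ...) {
  cat(sprintf("<bs_block_result> %s mode block (seed %s)\n",
              x$protocol$mode, format(x$seed)))
  cat(sprintf("  location (%.2f, %.2f) deg\n", x$location[1], x$location[2]))
  cat(sprintf("  size raw %.2f x %.2f deg, adjusted %.2f x %.2f deg\n",
              x$raw_width, x$raw_height, x$width, x$height))
  if (!is.null(x$validation))
    cat(sprintf("  validation: %s\n", x$protocol$validation$kind))
  invisible(x)
}

#' Summaries of a block result as a flat row
#'
#' One row per block with location, sizes, and the cardinal border points
#' of both stages, in the column layout consumed by
#' [summarize_observer()].
#'
#' @param block A `bs_block_result`.
#' @param block_id Identifier carried into the row.
#' @return A one-row data.frame.
#' @export
block_row <- function(block, block_id = NA) {
  bp <- block$border_points
  pick <- function(stage, path, side) {
    r <- bp[bp$stage == stage & bp$path_index == path & bp$side == side, ]
    c(r$x_deg[1], r$y_deg[1])
  }
  row <- data.frame(block_id = block_id,
                    loc_h = block$location[1], loc_v = block$location[2],
                    width = block$width, height = block$height)
  for (stage in c("raw", "adj")) {
    st <- if (stage == "raw") "raw" else "adjusted"
    for (spec in list(c("left", 3, "lo"), c("right", 3, "hi"),
                      c("bottom", 2, "lo"), c("top", 2, "hi"))) {
      p <- pick(st, as.numeric(spec[2]), spec[3])
      row[[paste(stage, spec[1], "x", sep = "_")]] <- p[1]
      row[[paste(stage, spec[1], "y", sep = "_")]] <- p[2]
    }
  }
  row
}

#' Read a block protocol from a JSON configuration file
#'
#' The configuration mirrors the package defaults; any omitted block
#' falls back to them. Recognized top-level blocks: `screen`
#' (`width_cm`, `height_cm`, `width_pix`, `height_pix`,
#' `viewing_distance_cm`, `fixation_pix`), `mode`, `round_trips`,
#' `staircase` (`initial_increment`, `step_sizes`, `n_trials`,
#' `n_reversals`, `down_count`), `validation` (`kind` plus its counts),
#' `fixation_tolerance`, `prior_region`, and `observer` (parameters for
#' [scotoma_observer()]).
#'
#' @param path Path to a JSON file.
#' @return A list with `protocol` (`bs_protocol`) and `observer`
#'   (`bs_observer`).
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  scr <- if (!is.null(cfg$screen))
    screen_model(cfg$screen$width_cm, cfg$screen$height_cm,
                 cfg$screen$width_pix, cfg$screen$height_pix,
                 cfg$screen$viewing_distance_cm)
  else default_screen()
  fixation <- if (!is.null(cfg$screen$fixation_pix))
    as.numeric(cfg$screen$fixation_pix) else c(-300, 0)
  sc <- cfg$staircase
  rules <- staircase_rules(
    initial_increment = sc$initial_increment %||% 50,
    step_sizes = sc$step_sizes %||% c(30, 15, 7, 3),
    n_trials = sc$n_trials %||% 20,
    n_reversals = sc$n_reversals %||% 4,
    down_count = sc$down_count %||% 3)
  val <- cfg$validation %||% list(kind = "scaling", n_sizes = 10,
                                  trials_per_size = 10)
  obs_args <- cfg$observer %||% list()
  if (!is.null(obs_args$center)) obs_args$center <- as.numeric(obs_args$center)
  obs <- do.call(scotoma_observer, obs_args)
  proto <- block_protocol(
    mode = cfg$mode %||% "low",
    round_trips = cfg$round_trips %||% 3,
    staircase = rules, validation = val,
    fixation_tolerance = cfg$fixation_tolerance %||% 1.5,
    prior_region = as.numeric(cfg$prior_region %||% c(12, 20, -6, 2)),
    screen = scr, fixation = fixation)
  list(protocol = proto, observer = obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write the artifacts of a block result to a directory
#'
#' Emits plain-text outputs: the border points CSV (raw and adjusted
#' stages), the staircase trace CSV, the validation CSV (heat-map matrix
#' or scaling curve), and a JSON summary of the estimates.
#'
#' @param block A `bs_block_result`.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_block <- function(block, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character()
  p <- file.path(dir, "border_points.csv")
  utils::write.csv(block$border_points, p, row.names = FALSE)
  paths <- c(paths, p)
  if (!is.null(block$staircase_traces)) {
    p <- file.path(dir, "staircase_trace.csv")
    utils::write.csv(block$staircase_traces, p, row.names = FALSE)
    paths <- c(paths, p)
  }
  if (!is.null(block$validation)) {
    p <- file.path(dir, "validation.csv")
    if (inherits(block$validation, "bs_heatmap")) {
      utils::write.csv(block$validation$matrix, p, row.names = FALSE)
    } else {
      utils::write.csv(as.data.frame(block$validation), p, row.names = FALSE)
    }
    paths <- c(paths, p)
  }
  p <- file.path(dir, "block_result.json")
  jsonlite::write_json(
    list(seed = block$seed, mode = block$protocol$mode,
         location = block$location,
         width = block$width, height = block$height,
         raw_width = block$raw_width, raw_height = block$raw_height),
    p, auto_unbox = TRUE, digits = NA)
  paths <- c(paths, p)
  invisible(paths)
}
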