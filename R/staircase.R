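#' Transformed up-down staircase rules
#'
#' Default rules: initial increment 50 pix, step-size schedule
#' \[30, 15, 7, 3\] pix applied largest first and advanced at each
#' reversal, 20 successful trials, 4 scheduled reversals, 1-up-3-down,
#' and the final-1-trial threshold rule (the threshold is the increment
#' at which the last trial was presented). Before the first reversal the
#' procedure behaves as 1-up-1-down, so it descends quickly from the
#' deliberately-invisible starting increment; after the first reversal a
#' single "yes" moves the target up (toward the scotoma center) while
#' only three consecutive "no" answers move it down. The 1-up-3-down rule
#' converges where the probability of "no" is 0.5^(1/3), about 79%, i.e.
#' at the 21%-visible level.
#'
#' @param initial_increment Starting increment in pix (positive = toward
#'   the scotoma center from the raw border point).
#' @param step_sizes Decreasing step-size schedule, pix.
#' @param n_trials Successful trials to run.
#' @param n_reversals Scheduled reversals (the step schedule supports
#'   this many step reductions).
#' @param up_count,down_count Responses required for an up move (yes) and
#'   a down move (consecutive no); 1 and 3 give the standard rule.
#' @param require_reversals If `TRUE`, [run_staircase()] extends the run
#'   past `n_trials` until `n_reversals` reversals have occurred.
#' @return An object of class `bs_staircase_rules`.
#' @export
staircase_rules <- function(initial_increment = 50,
                            step_sizes = c(30, 15, 7, 3),
                            n_trials = 20, n_reversals = 4,
                            up_count = 1, down_count = 3,
                            require_reversals = FALSE) {
  if (any(diff(step_sizes) >= 0) && length(step_sizes) > 1)
    stop("step_sizes must be strictly decreasing (largest first)")
  if (n_trials < n_reversals) stop("n_trials must be >= n_reversals")
  if (up_count != 1) stop("only 1-up rules are supported")
  stopifnot(down_count >= 1)
  structure(list(initial_increment = initial_increment,
                 step_sizes = step_sizes, n_trials = n_trials,
                 n_reversals = n_reversals, up_count = up_count,
                 down_count = down_count,
                 require_reversals = require_reversals),
            class = "bs_staircase_rules")
}

#' Initialize staircase state
#'
#' @param rules A `bs_staircase_rules`.
#' @return A `bs_staircase_state`: the increment to present on the next
#'   trial, position in the step schedule, reversal and consecutive-no
#'   counters, last move direction, and trial history.
#' @export
staircase_init <- function(rules) {
  structure(list(increment = rules$initial_increment,
                 step_index = 1L, reversal_count = 0L,
                 consecutive_no = 0L, last_move = "none",
                 trial_index = 0L,
                 history = list()),
            class = "bs_staircase_state")
}

#' Advance the staircase by one response
#'
#' Implements the transformed 1-up-3-down update. A "yes" always moves
#' the increment up (target toward the scotoma center) and resets the
#' consecutive-no counter. A "no" moves the increment down immediately
#' while no reversal has yet occurred (1-up-1-down start-up regime);
#' afterwards it moves down only on every `down_count`-th consecutive
#' "no", otherwise the increment holds. A move whose direction differs
#' from the previous move is a reversal: it advances the step schedule
#' (capped at the smallest step) and the reversal-causing move itself is
#' taken with the new, smaller step.
#'
#' @param state A `bs_staircase_state`.
#' @param response `"yes"` or `"no"`.
#' @param rules A `bs_staircase_rules`.
#' @return The updated state. `state$increment` is the increment for the
#'   next trial; the presented increment and response are appended to
#'   `state$history`.
#' @export
staircase_step <- function(state, response, rules) {
  if (!response %in% c("yes", "no")) stop("response must be 'yes' or 'no'")
  presented <- state$increment
  if (response == "yes") {
    direction <- 1L
    state$consecutive_no <- 0L
  } else {
    state$consecutive_no <- state$consecutive_no + 1L
    if (state$reversal_count == 0L ||
        state$consecutive_no >= rules$down_count) {
      direction <- -1L
      state$consecutive_no <- 0L
    } else {
      direction <- 0L
    }
  }
  reversal <- FALSE
  step_used <- NA_real_
  if (direction != 0L) {
    prev <- switch(state$last_move, up = 1L, down = -1L, 0L)
    if (prev != 0L && direction != prev) {
      reversal <- TRUE
      state$reversal_count <- state$reversal_count + 1L
      state$step_index <- min(state$step_index + 1L,
                              length(rules$step_sizes))
    }
    step_used <- rules$step_sizes[state$step_index]
    state$increment <- state$increment + direction * step_used
    state$last_move <- if (direction > 0L) "up" else "down"
  }
  state$trial_index <- state$trial_index + 1L
  state$history[[state$trial_index]] <- data.frame(
    trial_index = state$trial_index, increment_pix = presented,
    response = response, reversal = reversal,
    step_size = step_used,
    move = c("down", "hold", "up")[direction + 2L])
  state
}

#' Staircase trial history as a data.frame
#' @param state A `bs_staircase_state`.
#' @return One row per trial: presented increment, response, reversal
#'   flag, step size of the resulting move (`NA` for holds).
#' @export
staircase_trace <- function(state) do.call(rbind, state$history)

#' Run a staircase to refine one border point
#'
#' Presents a point target displaced from the raw border point toward the
#' estimated blind spot location by the current increment (pixels,
#' converted to degrees via the screen model), collects the simulated
#' observer's yes/no answer, and applies [staircase_step()] until
#' `n_trials` successful trials are done (optionally extended until the
#' scheduled reversal count is reached). Trials on which the sampled gaze
#' falls outside the fixation tolerance are discarded and re-run with
#' fresh randomness; they appear in the trace flagged invalid but do not
#' advance the staircase. The adjusted border point is the raw point
#' displaced by the final trial's increment (final-1-trial rule), so it
#' lies on the ray from the raw point toward the location.
#'
#' @param raw_point `c(h, v)` raw border point, deg.
#' @param center `c(h, v)` estimated blind spot location, deg.
#' @param obs A `bs_observer`.
#' @param rules A `bs_staircase_rules`.
#' @param screen A `bs_screen` for the pix-to-deg conversion.
#' @param fixation_tolerance Gaze tolerance in deg.
#' @param max_attempts Re-run guard per trial.
#' @return A list: `adjusted_point`, `final_increment_pix`, and `trace`
#'   (one row per attempted trial, including invalid ones).
#' @export
run_staircase <- function(raw_point, center, obs,
                          rules = staircase_rules(),
                          screen = default_screen(),
                          fixation_tolerance = 1.5,
                          max_attempts = 1000) {
  raw_point <- as.numeric(raw_point); center <- as.numeric(center)
  d <- center - raw_point
  len <- sqrt(sum(d^2))
  if (len == 0) stop("raw border point coincides with the estimated location")
  u <- d / len
  state <- staircase_init(rules)
  attempts <- list(); attempt_i <- 0L
  final_increment <- NA_real_
  repeat {
    done <- state$trial_index >= rules$n_trials &&
      (!rules$require_reversals || state$reversal_count >= rules$n_reversals)
    if (done) break
    inc_pix <- state$increment
    target <- raw_point + u * pix_to_deg(inc_pix, screen)
    tries <- 0L
    repeat {
      tries <- tries + 1L
      if (tries > max_attempts)
        stop("fixation never within tolerance after max_attempts re-runs")
      ans <- observer_answer(stimulus("point", target), obs)
      ok <- fixation_gate(ans$gaze_offset, fixation_tolerance)
      attempt_i <- attempt_i + 1L
      attempts[[attempt_i]] <- data.frame(
        attempt = attempt_i,
        trial_index = if (ok) state$trial_index + 1L else NA_integer_,
        increment_pix = inc_pix,
        target_x = target[1], target_y = target[2],
        response = ans$response, fixation_ok = ok,
        gaze_x = ans$gaze_offset[1], gaze_y = ans$gaze_offset[2])
      if (ok) break
    }
    final_increment <- inc_pix
    state <- staircase_step(state, ans$response, rules)
    machine <- state$history[[state$trial_index]]
    attempts[[attempt_i]]$reversal <- machine$reversal
    attempts[[attempt_i]]$step_size <- machine$step_size
  }
  trace <- do.call(rbind, lapply(attempts, function(a) {
    if (is.null(a$reversal)) { a$reversal <- NA; a$step_size <- NA_real_ }
    a
  }))
  adjusted <- raw_point + u * pix_to_deg(final_increment, screen)
  list(adjusted_point = adjusted, final_increment_pix = final_increment,
       trace = trace, state = state)
}

#' Long-run convergence level of a transformed up-down rule
#'
#' Monte-Carlo estimate of the probability of a "no" answer at the level
#' the staircase converges to, for an arbitrary monotone psychometric
#' function. Many long fixed-step staircases are simulated; each run's
#' converged level is the mean presented level over its second half, and
#' the psychometric is evaluated at the grand mean of these levels. For
#' the standard 1-up-3-down rule the result is P(no) = 0.5^(1/3), about
#' 0.794 (the 21%-visible level); a 1-up-1-down rule gives 0.5.
#'
#' The psychometric maps level to P(yes) and must be monotone (checked on
#' a grid); a "yes" moves the level in the direction that decreases
#' P(yes), as in the blind-spot task where seeing the target drives it
#' deeper into the scotoma.
#'
#' @param rules A `bs_staircase_rules`; only `down_count` matters here.
#' @param psychometric Function mapping level to P(yes).
#' @param n_runs Number of staircase runs (>= 2000 recommended).
#' @param n_trials Trials per run (at least 200 enforced).
#' @param step Fixed step size on the level axis.
#' @param start Starting level.
#' @param level_range Grid over which monotonicity is checked.
#' @return A list: `p_no` (probability of "no" at the converged level),
#'   `mean_level`, `n_runs`, `n_trials`.
#' @export
convergence_probability <- function(rules = staircase_rules(),
                                    psychometric, n_runs = 2000,
                                    n_trials = 200, step = 0.05,
                                    start = 0,
                                    level_range = c(-5, 5)) {
  n_trials <- max(n_trials, 200L)
  grid <- seq(level_range[1], level_range[2], length.out = 201)
  pg <- vapply(grid, psychometric, 0)
  dg <- diff(pg)
  if (any(dg > 1e-12) && any(dg < -1e-12))
    stop("psychometric must be monotone in the stimulus level")
  sgn_up <- if (sum(dg) <= 0) 1 else -1     # direction that decreases P(yes)
  down_count <- rules$down_count
  half <- (n_trials %/% 2L + 1L):n_trials
  run_means <- vapply(seq_len(n_runs), function(run) {
    lev <- start; last <- 0L; nrev <- 0L; cno <- 0L
    levels <- numeric(n_trials)
    for (i in seq_len(n_trials)) {
      levels[i] <- lev
      yes <- stats::runif(1) < psychometric(lev)
      if (yes) { dir <- 1L; cno <- 0L }
      else {
        cno <- cno + 1L
        if (nrev == 0L || cno >= down_count) { dir <- -1L; cno <- 0L }
        else dir <- 0L
      }
      if (dir != 0L) {
        if (last != 0L && dir != last) nrev <- nrev + 1L
        lev <- lev + dir * sgn_up * step
        last <- dir
      }
    }
    mean(levels[half])
  }, 0)
  mean_level <- mean(run_means)
  list(p_no = 1 - psychometric(mean_level), mean_level = mean_level,
       n_runs = n_runs, n_trials = n_trials)
}
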